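---
title: "Selecting a treatable-disease gene panel: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting a treatable-disease gene panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treatpanel)
```

## The problem and the model

Genomic newborn screening asks, for every candidate gene–disease pair:
would reporting a pathogenic genotype in a presymptomatic newborn do more
good than harm? `treatpanel` operationalizes that question as six
criteria. Two are mandatory gates — **treatability** (membership in at
least one curated source of treatable genetic diseases, with
source-specific filters applied at ingestion) and **genetic technical
feasibility** (mendelian inheritance, detectable by the sequencing
assay). The remaining four are scored 0–2 each:

* **Clinical validity** — GenCC-style multi-submitter curations; the
  highest-ranked curation wins (Definitive > Strong > Moderate > Limited
  > Animal Model Only > No Known Disease Relationship > Disputed >
  Refuted). Definitive/Strong score 2, Moderate 1, anything weaker 0.
* **Age of onset** — Orphanet categorical onset, earliest category of
  possibly several; ASQM onset is the fallback. Early childhood
  (antenatal, birth, neonatal, infancy, birth-to-childhood, childhood)
  scores 2, adolescence 1, adult/elderly 0.
* **Disease severity** — ASQM grades mapped 0→0, 1→1, 2→2, 3→2; a direct
  three-level category, when present, takes precedence.
* **Penetrance** — BabySeq-style categories low/moderate/high → 0/1/2; a
  numeric symptomatic fraction is categorized at ≥ 0.80 (high, boundary
  inclusive) and < 0.20 (low).

The total lies in [0, 8] and pairs totalling ≥ 7 are retained. The
arithmetic consequence — verified exhaustively in the test suite over all
3⁴ score combinations — is that exactly five combinations survive, the
minimum surviving total is 7, and **any criterion score of 0 excludes the
pair**. Scoring is per pair; a gene is retained when any of its pairs is,
and gene-level reports use each gene's best pair.

## Missing-data policy

Annotation resources for rare disease are incomplete, and the policy for
absent data is part of the model, not a nuisance detail:

* onset, severity, and penetrance default to the **middle score of 1**
  when no data exist in any consulted resource, so a pair is never
  excluded solely for lack of data on those criteria;
* validity is different: it is a strict evidence criterion (a pair must
  reach Definitive or Strong to be eligible), so a pair with **no
  validity curation at all scores 0** and fails the eligibility gate.
  This asymmetry is deliberate — validity is the one criterion where
  absence of evidence is disqualifying.

Every applied default is recorded in the score card's `notes` column, so
missing-data usage is auditable and testable (the generator's injected
missingness count must equal the number of noted defaults).

## Tunable parameters

All knobs live in `rubric_config()` and can be serialized to YAML, making
the rubric fully declarative:

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 7 | inclusion threshold on the 0–8 total |
| `missing_validity_score` | 0 | score for pairs with no validity curation |
| `missing_onset_score` / `missing_severity_score` / `missing_penetrance_score` | 1 | middle-score defaults |
| `validity_gate_enabled` | `TRUE` | require Definitive/Strong for eligibility |
| `penetrance_high_boundary` | 0.80 (inclusive) | fraction ↦ high category |
| `penetrance_low_boundary` | 0.20 (exclusive below) | fraction ↦ low category |
| `*_scores` tables | see above | every category-to-score mapping |

The 0.80 boundary is inclusive because the source penetrance vocabulary
defines high as "≥ 80 % of individuals symptomatic"; the boundary is a
config field precisely because restatements of that vocabulary differ on
the edge case.

## Identifier harmonization

Source lists name genes by symbol, previous symbol, or alias, and
diseases by Orphanet/OMIM accession or free text. Resolution is
case-insensitive with tier precedence current > previous > alias; an
alias matching two genes is returned as *unresolved* rather than guessed,
because a false gene identity is worse in a screening panel than a
flagged dropout. Merging is a **union** across sources keyed by (HGNC id,
MONDO id) — a source's presence is evidence of treatability, so the
combined list is the logical OR of the sources, with per-pair provenance
retained so any intersection view can be derived afterwards. Diseases
with no MONDO mapping survive under an `UNMAPPED` sentinel keyed by
label; records are never dropped silently, and the conservation identity
(resolved pairs + exceptions = distinct input records) is tested.

## Curation ledger semantics

Expert review is represented as typed proposals (include/exclude, reason
codes from a six-value taxonomy plus `OTHER`-with-free-text, proposer
role, round) each carrying one accept/reject decision. Design choices
where practice was genuinely open:

* decisions apply **as a set**, order-independently, with duplicate
  (action, gene) proposals collapsed — no semantics hide in row order;
* on conflict (same gene accepted for inclusion and exclusion) the
  **exclusion wins** with a logged warning, consistent with the panel's
  false-positive-averse posture;
* rejected and pending decisions are recorded in the audit trail but
  never touch the gene set;
* the treatment-window sub-criterion (treatment indicated within the
  first two years of life) is **not** part of the automated score; the
  package only *generates* exclusion proposals for genes all of whose
  pairs are annotated `treatment_within_2y = FALSE`. A missing flag
  generates nothing — automation surfaces documented negatives, experts
  decide everything else.

Panels are versioned with an audit trail; replaying a panel's audit onto
its post-threshold ancestor must reproduce the gene set exactly, and this
replay identity is tested on every pipeline run in the suite.

## The synthetic generator and the benchmark fixture

No real source list or annotation database is redistributed. The
generator (`generate_bundle()`) emulates their statistical structure:
per-source membership probabilities shaped like a treatability corpus
(broad curated sources covering most genes, narrow national-program lists
covering few), validity curations skewed toward Definitive/Strong (the
sources are pre-curated for treatability), paediatric-skewed onset, and
per-annotation missingness with penetrance the scarcest (defaults: 10 %
validity, 15 % onset, 20 % severity, 35 % penetrance). It also injects
alias-named and unresolvable gene tokens to exercise harmonization. Every
bundle carries a `truth` table computed by a straight-line oracle
(`oracle_scorecards()`) that shares no code with the rubric module, so
pipeline-vs-oracle equivalence is a meaningful check rather than a
tautology.

`benchmark_fixture()` is a deterministic constant engineered so the
pipeline reproduces a published panel build's flow: 484 genes / 485
pairs in, 265 genes excluded at the threshold, 219 retained, 34 removed
and 60 of 73 proposals added by curation, 245 genes out, with exact
pair-level score marginals (validity 36/11/438, onset 136/0/349, severity
7/311/167, penetrance 19/190/276), the published exclusion-reason
multiset (10/17/8/4/8/2 — 49 assignments over 34 genes, so genes carry
multiple reasons), and a nine-category composition totalling 245. The
binding constraints are the flow counts and composition; that the score
marginals could also be matched exactly is a property of the construction
(one gene carries two pairs, both excluded, reconciling 485 pairs with
484 genes). No retained pair has a validity score of 1, so toggling the
validity eligibility gate leaves every count unchanged — the fixture is
agnostic to that configuration choice. The fixture reproduces published
*counts*, not gene identities: all identifiers live in a reserved
namespace (`HGNC:9000001`+, `MONDO:91`…) that cannot collide with real
genes.

What passing on synthetic data does and does not show: it validates the
*logic* — scoring rules, threshold structure, ledger algebra, report
reconciliation — under realistic category frequencies and missingness. It
cannot validate the *content* of real sources (symbol drift in live HGNC
data, disagreeing GenCC submitters beyond two per pair, Orphanet records
whose onset spans change between releases), so a production run should
always review the exceptions report and the missing-default notes.

## Numerical and procedural choices

* Onset "earliest" uses the ordinal order antenatal < birth < neonatal <
  infancy < birth-to-childhood < childhood < adolescence < adult <
  elderly; antenatal scores 2, being unambiguously earlier than birth.
* Orphanet onset takes precedence over ASQM (fallback, not minimum):
  the two resources are consulted in order, matching how the missing
  rule is phrased against "either of these two resources".
* All outputs are deterministically ordered by (HGNC id, MONDO id); JSON
  exports use stable key order so repeated exports are byte-identical.
* Degenerate inputs: empty record sets error; empty ledgers advance the
  stage without changing the gene set; empty panels produce all-zero
  reports; out-of-vocabulary tokens error naming the offending token
  rather than being coerced.
* Problem sizes in the test suite were chosen for tight feedback loops:
  oracle-equivalence runs 100 seeded bundles of 12 genes, monotonicity 25
  bundles of 10 genes with four single-annotation improvements each, and
  the threshold enumeration covers all 81 combinations exactly.

## Known limitations

* Validity aggregation models multi-submitter curation only through the
  classification multiset; submitter identity and recency are carried
  but unused.
* The treatability gate is provenance-based: a source's internal
  evidence tier beyond its ingestion filter is not re-evaluated.
* Gene-level views assume the best-scoring pair represents the gene;
  programs screening for specific disease subtypes may prefer pair-level
  panels (both report variants are emitted).
* The curation module models the typed artifacts of expert review, not
  the review process itself (board composition, consensus dynamics).
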