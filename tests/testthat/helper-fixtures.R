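# Small in-code fixtures shared across test files.

tiny_symbol_map <- function() {
  symbol_map(
    token = c("smn1", "gaa", "oldgaa", "idua", "mut", "sharedalias", "sharedalias"),
    tier = c("current", "current", "previous", "current", "current", "alias", "alias"),
    hgnc_id = c("HGNC:11117", "HGNC:4065", "HGNC:4065", "HGNC:5391",
                "HGNC:7526", "HGNC:11117", "HGNC:4065"),
    symbol = c("SMN1", "GAA", "GAA", "IDUA", "MUT", "SMN1", "GAA")
  )
}

tiny_crosswalk <- function() {
  tibble::tibble(
    token = c("orpha:70", "orpha:365", "pompe disease"),
    mondo_id = c("MONDO:0010679", "MONDO:0009290", "MONDO:0009290")
  )
}

# one-row annotation table builder with every field defaulting to missing
annotation_row <- function(hgnc_id, mondo_id,
                           onset_orphanet = NA_character_,
                           onset_asqm = NA_character_,
                           severity_asqm = NA_integer_,
                           severity_category = NA_character_,
                           penetrance_category = NA_character_,
                           penetrance_fraction = NA_real_,
                           feasible = TRUE,
                           feasibility_reason = NA_character_,
                           treatment_within_2y = NA) {
  tibble::tibble(
    hgnc_id = hgnc_id, mondo_id = mondo_id,
    onset_orphanet = onset_orphanet, onset_asqm = onset_asqm,
    severity_asqm = severity_asqm, severity_category = severity_category,
    penetrance_category = penetrance_category,
    penetrance_fraction = penetrance_fraction,
    feasible = feasible, feasibility_reason = feasibility_reason,
    treatment_within_2y = treatment_within_2y
  )
}

# realize a target criterion-score vector (v, o, s, p) as annotations;
# used by the exhaustive threshold enumeration
realize_scores <- function(v, o, s, p, hgnc_id = "HGNC:1", mondo_id = "MONDO:0000001") {
  validity <- if (v == 2) {
    tibble::tibble(hgnc_id = hgnc_id, mondo_id = mondo_id,
                   submitter = "s1", classification = "Definitive")
  } else if (v == 1) {
    tibble::tibble(hgnc_id = hgnc_id, mondo_id = mondo_id,
                   submitter = "s1", classification = "Moderate")
  } else {
    tibble::tibble(hgnc_id = character(0), mondo_id = character(0),
                   submitter = character(0), classification = character(0))
  }
  ann <- annotation_row(
    hgnc_id, mondo_id,
    onset_orphanet = c("adult", "adolescence", "neonatal")[o + 1],
    severity_asqm = c(0L, 1L, 3L)[s + 1],
    penetrance_category = c("low", "moderate", "high")[p + 1]
  )
  pairs <- tibble::tibble(hgnc_id = hgnc_id, symbol = "G1",
                          mondo_id = mondo_id, provenance = "RxGenes")
  list(pairs = pairs, annotations = ann, validity = validity)
}

# a small decided ledger used by curation tests
tiny_panel <- function(n = 6) {
  cards <- tibble::tibble(
    hgnc_id = sprintf("HGNC:%d", 9000000 + seq_len(n)),
    symbol = sprintf("G%02d", seq_len(n)),
    mondo_id = sprintf("MONDO:%07d", 9100000 + seq_len(n))
  )
  new_panel(cards, version_tag = "test")
}

ledger_row <- function(action, hgnc_id, status,
                       mondo_id = NA_character_, symbol = "GX",
                       reasons = "NOT_TREATABLE_OR_QUESTIONABLE",
                       free_text = NA_character_,
                       references = if (action == "include") "PMID:1" else NA_character_,
                       proposer_role = "consortium_expert",
                       round = 1L, rationale = "test") {
  tibble::tibble(
    action = action, hgnc_id = hgnc_id, symbol = symbol, mondo_id = mondo_id,
    reasons = reasons, free_text = free_text, references = references,
    proposer_role = proposer_role, round = round, status = status,
    rationale = rationale
  )
}
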