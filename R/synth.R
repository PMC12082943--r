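#' Seeded synthetic source bundles
#'
#' Real panel selection draws on external databases (treatability lists,
#' validity curations, onset/severity/penetrance annotations) that cannot
#' be redistributed. The generator emulates their statistical structure --
#' source overlap, categorical distributions, per-annotation missingness,
#' multi-submitter validity records, alias and junk gene tokens -- so the
#' whole pipeline can be exercised end to end with no downloads. Every
#' bundle carries a `truth` table of expected score cards computed by a
#' straight-line oracle that is independent of the rubric module.
#'
#' Synthetic identifiers live in a reserved namespace (`HGNC:9000001` and
#' up, `MONDO:9xxxxxx`) so they can never collide with real genes.
#'
#' @name synth
NULL

SOURCE_NAMES <- c("RxGenes", "GTRx", "RUSP", "NBS_IT", "NBS_DE", "EMA_ORPHAN", "ASQM")

#' Configuration for the synthetic bundle generator
#'
#' Defaults emulate a small treatability corpus: most genes sit in the
#' broad curated sources with minority membership in the narrow national
#' screening lists, validity curations skew Definitive/Strong (the sources
#' are themselves curated for treatability), onset skews paediatric, and
#' penetrance is the most frequently missing annotation.
#'
#' @param n_genes number of genes to simulate.
#' @param p_second_pair probability a gene carries a second disease pair.
#' @param source_membership_probs named per-source membership probability.
#' @param classification_dist named categorical distribution over validity
#'   classifications.
#' @param onset_dist named distribution over onset categories.
#' @param severity_dist named distribution over ASQM severity grades 0-3.
#' @param penetrance_dist named distribution over penetrance categories.
#' @param missingness named per-annotation missing probability (fields
#'   `validity`, `onset`, `severity`, `penetrance`).
#' @param n_submitters maximum validity submitters per pair.
#' @param p_alias_token probability a source record names its gene by alias.
#' @param p_junk_record expected fraction of extra unresolvable records.
#' @param p_infeasible probability a pair fails the feasibility gate.
#' @param treatment_window_probs probabilities for treatment-within-2-years
#'   flag being `TRUE`, `FALSE`, missing.
#' @param n_exclude_proposals,n_include_proposals,p_accept shape of the
#'   generated curation ledger.
#' @param seed integer seed; the bundle is a pure function of the config.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_genes = 60,
                         p_second_pair = 0.15,
                         source_membership_probs = c(
                           RxGenes = 0.42, GTRx = 0.50, RUSP = 0.15,
                           NBS_IT = 0.14, NBS_DE = 0.14, EMA_ORPHAN = 0.10,
                           ASQM = 0.85
                         ),
                         classification_dist = c(
                           "Definitive" = 0.45, "Strong" = 0.25,
                           "Moderate" = 0.15, "Limited" = 0.10,
                           "Animal Model Only" = 0.05
                         ),
                         onset_dist = c(
                           antenatal = 0.05, birth = 0.08, neonatal = 0.20,
                           infancy = 0.25, "birth-to-childhood" = 0.05,
                           childhood = 0.17, adolescence = 0.08,
                           adult = 0.10, elderly = 0.02
                         ),
                         severity_dist = c("0" = 0.05, "1" = 0.35,
                                           "2" = 0.35, "3" = 0.25),
                         penetrance_dist = c(low = 0.08, moderate = 0.32,
                                             high = 0.60),
                         missingness = c(validity = 0.10, onset = 0.15,
                                         severity = 0.20, penetrance = 0.35),
                         n_submitters = 2,
                         p_alias_token = 0.05,
                         p_junk_record = 0.02,
                         p_infeasible = 0.02,
                         treatment_window_probs = c(0.85, 0.05, 0.10),
                         n_exclude_proposals = 3,
                         n_include_proposals = 5,
                         p_accept = 0.8,
                         seed = 1L) {
  cfg <- as.list(environment())
  for (d in list(cfg$classification_dist, cfg$onset_dist, cfg$severity_dist,
                 cfg$penetrance_dist, cfg$treatment_window_probs)) {
    if (abs(sum(d) - 1) > 1e-9) abort("distribution does not sum to 1")
    if (any(d < 0 | d > 1)) abort("probabilities must lie in [0, 1]")
  }
  if (any(cfg$source_membership_probs < 0 | cfg$source_membership_probs > 1) ||
      any(cfg$missingness < 0 | cfg$missingness > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  structure(cfg, class = "synth_config")
}

sample_cat <- function(n, dist) {
  sample(names(dist), n, replace = TRUE, prob = dist)
}

#' Generate a synthetic source bundle
#'
#' @param cfg a [synth_config()].
#' @return a list of class `tp_bundle` with elements `records` (source
#'   records), `symbol_map`, `crosswalk`, `annotations`, `validity`,
#'   `ledger`, `truth` (expected score cards from the independent oracle),
#'   and `config`.
#' @examples
#' b <- generate_bundle(synth_config(n_genes = 10, seed = 42))
#' nrow(b$truth)
#' @export
generate_bundle <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, generate_bundle_impl(cfg))
}

generate_bundle_impl <- function(cfg) {
  n <- cfg$n_genes
  genes <- tibble(
    hgnc_id = sprintf("HGNC:%d", 9000000L + seq_len(n)),
    symbol = sprintf("SYNG%04d", seq_len(n))
  )
  # pairs: every gene one disease, some a second
  second <- stats::runif(n) < cfg$p_second_pair
  gene_idx <- c(seq_len(n), which(second))
  pair_id <- seq_along(gene_idx)
  pairs <- tibble(
    hgnc_id = genes$hgnc_id[gene_idx],
    symbol = genes$symbol[gene_idx],
    mondo_id = sprintf("MONDO:%07d", 9100000L + pair_id)
  )

  # source membership per gene; every gene in at least one source
  member <- sapply(cfg$source_membership_probs, function(p) stats::runif(n) < p)
  member[rowSums(member) == 0, "ASQM"] <- TRUE

  # symbol map: current symbols plus alias entries for every gene
  smap <- bind_rows(
    tibble(token = casefold(genes$symbol), tier = "current",
           hgnc_id = genes$hgnc_id, symbol = genes$symbol),
    tibble(token = casefold(paste0(genes$symbol, "ALT")), tier = "alias",
           hgnc_id = genes$hgnc_id, symbol = genes$symbol)
  )

  # one record per (pair, member source); odd pairs named via ORPHA token
  rec <- purrr::map(seq_len(nrow(pairs)), function(p) {
    g <- gene_idx[[p]]
    srcs <- SOURCE_NAMES[member[g, ]]
    tibble(source_name = srcs,
           gene = genes$symbol[[g]],
           disease = if (p %% 2 == 1) sprintf("ORPHA:%d", 900000L + p)
                     else pairs$mondo_id[[p]])
  })
  records <- bind_rows(rec)
  alias_rows <- stats::runif(nrow(records)) < cfg$p_alias_token
  records$gene[alias_rows] <- paste0(records$gene[alias_rows], "ALT")
  # sprinkle case variation; resolution is case-insensitive
  lower_rows <- seq_len(nrow(records)) %% 13 == 0
  records$gene[lower_rows] <- casefold(records$gene[lower_rows])
  records$filter_note <- NA_character_

  n_junk <- round(cfg$p_junk_record * nrow(records))
  if (n_junk > 0) {
    records <- bind_rows(records, tibble(
      source_name = sample_cat(n_junk, stats::setNames(
        rep(1 / length(SOURCE_NAMES), length(SOURCE_NAMES)), SOURCE_NAMES)),
      gene = sprintf("JUNK%03d", seq_len(n_junk)),
      disease = sprintf("unknown condition %d", seq_len(n_junk)),
      filter_note = NA_character_
    ))
  }

  crosswalk <- tibble(
    token = casefold(sprintf("ORPHA:%d", 900000L + pair_id[pair_id %% 2 == 1])),
    mondo_id = pairs$mondo_id[pair_id %% 2 == 1]
  )

  np <- nrow(pairs)
  # validity: 1..n_submitters assertions, or none at all
  v_missing <- stats::runif(np) < cfg$missingness[["validity"]]
  validity <- bind_rows(purrr::map(which(!v_missing), function(p) {
    k <- sample.int(cfg$n_submitters, 1)
    tibble(hgnc_id = pairs$hgnc_id[[p]], mondo_id = pairs$mondo_id[[p]],
           submitter = sprintf("submitter_%d", seq_len(k)),
           classification = sample_cat(k, cfg$classification_dist))
  }))

  o_missing <- stats::runif(np) < cfg$missingness[["onset"]]
  n_onset_cats <- sample(1:2, np, replace = TRUE)
  onset <- vapply(seq_len(np), function(p) {
    if (o_missing[[p]]) return(NA_character_)
    paste(unique(sample_cat(n_onset_cats[[p]], cfg$onset_dist)), collapse = ";")
  }, character(1))

  s_missing <- stats::runif(np) < cfg$missingness[["severity"]]
  sev <- ifelse(s_missing, NA_integer_,
                as.integer(sample_cat(np, cfg$severity_dist)))

  p_missing <- stats::runif(np) < cfg$missingness[["penetrance"]]
  pen <- ifelse(p_missing, NA_character_, sample_cat(np, cfg$penetrance_dist))

  infeasible <- stats::runif(np) < cfg$p_infeasible
  tw <- sample(c(TRUE, FALSE, NA), np, replace = TRUE,
               prob = cfg$treatment_window_probs)

  annotations <- tibble(
    hgnc_id = pairs$hgnc_id, mondo_id = pairs$mondo_id,
    onset_orphanet = onset, onset_asqm = NA_character_,
    severity_asqm = sev, severity_category = NA_character_,
    penetrance_category = pen, penetrance_fraction = NA_real_,
    feasible = !infeasible,
    feasibility_reason = ifelse(infeasible, "non-mendelian inheritance", NA),
    treatment_within_2y = tw
  )

  pairs$provenance <- vapply(gene_idx, function(g) {
    paste(sort(SOURCE_NAMES[member[g, ]]), collapse = ";")
  }, character(1))

  truth <- oracle_scorecards(pairs, annotations, validity)

  ledger <- generate_ledger(cfg, pairs, truth)

  structure(
    list(records = records, symbol_map = smap, crosswalk = crosswalk,
         pairs = pairs, annotations = annotations, validity = validity,
         ledger = ledger, truth = truth, config = cfg),
    class = "tp_bundle"
  )
}

generate_ledger <- function(cfg, pairs, truth) {
  retained_genes <- unique(truth$hgnc_id[truth$included])
  n_ex <- min(cfg$n_exclude_proposals, length(retained_genes))
  ex_genes <- if (n_ex > 0) sample(retained_genes, n_ex) else character(0)
  taxonomy <- setdiff(REASON_CODES, "OTHER")
  ex <- tibble(
    action = rep("exclude", n_ex),
    hgnc_id = ex_genes,
    symbol = pairs$symbol[match(ex_genes, pairs$hgnc_id)],
    mondo_id = NA_character_,
    reasons = sample(taxonomy, n_ex, replace = TRUE),
    free_text = NA_character_,
    references = NA_character_,
    proposer_role = sample(PROPOSER_ROLES, n_ex, replace = TRUE),
    round = rep(1L, n_ex),
    status = ifelse(stats::runif(n_ex) < cfg$p_accept, "accepted", "rejected"),
    rationale = rep("synthetic exclusion proposal", n_ex)
  )
  n_in <- cfg$n_include_proposals
  inc <- tibble(
    action = rep("include", n_in),
    hgnc_id = sprintf("HGNC:%d", 9500000L + seq_len(n_in)),
    symbol = sprintf("SYNA%03d", seq_len(n_in)),
    mondo_id = sprintf("MONDO:%07d", 9600000L + seq_len(n_in)),
    reasons = rep("OTHER", n_in),
    free_text = rep("expert-proposed addition", n_in),
    references = sprintf("PMID:%d", 31000000L + seq_len(n_in)),
    proposer_role = sample(PROPOSER_ROLES, n_in, replace = TRUE),
    round = rep(1L, n_in),
    status = ifelse(stats::runif(n_in) < cfg$p_accept, "accepted", "rejected"),
    rationale = rep("synthetic inclusion proposal", n_in)
  )
  bind_rows(ex, inc)
}

#' @export
print.tp_bundle <- function(x, ...) {
  cat("<synthetic source bundle> ", dplyr::n_distinct(x$pairs$hgnc_id),
      " genes, ", nrow(x$pairs), " pairs, ", nrow(x$records), " source records\n",
      sep = "")
  invisible(x)
}

#' Independent straight-line score oracle
#'
#' Recomputes the expected score card for every pair directly from the
#' annotation tables using literal rule-by-rule logic under the default
#' rubric (cutoff 7, validity gate on, missing defaults 0/1/1/1). It shares
#' no code with [score_pairs()] and exists so that generated bundles carry
#' a ground truth against which the rubric implementation can be checked.
#'
#' @param pairs pair table with `hgnc_id`, `mondo_id`, `provenance`.
#' @param annotations,validity annotation tables as in [score_pairs()].
#' @return a `tbl_df` shaped like the [score_pairs()] output (without
#'   `notes`; the oracle records `n_missing_defaults` instead).
#' @export
oracle_scorecards <- function(pairs, annotations, validity) {
  early <- c("antenatal", "birth", "neonatal", "infancy",
             "birth-to-childhood", "childhood")
  ord <- c("antenatal", "birth", "neonatal", "infancy", "birth-to-childhood",
           "childhood", "adolescence", "adult", "elderly")
  strength <- c("Definitive", "Strong", "Moderate", "Limited",
                "Animal Model Only", "No Known Disease Relationship",
                "Disputed Evidence", "Refuted Evidence")
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    h <- pairs$hgnc_id[[i]]; m <- pairs$mondo_id[[i]]
    n_miss <- 0L
    cls <- validity$classification[validity$hgnc_id == h & validity$mondo_id == m]
    if (length(cls) == 0) {
      sv <- 0L; gv <- FALSE; n_miss <- n_miss + 1L
    } else {
      best <- strength[[min(match(cls, strength))]]
      sv <- if (best %in% c("Definitive", "Strong")) 2L
            else if (best == "Moderate") 1L else 0L
      gv <- best %in% c("Definitive", "Strong")
    }
    a <- annotations[annotations$hgnc_id == h & annotations$mondo_id == m, ]
    ocats <- character(0)
    if (nrow(a) == 1 && !is.na(a$onset_orphanet) && nzchar(a$onset_orphanet)) {
      ocats <- strsplit(a$onset_orphanet, ";", fixed = TRUE)[[1]]
    }
    if (length(ocats) == 0 && nrow(a) == 1 && !is.na(a$onset_asqm)) {
      ocats <- a$onset_asqm
    }
    if (length(ocats) == 0) {
      so <- 1L; n_miss <- n_miss + 1L
    } else {
      earliest <- ord[[min(match(ocats, ord))]]
      so <- if (earliest %in% early) 2L
            else if (earliest == "adolescence") 1L else 0L
    }
    if (nrow(a) == 1 && !is.na(a$severity_category)) {
      ss <- switch(a$severity_category, not_significant = 0L,
                   spectrum_unpredictable = 1L, significant = 2L)
    } else if (nrow(a) == 1 && !is.na(a$severity_asqm)) {
      ss <- if (a$severity_asqm >= 2) 2L else as.integer(a$severity_asqm)
    } else {
      ss <- 1L; n_miss <- n_miss + 1L
    }
    if (nrow(a) == 1 && !is.na(a$penetrance_category)) {
      sp <- switch(a$penetrance_category, low = 0L, moderate = 1L, high = 2L)
    } else if (nrow(a) == 1 && !is.na(a$penetrance_fraction)) {
      f <- a$penetrance_fraction
      sp <- if (f >= 0.8) 2L else if (f < 0.2) 0L else 1L
    } else {
      sp <- 1L; n_miss <- n_miss + 1L
    }
    gt <- nzchar(pairs$provenance[[i]])
    gf <- !(nrow(a) == 1 && isFALSE(a$feasible))
    total <- sv + so + ss + sp
    out[[i]] <- tibble(
      hgnc_id = h, symbol = pairs$symbol[[i]], mondo_id = m,
      s_validity = sv, s_onset = so, s_severity = ss, s_penetrance = sp,
      gate_treatability = gt, gate_feasibility = gf, gate_validity = gv,
      total = total,
      included = gt && gf && gv && total >= 7,
      n_missing_defaults = n_miss
    )
  }
  arrange(bind_rows(out), .data$hgnc_id, .data$mondo_id)
}

#' Write a bundle to a directory of TSV files with a manifest
#'
#' @param bundle a `tp_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    sources = bundle$records, symbol_map = bundle$symbol_map,
    crosswalk = bundle$crosswalk, annotations = bundle$annotations,
    validity = bundle$validity, ledger = bundle$ledger, truth = bundle$truth
  )
  paths <- character(0)
  for (name in names(files)) {
    if (is.null(files[[name]])) next
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(files[[name]], p)
    paths[name] <- p
  }
  manifest <- list(
    seed = bundle$config$seed,
    n_genes = bundle$config$n_genes,
    checksums = as.list(tools::md5sum(paths))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
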