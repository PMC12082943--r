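#' The four-criterion scoring rubric
#'
#' Each gene-disease pair is scored 0-2 on four criteria -- clinical
#' validity, age of onset, disease severity, and penetrance -- for a maximum
#' total of 8. Treatability and genetic technical feasibility are mandatory
#' gates rather than scored criteria: a pair failing either is excluded
#' outright. Pairs whose total reaches the inclusion cutoff (7 by default)
#' are retained for expert curation. Because each criterion contributes at
#' most 2 points, a cutoff of 7 means any single criterion score of 0 forces
#' exclusion.
#'
#' All category-to-score mappings live in the [rubric_config()] object, so
#' the rubric is fully declarative and can be serialized to YAML.
#'
#' @name rubric
NULL

#' Controlled vocabulary of gene-disease validity classifications
#' @export
VALIDITY_CLASSES <- c(
  "Definitive", "Strong", "Moderate", "Limited",
  "Animal Model Only", "No Known Disease Relationship",
  "Disputed Evidence", "Refuted Evidence"
)

#' Controlled vocabulary of categorical age-of-onset values, earliest first
#' @export
ONSET_CATEGORIES <- c(
  "antenatal", "birth", "neonatal", "infancy", "birth-to-childhood",
  "childhood", "adolescence", "adult", "elderly"
)

#' Controlled vocabulary of direct severity categories
#' @export
SEVERITY_CATEGORIES <- c("not_significant", "spectrum_unpredictable", "significant")

#' Controlled vocabulary of penetrance categories
#' @export
PENETRANCE_CATEGORIES <- c("low", "moderate", "high")

#' Rubric configuration
#'
#' Holds the inclusion cutoff, the missing-data defaults, the gate toggle,
#' and every category-to-score mapping used by the scorers.
#'
#' Missing-data policy: absent onset, severity, and penetrance annotations
#' each default to the middle score of 1 so that a pair is never excluded
#' solely for lack of data on those criteria. Validity is different: it is a
#' strict evidence criterion (a pair must reach Definitive or Strong to be
#' eligible), so a pair with no validity curation at all scores 0.
#'
#' @param cutoff total-score inclusion threshold, in \[0, 8\].
#' @param missing_validity_score,missing_onset_score,missing_severity_score,missing_penetrance_score
#'   scores (each in 0-2) assigned when the corresponding annotation is
#'   entirely missing.
#' @param validity_gate_enabled when `TRUE` a pair must additionally have a
#'   highest validity classification of Definitive or Strong to be included.
#' @param penetrance_high_boundary symptomatic fraction at or above which a
#'   numeric penetrance annotation is treated as high (inclusive).
#' @param penetrance_low_boundary fraction strictly below which a numeric
#'   penetrance annotation is treated as low.
#' @return a list of class `rubric_config`.
#' @examples
#' cfg <- rubric_config()
#' cfg$cutoff
#' @export
rubric_config <- function(cutoff = 7L,
                          missing_validity_score = 0L,
                          missing_onset_score = 1L,
                          missing_severity_score = 1L,
                          missing_penetrance_score = 1L,
                          validity_gate_enabled = TRUE,
                          penetrance_high_boundary = 0.80,
                          penetrance_low_boundary = 0.20) {
  cfg <- list(
    cutoff = as.integer(cutoff),
    missing_validity_score = as.integer(missing_validity_score),
    missing_onset_score = as.integer(missing_onset_score),
    missing_severity_score = as.integer(missing_severity_score),
    missing_penetrance_score = as.integer(missing_penetrance_score),
    validity_gate_enabled = isTRUE(validity_gate_enabled),
    penetrance_high_boundary = penetrance_high_boundary,
    penetrance_low_boundary = penetrance_low_boundary,
    # score mappings; data, not code, so the rubric is declarative
    validity_scores = c(
      "Definitive" = 2L, "Strong" = 2L, "Moderate" = 1L, "Limited" = 0L,
      "Animal Model Only" = 0L, "No Known Disease Relationship" = 0L,
      "Disputed Evidence" = 0L, "Refuted Evidence" = 0L
    ),
    # ordering used for "highest scoring curation"; strongest first
    validity_order = VALIDITY_CLASSES,
    validity_gate_classes = c("Definitive", "Strong"),
    onset_order = ONSET_CATEGORIES,
    onset_scores = c(
      "antenatal" = 2L, "birth" = 2L, "neonatal" = 2L, "infancy" = 2L,
      "birth-to-childhood" = 2L, "childhood" = 2L,
      "adolescence" = 1L, "adult" = 0L, "elderly" = 0L
    ),
    severity_asqm_scores = c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 2L),
    severity_category_scores = c(
      "not_significant" = 0L, "spectrum_unpredictable" = 1L, "significant" = 2L
    ),
    penetrance_scores = c("low" = 0L, "moderate" = 1L, "high" = 2L)
  )
  validate_rubric_config(cfg)
}

validate_rubric_config <- function(cfg) {
  stopifnot(
    cfg$cutoff >= 0L, cfg$cutoff <= 8L,
    all(c(cfg$missing_validity_score, cfg$missing_onset_score,
          cfg$missing_severity_score, cfg$missing_penetrance_score) %in% 0:2),
    cfg$penetrance_low_boundary < cfg$penetrance_high_boundary
  )
  structure(cfg, class = "rubric_config")
}

#' @export
print.rubric_config <- function(x, ...) {
  cat("<rubric config> cutoff ", x$cutoff, "/8; validity gate ",
      if (x$validity_gate_enabled) "on" else "off",
      "; missing defaults V=", x$missing_validity_score,
      " O=", x$missing_onset_score, " S=", x$missing_severity_score,
      " P=", x$missing_penetrance_score, "\n", sep = "")
  invisible(x)
}

#' Read or write a rubric configuration as YAML
#'
#' Only fields present in the file override the defaults, so a config file
#' can state just `cutoff: 8`.
#'
#' @param path YAML file path.
#' @param cfg a `rubric_config`.
#' @name rubric_config_io
#' @export
read_rubric_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- unclass(rubric_config())
  scalar <- intersect(names(raw), c(
    "cutoff", "missing_validity_score", "missing_onset_score",
    "missing_severity_score", "missing_penetrance_score",
    "validity_gate_enabled", "penetrance_high_boundary",
    "penetrance_low_boundary"
  ))
  cfg[scalar] <- raw[scalar]
  for (tbl in c("validity_scores", "onset_scores", "severity_asqm_scores",
                "severity_category_scores", "penetrance_scores")) {
    if (!is.null(raw[[tbl]])) {
      v <- unlist(raw[[tbl]])
      cfg[[tbl]] <- stats::setNames(as.integer(v), names(v))
    }
  }
  cfg$cutoff <- as.integer(cfg$cutoff)
  validate_rubric_config(cfg)
}

#' @rdname rubric_config_io
#' @export
write_rubric_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x) {
    if (!is.null(names(x)) && length(x) > 1) as.list(x) else x
  }), path)
  invisible(path)
}

check_vocab <- function(x, vocab, what) {
  bad <- setdiff(x, vocab)
  if (length(bad) > 0) {
    abort(paste0("unknown ", what, ": ", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

highest_validity <- function(classifications, cfg) {
  check_vocab(classifications, cfg$validity_order, "validity classification")
  cfg$validity_order[min(match(classifications, cfg$validity_order))]
}

#' Score clinical validity for one gene-disease pair
#'
#' Assertions from multiple submitters are combined by taking the highest
#' scoring curation (Definitive strongest). Definitive and Strong score 2,
#' Moderate scores 1, and all weaker classifications score 0. A pair with no
#' curation at all receives the missing-validity default (0: validity is a
#' strict evidence criterion).
#'
#' @param classifications character vector of classifications for one pair
#'   (one per submitter); length 0 or `NULL` means no curation exists.
#' @param cfg a [rubric_config()].
#' @return integer score in 0-2.
#' @examples
#' score_validity(c("Strong", "Moderate"))
#' score_validity(character(0))
#' @export
score_validity <- function(classifications, cfg = rubric_config()) {
  classifications <- classifications[!is.na(classifications)]
  if (length(classifications) == 0) {
    return(cfg$missing_validity_score)
  }
  unname(cfg$validity_scores[[highest_validity(classifications, cfg)]])
}

#' Clinical validity eligibility gate
#'
#' `TRUE` iff the highest classification across submitters is Definitive or
#' Strong. Consulted only when `validity_gate_enabled` is set in the config.
#'
#' @inheritParams score_validity
#' @return logical.
#' @export
validity_gate <- function(classifications, cfg = rubric_config()) {
  classifications <- classifications[!is.na(classifications)]
  if (length(classifications) == 0) {
    return(FALSE)
  }
  highest_validity(classifications, cfg) %in% cfg$validity_gate_classes
}

#' Score age of onset for one gene-disease pair
#'
#' The effective category is the earliest of the Orphanet onset categories;
#' when Orphanet carries no data the ASQM onset category is used as
#' fallback. Early-childhood onset (antenatal through childhood) scores 2,
#' adolescence 1, adult or elderly onset 0. With no data in either resource
#' the missing-onset default of 1 applies.
#'
#' @param orphanet character vector of Orphanet onset categories (possibly
#'   empty).
#' @param asqm a single ASQM onset category or `NA`.
#' @inheritParams score_validity
#' @return integer score in 0-2.
#' @examples
#' score_onset(c("adult", "neonatal"))  # earliest wins
#' score_onset(character(0))            # missing -> 1
#' @export
score_onset <- function(orphanet = character(0), asqm = NA_character_,
                        cfg = rubric_config()) {
  orphanet <- orphanet[!is.na(orphanet)]
  check_vocab(orphanet, cfg$onset_order, "onset category")
  if (length(orphanet) > 0) {
    eff <- cfg$onset_order[min(match(orphanet, cfg$onset_order))]
    return(unname(cfg$onset_scores[[eff]]))
  }
  if (!is.na(asqm)) {
    check_vocab(asqm, cfg$onset_order, "onset category")
    return(unname(cfg$onset_scores[[asqm]]))
  }
  cfg$missing_onset_score
}

#' Score disease severity for one gene-disease pair
#'
#' A direct severity category takes precedence when present
#' (not_significant 0, spectrum_unpredictable 1, significant 2); otherwise
#' the ASQM severity grade is mapped 0->0, 1->1, 2->2, 3->2 (both ASQM
#' grades 2 and 3 describe diseases most likely to cause significant health
#' problems). Both missing gives the default of 1.
#'
#' @param asqm ASQM severity grade in 0-3, or `NA`.
#' @param category direct severity category, or `NA`.
#' @inheritParams score_validity
#' @return integer score in 0-2.
#' @export
score_severity <- function(asqm = NA, category = NA_character_,
                           cfg = rubric_config()) {
  if (!is.na(category)) {
    check_vocab(category, names(cfg$severity_category_scores), "severity category")
    return(unname(cfg$severity_category_scores[[category]]))
  }
  if (!is.na(asqm)) {
    key <- as.character(as.integer(asqm))
    if (!key %in% names(cfg$severity_asqm_scores)) {
      abort(paste0("ASQM severity grade out of range: ", asqm))
    }
    return(unname(cfg$severity_asqm_scores[[key]]))
  }
  cfg$missing_severity_score
}

#' Score penetrance for one gene-disease pair
#'
#' Categories low / moderate / high score 0 / 1 / 2. When only a numeric
#' symptomatic fraction is available the category is derived from it:
#' fraction >= 0.80 is high (boundary inclusive), < 0.20 low, otherwise
#' moderate. With no data the default of 1 applies, so a pair is never
#' excluded solely for lack of penetrance data.
#'
#' @param category penetrance category, or `NA`.
#' @param fraction symptomatic fraction in \[0, 1\], or `NA`.
#' @inheritParams score_validity
#' @return integer score in 0-2.
#' @export
score_penetrance <- function(category = NA_character_, fraction = NA_real_,
                             cfg = rubric_config()) {
  if (is.na(category) && !is.na(fraction)) {
    if (fraction < 0 || fraction > 1) {
      abort(paste0("penetrance fraction outside [0, 1]: ", fraction))
    }
    category <- if (fraction >= cfg$penetrance_high_boundary) {
      "high"
    } else if (fraction < cfg$penetrance_low_boundary) {
      "low"
    } else {
      "moderate"
    }
  }
  if (is.na(category)) {
    return(cfg$missing_penetrance_score)
  }
  check_vocab(category, names(cfg$penetrance_scores), "penetrance category")
  unname(cfg$penetrance_scores[[category]])
}

#' Treatability gate
#'
#' `TRUE` iff the pair's provenance contains at least one treatability
#' source. All bundled source lists are treatability-qualifying (their
#' source-specific filters are applied at ingestion), so in practice this
#' gate checks that provenance is non-empty.
#'
#' @param provenance character vector of source names, or a single
#'   ";"-joined provenance string.
#' @return logical.
#' @export
treatability_gate <- function(provenance) {
  if (length(provenance) == 1 && grepl(";", provenance)) {
    provenance <- strsplit(provenance, ";", fixed = TRUE)[[1]]
  }
  provenance <- provenance[!is.na(provenance) & nzchar(provenance)]
  if (length(provenance) == 0) {
    abort("gene-disease pair with empty provenance: invariant violation")
  }
  TRUE
}

#' Score a table of annotated gene-disease pairs
#'
#' Applies the four criterion scorers and the two (optionally three) gates
#' to every pair and assembles score cards. The annotation table holds one
#' row per pair; validity assertions live in a separate long table because a
#' pair can carry assertions from several submitters.
#'
#' @param pairs merged pair table (`hgnc_id`, `symbol`, `mondo_id`,
#'   `provenance`, ...), as from [merge_sources()].
#' @param annotations one row per pair with columns `hgnc_id`, `mondo_id`,
#'   `onset_orphanet` (";"-joined categories or `NA`), `onset_asqm`,
#'   `severity_asqm`, `severity_category`, `penetrance_category`,
#'   `penetrance_fraction`, `feasible`, `feasibility_reason`,
#'   `treatment_within_2y`. Pairs absent from the table are treated as
#'   having every annotation missing and as feasible.
#' @param validity long table with columns `hgnc_id`, `mondo_id`,
#'   `submitter`, `classification`.
#' @param cfg a [rubric_config()].
#' @return a score card `tbl_df`: one row per pair with the four criterion
#'   scores, the three gates, `total`, `included`, and a `notes` column
#'   recording every missing-data default that was applied.
#' @export
score_pairs <- function(pairs, annotations = NULL, validity = NULL,
                        cfg = rubric_config()) {
  stopifnot(all(c("hgnc_id", "mondo_id") %in% names(pairs)))
  ann <- normalize_annotations(pairs, annotations)
  vkey <- paste(pairs$hgnc_id, pairs$mondo_id)
  vlist <- split_validity(validity, vkey)

  n <- nrow(pairs)
  s_validity <- integer(n); s_onset <- integer(n)
  s_severity <- integer(n); s_penetrance <- integer(n)
  gate_validity <- logical(n); notes <- character(n)

  for (i in seq_len(n)) {
    cls <- vlist[[vkey[[i]]]]
    s_validity[[i]] <- score_validity(cls, cfg)
    gate_validity[[i]] <- validity_gate(cls, cfg)
    orph <- split_categories(ann$onset_orphanet[[i]])
    s_onset[[i]] <- score_onset(orph, ann$onset_asqm[[i]], cfg)
    s_severity[[i]] <- score_severity(ann$severity_asqm[[i]],
                                      ann$severity_category[[i]], cfg)
    s_penetrance[[i]] <- score_penetrance(ann$penetrance_category[[i]],
                                          ann$penetrance_fraction[[i]], cfg)
    miss <- c(
      if (length(cls) == 0) "validity:missing_default",
      if (length(orph) == 0 && is.na(ann$onset_asqm[[i]])) "onset:missing_default",
      if (is.na(ann$severity_asqm[[i]]) && is.na(ann$severity_category[[i]]))
        "severity:missing_default",
      if (is.na(ann$penetrance_category[[i]]) && is.na(ann$penetrance_fraction[[i]]))
        "penetrance:missing_default"
    )
    notes[[i]] <- paste(miss, collapse = ";")
  }

  gate_treatability <- vapply(pairs$provenance, treatability_gate, logical(1),
                              USE.NAMES = FALSE)
  gate_feasibility <- !vapply(ann$feasible, isFALSE, logical(1))
  total <- s_validity + s_onset + s_severity + s_penetrance
  gates_ok <- gate_treatability & gate_feasibility &
    (if (cfg$validity_gate_enabled) gate_validity else TRUE)

  tibble(
    hgnc_id = pairs$hgnc_id,
    symbol = if ("symbol" %in% names(pairs)) pairs$symbol else NA_character_,
    mondo_id = pairs$mondo_id,
    s_validity = s_validity, s_onset = s_onset,
    s_severity = s_severity, s_penetrance = s_penetrance,
    gate_treatability = gate_treatability,
    gate_feasibility = gate_feasibility,
    gate_validity = gate_validity,
    total = total,
    included = gates_ok & total >= cfg$cutoff,
    notes = notes
  ) %>%
    arrange(.data$hgnc_id, .data$mondo_id)
}

split_categories <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  strsplit(x, ";", fixed = TRUE)[[1]]
}

split_validity <- function(validity, keys) {
  empty <- stats::setNames(rep(list(character(0)), length(unique(keys))), unique(keys))
  if (is.null(validity) || nrow(validity) == 0) return(empty)
  got <- split(validity$classification, paste(validity$hgnc_id, validity$mondo_id))
  empty[names(got)[names(got) %in% names(empty)]] <-
    got[names(got) %in% names(empty)]
  empty
}

normalize_annotations <- function(pairs, annotations) {
  template <- tibble(
    hgnc_id = pairs$hgnc_id, mondo_id = pairs$mondo_id,
    onset_orphanet = NA_character_, onset_asqm = NA_character_,
    severity_asqm = NA_integer_, severity_category = NA_character_,
    penetrance_category = NA_character_, penetrance_fraction = NA_real_,
    feasible = TRUE, feasibility_reason = NA_character_,
    treatment_within_2y = NA
  )
  if (is.null(annotations) || nrow(annotations) == 0) return(template)
  ann <- as_tibble(annotations)
  for (col in setdiff(names(template), names(ann))) {
    ann[[col]] <- template[[col]][seq_len(nrow(ann))]
  }
  dup <- duplicated(ann[, c("hgnc_id", "mondo_id")])
  if (any(dup)) abort("annotation table has duplicate (hgnc_id, mondo_id) rows")
  out <- left_join(template[, c("hgnc_id", "mondo_id")], ann,
                   by = c("hgnc_id", "mondo_id"))
  out$feasible[is.na(out$feasible)] <- TRUE
  out
}

#' Partition score cards at the inclusion threshold
#'
#' @param cards score cards from [score_pairs()].
#' @param cfg a [rubric_config()] (unused beyond symmetry; the `included`
#'   decision is already on the cards).
#' @return list with `retained` and `excluded` card tables, each ordered by
#'   (`hgnc_id`, `mondo_id`), plus `retained_genes`: the distinct HGNC ids
#'   with at least one retained pair.
#' @export
apply_threshold <- function(cards, cfg = rubric_config()) {
  retained <- arrange(filter(cards, .data$included), .data$hgnc_id, .data$mondo_id)
  excluded <- arrange(filter(cards, !.data$included), .data$hgnc_id, .data$mondo_id)
  list(
    retained = retained,
    excluded = excluded,
    retained_genes = unique(retained$hgnc_id)
  )
}

#' Write score cards to TSV
#'
#' @param cards score cards.
#' @param path output path.
#' @export
write_scorecards <- function(cards, path) {
  readr::write_tsv(cards, path)
  invisible(path)
}

#' @rdname write_scorecards
#' @export
read_scorecards <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    hgnc_id = readr::col_character(), symbol = readr::col_character(),
    mondo_id = readr::col_character(), notes = readr::col_character(),
    gate_treatability = readr::col_logical(),
    gate_feasibility = readr::col_logical(),
    gate_validity = readr::col_logical(),
    included = readr::col_logical(),
    .default = readr::col_integer()
  ))
}
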