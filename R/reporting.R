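#' Result reports: score distributions, selection flow, panel composition
#' @name reporting
NULL

#' Controlled vocabulary of disorder categories for panel composition
#' @export
DISORDER_CATEGORIES <- c(
  "blood_coagulation", "cardiological", "endocrinological", "immunological",
  "kidney", "metabolic", "neuro", "syndromic", "other"
)

#' Distribution of criterion scores
#'
#' Tabulates, for each of the four criteria, how many units scored 0, 1,
#' and 2. At pair level every score card is a unit; at gene level each
#' gene is represented by its best-scoring pair (ties broken by MONDO id),
#' so row sums equal the number of genes.
#'
#' @param cards score cards from [score_pairs()].
#' @param level `"pair"` or `"gene"`.
#' @return a `tbl_df` with columns `criterion`, `score_0`, `score_1`,
#'   `score_2`.
#' @export
score_distribution <- function(cards, level = c("pair", "gene")) {
  level <- match.arg(level)
  if (level == "gene" && nrow(cards) > 0) {
    cards <- cards %>%
      arrange(.data$hgnc_id, dplyr::desc(.data$total), .data$mondo_id) %>%
      distinct(.data$hgnc_id, .keep_all = TRUE)
  }
  crit <- c(validity = "s_validity", onset = "s_onset",
            severity = "s_severity", penetrance = "s_penetrance")
  rows <- purrr::imap(crit, function(col, name) {
    counts <- table(factor(cards[[col]], levels = 0:2))
    tibble(criterion = name, score_0 = as.integer(counts[["0"]]),
           score_1 = as.integer(counts[["1"]]), score_2 = as.integer(counts[["2"]]))
  })
  bind_rows(rows)
}

#' Selection flow counts
#'
#' Assembles the flow of genes through the pipeline -- initial list, score
#' threshold, curation exclusions and additions -- and verifies the two
#' accounting identities that tie the counts together:
#' `retained = initial - excluded_by_score` and
#' `final = retained - curation_excluded + curation_added`.
#'
#' @param initial_genes,excluded_by_score,retained_after_threshold,curation_excluded,curation_added
#'   non-negative integer counts; `retained_after_threshold` may be omitted
#'   and is then derived.
#' @param final_genes observed final count; derived when omitted.
#' @return a list of class `tp_flow` with the six counts.
#' @examples
#' flow_report(484, 265, curation_excluded = 34, curation_added = 60)
#' @export
flow_report <- function(initial_genes, excluded_by_score,
                        retained_after_threshold = NULL,
                        curation_excluded = 0L, curation_added = 0L,
                        final_genes = NULL) {
  if (is.null(retained_after_threshold)) {
    retained_after_threshold <- initial_genes - excluded_by_score
  }
  if (is.null(final_genes)) {
    final_genes <- retained_after_threshold - curation_excluded + curation_added
  }
  counts <- c(initial_genes, excluded_by_score, retained_after_threshold,
              curation_excluded, curation_added, final_genes)
  if (any(counts < 0)) abort("flow counts must be non-negative")
  if (retained_after_threshold != initial_genes - excluded_by_score) {
    abort("inconsistent flow: retained_after_threshold != initial_genes - excluded_by_score")
  }
  if (final_genes != retained_after_threshold - curation_excluded + curation_added) {
    abort("inconsistent flow: final_genes != retained - curation_excluded + curation_added")
  }
  structure(
    list(initial_genes = as.integer(initial_genes),
         excluded_by_score = as.integer(excluded_by_score),
         retained_after_threshold = as.integer(retained_after_threshold),
         curation_excluded = as.integer(curation_excluded),
         curation_added = as.integer(curation_added),
         final_genes = as.integer(final_genes)),
    class = "tp_flow"
  )
}

#' @export
print.tp_flow <- function(x, ...) {
  cat("<selection flow> ", x$initial_genes, " initial -> -", x$excluded_by_score,
      " by score -> ", x$retained_after_threshold, " -> -", x$curation_excluded,
      " / +", x$curation_added, " by curation -> ", x$final_genes, " final\n",
      sep = "")
  invisible(x)
}

#' Flow counts from pipeline objects
#'
#' Convenience wrapper deriving the [flow_report()] inputs from the score
#' cards and the post-threshold and final panels.
#'
#' @param cards all score cards (retained and excluded).
#' @param post_threshold,final the corresponding `tp_panel` objects.
#' @return a `tp_flow`.
#' @export
flow_from_run <- function(cards, post_threshold, final) {
  initial <- dplyr::n_distinct(cards$hgnc_id)
  retained <- panel_size(post_threshold)
  excluded_genes <- setdiff(post_threshold$genes$hgnc_id, final$genes$hgnc_id)
  added_genes <- setdiff(final$genes$hgnc_id, post_threshold$genes$hgnc_id)
  flow_report(
    initial_genes = initial,
    excluded_by_score = initial - retained,
    retained_after_threshold = retained,
    curation_excluded = length(excluded_genes),
    curation_added = length(added_genes),
    final_genes = panel_size(final)
  )
}

#' Panel composition by disorder category
#'
#' Disorder category is an expert-assigned input annotation, not inferred.
#' Panel genes missing from the category table fall into `"other"` and are
#' reported via a message.
#'
#' @param panel a `tp_panel`.
#' @param categories a `tbl_df` with columns `hgnc_id`, `category` (values
#'   from [DISORDER_CATEGORIES]).
#' @return a `tbl_df` with one row per category (all nine always present)
#'   plus a final `total` attribute equal to the panel size; columns
#'   `category`, `n_genes`.
#' @export
composition_report <- function(panel, categories) {
  check_vocab(stats::na.omit(categories$category), DISORDER_CATEGORIES,
              "disorder category")
  cat_of <- categories$category[match(panel$genes$hgnc_id, categories$hgnc_id)]
  n_uncat <- sum(is.na(cat_of))
  if (n_uncat > 0) {
    inform(paste0(n_uncat, " panel gene(s) without a disorder category; ",
                  "counted as 'other'"))
    cat_of[is.na(cat_of)] <- "other"
  }
  counts <- table(factor(cat_of, levels = DISORDER_CATEGORIES))
  out <- tibble(category = DISORDER_CATEGORIES, n_genes = as.integer(counts))
  attr(out, "total") <- nrow(panel$genes)
  out
}

#' Export a report table as TSV or JSON with stable formatting
#'
#' JSON is written with keys in column order, UTF-8, LF line endings, so
#' repeated exports of the same table are byte-identical.
#'
#' @param report a `tbl_df` (e.g. from [score_distribution()] or
#'   [composition_report()]) or a `tp_flow`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (inherits(report, "tp_flow")) report <- as_tibble(unclass(report))
  if (format == "tsv") {
    readr::write_tsv(report, path)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }
  invisible(path)
}

#' Export the final panel gene table
#'
#' @param panel a `tp_panel`.
#' @param pairs optional merged pair table supplying `mondo_id`,
#'   `disease_label` and `provenance` per gene.
#' @param categories optional category table (`hgnc_id`, `category`).
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return the exported table, invisibly.
#' @export
export_panel <- function(panel, path, pairs = NULL, categories = NULL,
                         format = c("tsv", "json")) {
  format <- match.arg(format)
  out <- left_join(panel$pairs, panel$genes, by = "hgnc_id")
  if (!is.null(pairs)) {
    out <- left_join(out, pairs[, c("hgnc_id", "mondo_id", "disease_label", "provenance")],
                     by = c("hgnc_id", "mondo_id"))
  }
  if (!is.null(categories)) {
    out$category <- categories$category[match(out$hgnc_id, categories$hgnc_id)]
  }
  out <- arrange(out, .data$hgnc_id, .data$mondo_id)
  if (format == "tsv") {
    readr::write_tsv(out, path)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                         na = "null", pretty = TRUE, digits = NA)
  }
  invisible(out)
}
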