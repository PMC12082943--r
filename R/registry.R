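#' Identifier harmonization and source merging
#'
#' Gene panels for newborn screening are assembled from several independently
#' curated source lists, each naming genes and diseases in its own dialect.
#' The registry layer resolves raw gene tokens onto stable HGNC identifiers,
#' maps disease tokens onto MONDO accessions, and merges everything into a
#' deduplicated table of gene-disease pairs that remembers which sources
#' contributed each pair. Nothing is dropped silently: tokens that cannot be
#' resolved are collected into an exceptions report for human review.
#'
#' @name registry
NULL

#' Sentinel used for diseases that cannot be mapped to a MONDO accession
#' @export
UNMAPPED <- "UNMAPPED"

#' Test whether strings are well-formed HGNC or MONDO accessions
#'
#' @param x character vector.
#' @return logical vector.
#' @examples
#' is_hgnc_id(c("HGNC:11117", "hgnc:1", "SMN1"))
#' is_mondo_id("MONDO:0010679")
#' @export
is_hgnc_id <- function(x) grepl("^HGNC:[0-9]+$", x)

#' @rdname is_hgnc_id
#' @export
is_mondo_id <- function(x) grepl("^MONDO:[0-9]{7}$", x)

symbol_map_tiers <- c("current", "previous", "alias")

#' Construct or read a gene symbol map
#'
#' A symbol map relates raw gene tokens (approved symbols, previous symbols,
#' and aliases, matched case-insensitively) to HGNC identifiers. Current-tier
#' entries must be one-to-one; only the alias tier may be ambiguous, and
#' ambiguous aliases are never silently resolved.
#'
#' @param token,tier,hgnc_id,symbol character vectors of equal length.
#' @return a `tbl_df` with columns `token`, `tier`, `hgnc_id`, `symbol`.
#' @export
symbol_map <- function(token, tier, hgnc_id, symbol) {
  map <- tibble(
    token = casefold(as.character(token)),
    tier = as.character(tier),
    hgnc_id = as.character(hgnc_id),
    symbol = toupper(as.character(symbol))
  )
  validate_symbol_map(map)
}

validate_symbol_map <- function(map) {
  stopifnot(all(c("token", "tier", "hgnc_id", "symbol") %in% names(map)))
  bad_tier <- setdiff(unique(map$tier), symbol_map_tiers)
  if (length(bad_tier) > 0) {
    abort(paste0("unknown symbol map tier(s): ", paste(bad_tier, collapse = ", ")))
  }
  bad_id <- map$hgnc_id[!is_hgnc_id(map$hgnc_id)]
  if (length(bad_id) > 0) {
    abort(paste0("malformed HGNC id(s) in symbol map: ", paste(unique(bad_id), collapse = ", ")))
  }
  cur <- map[map$tier == "current", ]
  dup <- cur$token[duplicated(cur$token)]
  if (length(dup) > 0) {
    abort(paste0("current-tier token maps to multiple HGNC ids: ", paste(unique(dup), collapse = ", ")))
  }
  map
}

#' @param path path to a TSV with columns `token`, `tier`, `hgnc_id`, `symbol`.
#' @rdname symbol_map
#' @export
read_symbol_map <- function(path) {
  map <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  map$token <- casefold(map$token)
  map$symbol <- toupper(map$symbol)
  validate_symbol_map(map)
}

#' Read a disease crosswalk table
#'
#' The crosswalk maps raw disease tokens (Orphanet or OMIM accessions, MONDO
#' accessions, or free-text labels) to MONDO identifiers. Well-formed MONDO
#' tokens pass through even when absent from the crosswalk.
#'
#' @param path path to a TSV with columns `token`, `mondo_id`.
#' @return a `tbl_df` with columns `token` (case-folded) and `mondo_id`.
#' @export
read_crosswalk <- function(path) {
  cw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  stopifnot(all(c("token", "mondo_id") %in% names(cw)))
  cw$token <- casefold(cw$token)
  bad <- cw$mondo_id[!is_mondo_id(cw$mondo_id)]
  if (length(bad) > 0) {
    abort(paste0("malformed MONDO id(s) in crosswalk: ", paste(unique(bad), collapse = ", ")))
  }
  cw
}

#' Resolve a raw gene token to an HGNC identifier
#'
#' Resolution is case-insensitive with tier precedence current > previous >
#' alias. A token matching two or more HGNC ids at its best tier is returned
#' as unresolved (reason `"ambiguous alias"`) rather than guessed: a false
#' gene identity is worse than a flagged dropout in a screening panel.
#'
#' @param raw_token a single gene token.
#' @param map a symbol map (see [symbol_map()]).
#' @return a list with elements `hgnc_id` and `symbol`, or an object of class
#'   `tp_unresolved` carrying `token` and `reason` (`"no match"` or
#'   `"ambiguous alias"`).
#' @examples
#' map <- symbol_map("smn1", "current", "HGNC:11117", "SMN1")
#' resolve_gene("SMN1", map)
#' resolve_gene("NOSUCH", map)
#' @export
resolve_gene <- function(raw_token, map) {
  stopifnot(length(raw_token) == 1, nrow(map) > 0)
  hits <- map[map$token == casefold(raw_token), ]
  if (nrow(hits) == 0) {
    return(unresolved(raw_token, "no match"))
  }
  for (tier in symbol_map_tiers) {
    th <- hits[hits$tier == tier, ]
    if (nrow(th) == 0) next
    ids <- unique(th$hgnc_id)
    if (length(ids) > 1) {
      return(unresolved(raw_token, "ambiguous alias"))
    }
    return(list(hgnc_id = ids, symbol = th$symbol[match(ids, th$hgnc_id)]))
  }
}

unresolved <- function(token, reason) {
  structure(list(token = token, reason = reason), class = "tp_unresolved")
}

#' @export
print.tp_unresolved <- function(x, ...) {
  cat("<unresolved gene token> ", x$token, " (", x$reason, ")\n", sep = "")
  invisible(x)
}

#' Resolve a raw disease token to a MONDO identifier
#'
#' Well-formed `MONDO:` accessions pass through unchanged; other tokens are
#' looked up (case-insensitively) in the crosswalk. Tokens with no mapping
#' are retained under the [UNMAPPED] sentinel with the raw label preserved,
#' so that records survive harmonization even when disease-level data are
#' missing.
#'
#' @param raw_token a single disease token.
#' @param crosswalk a crosswalk table (see [read_crosswalk()]).
#' @return a list with elements `mondo_id` and `label`.
#' @export
resolve_disease <- function(raw_token, crosswalk) {
  stopifnot(length(raw_token) == 1)
  if (is.na(raw_token) || !nzchar(trimws(raw_token))) {
    return(list(mondo_id = UNMAPPED, label = "unspecified disease"))
  }
  tok <- trimws(raw_token)
  if (is_mondo_id(tok)) {
    return(list(mondo_id = tok, label = tok))
  }
  hit <- crosswalk$mondo_id[crosswalk$token == casefold(tok)]
  if (length(hit) >= 1) {
    return(list(mondo_id = hit[[1]], label = tok))
  }
  list(mondo_id = UNMAPPED, label = tok)
}

#' Read source tables of raw gene-disease records
#'
#' @param paths one or more TSV/CSV paths; each file needs columns
#'   `source_name`, `gene`, `disease` and may carry `filter_note` recording
#'   the source-specific filter applied at ingestion (e.g. "Group A
#'   category").
#' @return a `tbl_df` of source records.
#' @export
read_source_tables <- function(paths) {
  recs <- purrr::map(paths, function(p) {
    reader <- if (grepl("\\.csv$", p)) readr::read_csv else readr::read_tsv
    x <- reader(p, col_types = readr::cols(.default = readr::col_character()))
    stopifnot(all(c("source_name", "gene", "disease") %in% names(x)))
    if (!"filter_note" %in% names(x)) x$filter_note <- NA_character_
    x[, c("source_name", "gene", "disease", "filter_note")]
  })
  bind_rows(recs)
}

#' Merge source records into deduplicated gene-disease pairs
#'
#' Resolvable records are unioned and keyed by (HGNC id, MONDO id); the
#' provenance of each pair is the set of contributing sources. Records whose
#' gene token cannot be resolved go to the exceptions report. Two diseases
#' both unmapped to MONDO are treated as the same disease only if their
#' labels match case-insensitively.
#'
#' @param records a `tbl_df` of source records (`source_name`, `gene`,
#'   `disease`, optional `filter_note`).
#' @param map a symbol map.
#' @param crosswalk a disease crosswalk.
#' @return a list of class `tp_merge` with elements
#'   \describe{
#'     \item{pairs}{`tbl_df` with `hgnc_id`, `symbol`, `mondo_id`,
#'       `disease_label`, `provenance` (";"-joined sorted source names).}
#'     \item{exceptions}{`tbl_df` with `raw_gene`, `raw_disease`,
#'       `source_name`, `reason`.}
#'   }
#' @export
merge_sources <- function(records, map, crosswalk) {
  if (is.null(records) || nrow(records) == 0) {
    abort("no source records")
  }
  stopifnot(all(nzchar(records$source_name)), all(nzchar(records$gene)))
  records <- distinct(records, .data$source_name, .data$gene, .data$disease,
                      .keep_all = TRUE)

  genes <- purrr::map(records$gene, resolve_gene, map = map)
  ok <- !map_lgl(genes, inherits, what = "tp_unresolved")

  exceptions <- tibble(
    raw_gene = records$gene[!ok],
    raw_disease = records$disease[!ok],
    source_name = records$source_name[!ok],
    reason = map_chr(genes[!ok], "reason")
  )

  kept <- records[ok, ]
  diseases <- purrr::map(kept$disease, resolve_disease, crosswalk = crosswalk)
  resolved <- tibble(
    hgnc_id = map_chr(genes[ok], "hgnc_id"),
    symbol = map_chr(genes[ok], "symbol"),
    mondo_id = map_chr(diseases, "mondo_id"),
    disease_label = map_chr(diseases, "label"),
    source_name = kept$source_name
  )
  # unmapped diseases are distinguished by label, mapped ones by accession
  resolved$pair_key <- ifelse(
    resolved$mondo_id == UNMAPPED,
    paste0(UNMAPPED, "|", casefold(resolved$disease_label)),
    resolved$mondo_id
  )
  pairs <- resolved %>%
    group_by(.data$hgnc_id, .data$pair_key) %>%
    summarise(
      symbol = .data$symbol[[1]],
      mondo_id = .data$mondo_id[[1]],
      disease_label = sort(.data$disease_label)[[1]],
      provenance = paste(sort(unique(.data$source_name)), collapse = ";"),
      .groups = "drop"
    ) %>%
    select("hgnc_id", "symbol", "mondo_id", "disease_label", "provenance") %>%
    arrange(.data$hgnc_id, .data$mondo_id, .data$disease_label)

  structure(list(pairs = pairs, exceptions = exceptions), class = "tp_merge")
}

#' @export
print.tp_merge <- function(x, ...) {
  cat("<merged gene-disease pairs>\n")
  cat("  pairs:      ", nrow(x$pairs), " (", dplyr::n_distinct(x$pairs$hgnc_id),
      " distinct genes)\n", sep = "")
  cat("  exceptions: ", nrow(x$exceptions), "\n", sep = "")
  invisible(x)
}

#' Per-source pair counts from a merged pair table
#'
#' Counts, for each source, how many merged pairs carry that source in their
#' provenance; the overlap structure of the underlying source lists can be
#' reconstructed from the provenance strings.
#'
#' @param pairs a merged pair table.
#' @return a `tbl_df` with columns `source_name` and `n_pairs`.
#' @export
provenance_counts <- function(pairs) {
  tibble(source_name = unlist(strsplit(pairs$provenance, ";", fixed = TRUE))) %>%
    count(.data$source_name, name = "n_pairs") %>%
    arrange(.data$source_name)
}

#' Write and read merged pair and exceptions tables
#'
#' @param pairs,exceptions tables as produced by [merge_sources()].
#' @param path output/input TSV path.
#' @name pair_io
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path)
  invisible(path)
}

#' @rdname pair_io
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
}

#' @rdname pair_io
#' @export
write_exceptions <- function(exceptions, path) {
  readr::write_tsv(exceptions, path)
  invisible(path)
}
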