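#' Expert curation as a typed, replayable ledger
#'
#' After automated scoring, the candidate panel goes through rounds of
#' expert review in which genes can be proposed for exclusion (with reasons
#' from a fixed taxonomy) or for inclusion (with supporting references).
#' Every proposal receives exactly one accept/reject decision per round.
#' This module represents those decisions as a ledger that can be validated,
#' applied deterministically, summarized by reason, and replayed to audit
#' any panel version.
#'
#' @name curation
NULL

#' Taxonomy of exclusion reason codes
#'
#' \describe{
#'   \item{NO_GENO_PHENO_CORRELATION}{no genotype-phenotype correlation, not
#'     predictable, or highly variable presentation}
#'   \item{ONSET_NOT_PREDICTABLE_OR_LATE}{age at onset not predictable or
#'     predominantly after two years of age}
#'   \item{EARLY_DX_NO_BENEFIT}{no evidence that early diagnosis changes the
#'     disease course}
#'   \item{VARIABLE_PENETRANCE}{intermediate or variable penetrance}
#'   \item{NOT_TREATABLE_OR_QUESTIONABLE}{majority of phenotypes not
#'     treatable, or treatment effectiveness questionable}
#'   \item{TREATMENT_NOT_EARLY_CHILDHOOD}{treatment not available or not
#'     indicated within early childhood}
#'   \item{OTHER}{anything else; requires free-text elaboration}
#' }
#' @export
REASON_CODES <- c(
  "NO_GENO_PHENO_CORRELATION", "ONSET_NOT_PREDICTABLE_OR_LATE",
  "EARLY_DX_NO_BENEFIT", "VARIABLE_PENETRANCE",
  "NOT_TREATABLE_OR_QUESTIONABLE", "TREATMENT_NOT_EARLY_CHILDHOOD", "OTHER"
)

#' Roles allowed to propose curation changes
#' @export
PROPOSER_ROLES <- c("consortium_expert", "patient_advisory", "scientific_advisory")

panel_stages <- c("post_threshold", "post_round1", "post_round2", "final")

#' Construct a panel from threshold results
#'
#' A panel is an ordered gene set (with the pairs backing each gene), a
#' pipeline stage, and an audit trail of applied curation decisions.
#'
#' @param retained_cards retained score cards, e.g.
#'   `apply_threshold(cards)$retained`.
#' @param stage one of `"post_threshold"`, `"post_round1"`, `"post_round2"`,
#'   `"final"`.
#' @param version_tag free-text version label.
#' @return an object of class `tp_panel` with elements `genes` (`tbl_df`:
#'   `hgnc_id`, `symbol`), `pairs` (`tbl_df`: `hgnc_id`, `mondo_id`),
#'   `stage`, `audit` (list of applied decision tables), `version_tag`.
#' @export
new_panel <- function(retained_cards, stage = "post_threshold",
                      version_tag = "untagged") {
  stopifnot(stage %in% panel_stages)
  genes <- retained_cards %>%
    distinct(.data$hgnc_id, .keep_all = TRUE) %>%
    select("hgnc_id", dplyr::any_of("symbol")) %>%
    arrange(.data$hgnc_id)
  if (!"symbol" %in% names(genes)) genes$symbol <- NA_character_
  pairs <- retained_cards %>%
    distinct(.data$hgnc_id, .data$mondo_id) %>%
    arrange(.data$hgnc_id, .data$mondo_id)
  structure(
    list(genes = genes, pairs = pairs, stage = stage,
         audit = list(), version_tag = version_tag),
    class = "tp_panel"
  )
}

#' @export
print.tp_panel <- function(x, ...) {
  cat("<gene panel> ", nrow(x$genes), " genes, ", nrow(x$pairs), " pairs; stage ",
      x$stage, "; version ", x$version_tag, "\n", sep = "")
  invisible(x)
}

#' Number of genes in a panel
#' @param panel a `tp_panel`.
#' @export
panel_size <- function(panel) nrow(panel$genes)

ledger_columns <- c(
  "action", "hgnc_id", "symbol", "mondo_id", "reasons", "free_text",
  "references", "proposer_role", "round", "status", "rationale"
)

#' Read or write a curation ledger
#'
#' A ledger is a table of curation proposals with their decisions; one row
#' per proposal. `reasons` holds ";"-separated reason codes from
#' [REASON_CODES]; `status` is `"accepted"`, `"rejected"`, or empty for
#' pending proposals.
#'
#' @param path TSV path.
#' @param ledger a ledger table.
#' @return `read_ledger()` returns a `tbl_df` with the canonical ledger
#'   columns.
#' @name ledger_io
#' @export
read_ledger <- function(path) {
  led <- readr::read_tsv(path, col_types = readr::cols(
    round = readr::col_integer(),
    .default = readr::col_character()
  ))
  for (col in setdiff(ledger_columns, names(led))) {
    led[[col]] <- if (col == "round") NA_integer_ else NA_character_
  }
  check_ledger(led[, ledger_columns])
}

#' @rdname ledger_io
#' @export
write_ledger <- function(ledger, path) {
  readr::write_tsv(ledger, path)
  invisible(path)
}

check_ledger <- function(ledger) {
  stopifnot(all(ledger$action %in% c("include", "exclude")))
  codes <- unlist(strsplit(ledger$reasons[!is.na(ledger$reasons)], ";", fixed = TRUE))
  bad <- setdiff(codes, REASON_CODES)
  if (length(bad) > 0) {
    abort(paste0("unknown reason code(s): ", paste(unique(bad), collapse = ", ")))
  }
  other_no_text <- grepl("\\bOTHER\\b", ledger$reasons) &
    (is.na(ledger$free_text) | !nzchar(ledger$free_text))
  if (any(other_no_text, na.rm = TRUE)) {
    abort("reason code OTHER requires free_text elaboration")
  }
  bad_id <- !is_hgnc_id(ledger$hgnc_id)
  if (any(bad_id)) {
    abort(paste0("ledger references malformed gene identifier(s): ",
                 paste(unique(ledger$hgnc_id[bad_id]), collapse = ", ")))
  }
  ledger
}

#' Validate curation proposals against score cards and the current panel
#'
#' Annotates each proposal with advisory flags; it never auto-rejects,
#' because accept/reject is an expert decision. Flags raised:
#' * `gate violation` -- an include proposal whose pair fails a mandatory
#'   gate on the score cards;
#' * `not in panel` -- an exclude proposal for a gene absent from the
#'   current panel;
#' * `missing references` -- an include proposal without supporting
#'   references.
#'
#' @param ledger a ledger table (see [read_ledger()]).
#' @param cards score cards for context (may omit proposed-for-inclusion
#'   pairs that were never scored).
#' @param panel the current `tp_panel`.
#' @return the ledger with an added `flags` column (";"-joined, empty when
#'   clean).
#' @export
validate_proposals <- function(ledger, cards = NULL, panel = NULL) {
  ledger <- check_ledger(ledger)
  flags <- character(nrow(ledger))
  for (i in seq_len(nrow(ledger))) {
    f <- character(0)
    if (ledger$action[[i]] == "include") {
      if (is.na(ledger$references[[i]]) || !nzchar(ledger$references[[i]])) {
        f <- c(f, "missing references")
      }
      if (!is.null(cards)) {
        hit <- cards[cards$hgnc_id == ledger$hgnc_id[[i]] &
                       cards$mondo_id == ledger$mondo_id[[i]], ]
        if (nrow(hit) > 0 &&
            !all(hit$gate_treatability & hit$gate_feasibility)) {
          f <- c(f, "gate violation")
        }
      }
    } else if (!is.null(panel) &&
               !ledger$hgnc_id[[i]] %in% panel$genes$hgnc_id) {
      f <- c(f, "not in panel")
    }
    flags[[i]] <- paste(f, collapse = ";")
  }
  ledger$flags <- flags
  ledger
}

#' Generate exclusion proposals from the treatment-window sub-criterion
#'
#' Inclusion additionally requires that treatment be indicated within the
#' first two years of life. This sub-criterion is applied after automated
#' scoring: for every panel gene all of whose pairs are annotated
#' `treatment_within_2y = FALSE`, an exclusion proposal with reason
#' `TREATMENT_NOT_EARLY_CHILDHOOD` is generated for expert review. A
#' missing flag generates no proposal -- automation only surfaces
#' documented negatives; the experts handle the rest.
#'
#' @param panel a `tp_panel` at the post-threshold stage.
#' @param annotations annotation table carrying `hgnc_id`, `mondo_id`,
#'   `treatment_within_2y`.
#' @param round curation round the proposals are destined for.
#' @return a ledger table of generated (pending) exclude proposals.
#' @export
apply_treatment_window_filter <- function(panel, annotations, round = 1L) {
  stopifnot(panel$stage == "post_threshold")
  ann <- left_join(panel$pairs, annotations, by = c("hgnc_id", "mondo_id"))
  hit <- ann %>%
    group_by(.data$hgnc_id) %>%
    summarise(all_false = all(!is.na(.data$treatment_within_2y) &
                                !.data$treatment_within_2y),
              .groups = "drop") %>%
    filter(.data$all_false)
  tibble(
    action = rep("exclude", nrow(hit)),
    hgnc_id = hit$hgnc_id,
    symbol = panel$genes$symbol[match(hit$hgnc_id, panel$genes$hgnc_id)],
    mondo_id = NA_character_,
    reasons = rep("TREATMENT_NOT_EARLY_CHILDHOOD", nrow(hit)),
    free_text = NA_character_,
    references = NA_character_,
    proposer_role = rep("consortium_expert", nrow(hit)),
    round = rep(as.integer(round), nrow(hit)),
    status = NA_character_,
    rationale = rep("generated by treatment-window screen", nrow(hit))
  )
}

#' Apply accepted ledger decisions to a panel
#'
#' Accepted exclusions remove genes; accepted inclusions add genes (with
#' their pairs). Rejected and pending decisions are recorded in the audit
#' trail but never change the gene set. Duplicate proposals for the same
#' (action, gene) are collapsed before application, and decisions are
#' applied as a set, so the result does not depend on row order. When the
#' same gene has both an accepted inclusion and an accepted exclusion, the
#' exclusion wins (a screening panel is conservative about false
#' positives) and a warning is emitted for human review.
#'
#' @param panel a `tp_panel`.
#' @param ledger a decided ledger table.
#' @param stage stage label for the resulting panel; defaults to the stage
#'   after `panel$stage`.
#' @return a new `tp_panel` with the decisions applied and appended to the
#'   audit trail.
#' @export
apply_ledger <- function(panel, ledger, stage = NULL) {
  stopifnot(inherits(panel, "tp_panel"))
  if (is.null(stage)) {
    pos <- match(panel$stage, panel_stages)
    if (is.na(pos) || pos >= length(panel_stages)) {
      abort(paste0("cannot advance panel beyond stage ", panel$stage))
    }
    stage <- panel_stages[[pos + 1]]
  }
  ledger <- check_ledger(ledger)

  accepted <- ledger[!is.na(ledger$status) & ledger$status == "accepted", ]
  excl <- unique(accepted$hgnc_id[accepted$action == "exclude"])
  incl_rows <- accepted[accepted$action == "include", ] %>%
    distinct(.data$hgnc_id, .data$mondo_id, .keep_all = TRUE)

  conflict <- intersect(excl, unique(incl_rows$hgnc_id))
  if (length(conflict) > 0) {
    warn(paste0("gene(s) with both accepted inclusion and accepted exclusion; ",
                "exclusion applied: ", paste(sort(conflict), collapse = ", ")))
    incl_rows <- incl_rows[!incl_rows$hgnc_id %in% conflict, ]
  }

  genes <- panel$genes[!panel$genes$hgnc_id %in% excl, ]
  pairs <- panel$pairs[!panel$pairs$hgnc_id %in% excl, ]

  new_genes <- incl_rows %>%
    filter(!.data$hgnc_id %in% genes$hgnc_id) %>%
    distinct(.data$hgnc_id, .keep_all = TRUE) %>%
    select("hgnc_id", "symbol")
  genes <- bind_rows(genes, new_genes) %>% arrange(.data$hgnc_id)
  pairs <- bind_rows(pairs, incl_rows[, c("hgnc_id", "mondo_id")]) %>%
    distinct() %>%
    arrange(.data$hgnc_id, .data$mondo_id)

  out <- panel
  out$genes <- genes
  out$pairs <- pairs
  out$stage <- stage
  out$audit <- c(panel$audit, list(list(stage = stage, ledger = ledger)))
  out
}

#' Replay a panel's audit trail from a starting panel
#'
#' Re-applies every audited decision table in order. Replaying a panel's
#' own audit onto its post-threshold ancestor reproduces the panel's gene
#' set exactly; this is the integrity check for panel versions.
#'
#' @param start the ancestor `tp_panel` (audit trail ignored).
#' @param audit an audit list, e.g. `final$audit`.
#' @return the replayed `tp_panel`.
#' @export
replay_audit <- function(start, audit) {
  out <- start
  out$audit <- list()
  for (entry in audit) {
    out <- suppressWarnings(apply_ledger(out, entry$ledger, stage = entry$stage))
  }
  out
}

#' Finalize a panel version
#'
#' @param panel a `tp_panel`.
#' @param version_tag version label to stamp.
#' @return the panel with stage `"final"`.
#' @export
finalize_panel <- function(panel, version_tag = panel$version_tag) {
  panel$stage <- "final"
  panel$version_tag <- version_tag
  panel
}

#' Summarize accepted exclusions by reason code
#'
#' Counts distinct genes per reason among accepted exclusion decisions. A
#' gene excluded for several reasons counts once under each, so the column
#' sum can exceed the number of excluded genes.
#'
#' @param ledger a decided ledger table.
#' @return a `tbl_df` with columns `reason` and `n_genes`, ordered by the
#'   [REASON_CODES] taxonomy.
#' @export
reason_summary <- function(ledger) {
  excl <- ledger[!is.na(ledger$status) & ledger$status == "accepted" &
                   ledger$action == "exclude", ]
  if (nrow(excl) == 0) {
    return(tibble(reason = character(0), n_genes = integer(0)))
  }
  expanded <- tibble(
    hgnc_id = rep(excl$hgnc_id, lengths(strsplit(excl$reasons, ";", fixed = TRUE))),
    reason = unlist(strsplit(excl$reasons, ";", fixed = TRUE))
  ) %>%
    distinct() %>%
    count(.data$reason, name = "n_genes")
  expanded[order(match(expanded$reason, REASON_CODES)), ]
}

#' Serialize a panel (with audit trail) to JSON and back
#'
#' Keys are written in a stable order so that export / import / export is
#' byte-identical.
#'
#' @param panel a `tp_panel`.
#' @param path JSON file path.
#' @name panel_io
#' @export
write_panel_json <- function(panel, path) {
  obj <- list(
    version_tag = panel$version_tag,
    stage = panel$stage,
    genes = panel$genes,
    pairs = panel$pairs,
    audit = lapply(panel$audit, function(e) list(stage = e$stage, ledger = e$ledger))
  )
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       na = "null", pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_panel_json <- function(path) {
  obj <- jsonlite::read_json(path)  # no simplification: audit nests ledgers
  col_chr <- function(x) {
    vapply(if (is.null(x)) list() else x,
           function(v) if (is.null(v)) NA_character_ else as.character(v),
           character(1))
  }
  tbl_from <- function(x, cols) {
    out <- lapply(cols, function(col) col_chr(x[[col]]))
    names(out) <- cols
    as_tibble(out)
  }
  audit <- lapply(obj$audit, function(e) {
    led <- tbl_from(e$ledger, setdiff(ledger_columns, "round"))
    led$round <- vapply(
      if (is.null(e$ledger$round)) list() else e$ledger$round,
      function(v) if (is.null(v)) NA_integer_ else as.integer(v), integer(1))
    list(stage = e$stage, ledger = led[, ledger_columns])
  })
  structure(
    list(
      genes = tbl_from(obj$genes, c("hgnc_id", "symbol")),
      pairs = tbl_from(obj$pairs, c("hgnc_id", "mondo_id")),
      stage = obj$stage,
      audit = audit,
      version_tag = obj$version_tag
    ),
    class = "tp_panel"
  )
}
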