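test_that("ledger validation enforces the reason taxonomy", {
  bad <- ledger_row("exclude", "HGNC:9000001", "accepted", reasons = "BECAUSE")
  expect_error(apply_ledger(tiny_panel(), bad), "unknown reason code")

  other_no_text <- ledger_row("exclude", "HGNC:9000001", "accepted", reasons = "OTHER")
  expect_error(apply_ledger(tiny_panel(), other_no_text), "OTHER requires")

  bad_id <- ledger_row("exclude", "not-an-id", "accepted")
  expect_error(apply_ledger(tiny_panel(), bad_id), "malformed gene identifier")
})

test_that("proposal validation annotates but never auto-rejects", {
  panel <- tiny_panel()
  cards <- tibble::tibble(
    hgnc_id = "HGNC:9000099", mondo_id = "MONDO:0000099",
    gate_treatability = TRUE, gate_feasibility = FALSE
  )
  ledger <- dplyr::bind_rows(
    ledger_row("include", "HGNC:9000099", NA_character_, mondo_id = "MONDO:0000099"),
    ledger_row("exclude", "HGNC:9999999", NA_character_),
    ledger_row("include", "HGNC:9000098", NA_character_, mondo_id = "MONDO:0000098",
               references = NA_character_)
  )
  report <- validate_proposals(ledger, cards, panel)
  expect_equal(report$flags[[1]], "gate violation")
  expect_equal(report$flags[[2]], "not in panel")
  expect_equal(report$flags[[3]], "missing references")
  expect_equal(nrow(report), nrow(ledger))  # nothing dropped
})

test_that("treatment-window filter proposes exclusion only for documented negatives", {
  panel <- tiny_panel(4)
  ann <- dplyr::bind_rows(
    annotation_row("HGNC:9000001", "MONDO:9100001", treatment_within_2y = FALSE),
    annotation_row("HGNC:9000002", "MONDO:9100002", treatment_within_2y = TRUE),
    annotation_row("HGNC:9000003", "MONDO:9100003", treatment_within_2y = NA)
    # gene 4 has no annotation row at all
  )
  props <- apply_treatment_window_filter(panel, ann)
  expect_equal(props$hgnc_id, "HGNC:9000001")
  expect_equal(props$reasons, "TREATMENT_NOT_EARLY_CHILDHOOD")
  expect_true(all(is.na(props$status)))  # pending, not decided
})

test_that("a gene with any non-negative treatment-window pair is not proposed", {
  panel <- new_panel(tibble::tibble(
    hgnc_id = rep("HGNC:9000001", 2), symbol = "G01",
    mondo_id = c("MONDO:9100001", "MONDO:9100002")
  ))
  ann <- dplyr::bind_rows(
    annotation_row("HGNC:9000001", "MONDO:9100001", treatment_within_2y = FALSE),
    annotation_row("HGNC:9000001", "MONDO:9100002", treatment_within_2y = NA)
  )
  expect_equal(nrow(apply_treatment_window_filter(panel, ann)), 0L)
})

test_that("accepted decisions change the panel; rejected and pending do not", {
  panel <- tiny_panel(6)
  ledger <- dplyr::bind_rows(
    ledger_row("exclude", "HGNC:9000001", "accepted"),
    ledger_row("exclude", "HGNC:9000002", "rejected"),
    ledger_row("exclude", "HGNC:9000003", NA_character_),
    ledger_row("include", "HGNC:9000101", "accepted", mondo_id = "MONDO:0000101"),
    ledger_row("include", "HGNC:9000102", "rejected", mondo_id = "MONDO:0000102")
  )
  out <- apply_ledger(panel, ledger)
  expect_equal(panel_size(out), 6L)  # -1 +1
  expect_false("HGNC:9000001" %in% out$genes$hgnc_id)
  expect_true(all(c("HGNC:9000002", "HGNC:9000003") %in% out$genes$hgnc_id))
  expect_true("HGNC:9000101" %in% out$genes$hgnc_id)
  expect_false("HGNC:9000102" %in% out$genes$hgnc_id)
  expect_equal(out$stage, "post_round1")
  # empty ledger: identity on genes, stage still advances
  out2 <- apply_ledger(out, ledger[0, ])
  expect_identical(out2$genes, out$genes)
  expect_equal(out2$stage, "post_round2")
})

test_that("accounting identity holds and duplicates collapse", {
  panel <- tiny_panel(6)
  ledger <- dplyr::bind_rows(
    ledger_row("exclude", "HGNC:9000001", "accepted"),
    ledger_row("exclude", "HGNC:9000001", "accepted"),       # duplicate
    ledger_row("exclude", "HGNC:9000404", "accepted"),       # not in panel
    ledger_row("include", "HGNC:9000101", "accepted", mondo_id = "MONDO:0000101"),
    ledger_row("include", "HGNC:9000101", "accepted", mondo_id = "MONDO:0000101"),
    ledger_row("include", "HGNC:9000002", "accepted", mondo_id = "MONDO:0000999")
  )
  out <- apply_ledger(panel, ledger)
  excluded_present <- 1L  # only HGNC:9000001 was actually in the panel
  added_new <- 1L         # HGNC:9000101; HGNC:9000002 was already present
  expect_equal(panel_size(out), panel_size(panel) - excluded_present + added_new)
  # the include for an existing gene contributed its new pair, not a dup gene
  expect_equal(sum(out$genes$hgnc_id == "HGNC:9000002"), 1L)
  expect_true(any(out$pairs$hgnc_id == "HGNC:9000002" &
                    out$pairs$mondo_id == "MONDO:0000999"))
})

test_that("conflicting accepted decisions resolve to exclusion with a warning", {
  panel <- tiny_panel(3)
  ledger <- dplyr::bind_rows(
    ledger_row("include", "HGNC:9000001", "accepted", mondo_id = "MONDO:0000001"),
    ledger_row("exclude", "HGNC:9000001", "accepted")
  )
  expect_warning(out <- apply_ledger(panel, ledger), "exclusion applied")
  expect_false("HGNC:9000001" %in% out$genes$hgnc_id)
})

test_that("decision application is order-independent", {
  panel <- tiny_panel(6)
  ledger <- dplyr::bind_rows(
    ledger_row("exclude", "HGNC:9000002", "accepted"),
    ledger_row("include", "HGNC:9000201", "accepted", mondo_id = "MONDO:0000201"),
    ledger_row("include", "HGNC:9000002", "accepted", mondo_id = "MONDO:0000299"),
    ledger_row("exclude", "HGNC:9000005", "rejected"),
    ledger_row("include", "HGNC:9000202", "accepted", mondo_id = "MONDO:0000202")
  )
  ref <- suppressWarnings(apply_ledger(panel, ledger))
  for (seed in 1:5) {
    shuffled <- ledger[withr::with_seed(seed, sample(nrow(ledger))), ]
    out <- suppressWarnings(apply_ledger(panel, shuffled))
    expect_identical(out$genes, ref$genes)
    expect_identical(out$pairs, ref$pairs)
  }
})

test_that("the audit trail replays to the identical gene set", {
  panel <- tiny_panel(6)
  l1 <- dplyr::bind_rows(
    ledger_row("exclude", "HGNC:9000001", "accepted"),
    ledger_row("include", "HGNC:9000101", "accepted", mondo_id = "MONDO:0000101")
  )
  l2 <- dplyr::bind_rows(
    ledger_row("exclude", "HGNC:9000101", "accepted", round = 2L),
    ledger_row("include", "HGNC:9000102", "accepted", mondo_id = "MONDO:0000102",
               round = 2L)
  )
  final <- finalize_panel(apply_ledger(apply_ledger(panel, l1), l2), "v1")
  replayed <- replay_audit(panel, final$audit)
  expect_identical(replayed$genes, final$genes)
  expect_identical(replayed$pairs, final$pairs)
})

test_that("reason summaries count genes once per reason", {
  ledger <- dplyr::bind_rows(
    ledger_row("exclude", "HGNC:9000001", "accepted",
               reasons = "VARIABLE_PENETRANCE;EARLY_DX_NO_BENEFIT"),
    ledger_row("exclude", "HGNC:9000002", "accepted",
               reasons = "VARIABLE_PENETRANCE;EARLY_DX_NO_BENEFIT"),
    ledger_row("exclude", "HGNC:9000003", "rejected",
               reasons = "NO_GENO_PHENO_CORRELATION")
  )
  tab <- reason_summary(ledger)
  expect_equal(sum(tab$n_genes), 4L)  # 2 genes x 2 reasons; rejected ignored
  expect_setequal(tab$reason, c("EARLY_DX_NO_BENEFIT", "VARIABLE_PENETRANCE"))
  expect_true(all(tab$n_genes == 2L))
  expect_equal(nrow(reason_summary(ledger[0, ])), 0L)
})

test_that("panels round-trip through JSON byte-identically", {
  panel <- tiny_panel(4)
  l1 <- dplyr::bind_rows(
    ledger_row("exclude", "HGNC:9000001", "accepted"),
    ledger_row("include", "HGNC:9000101", "accepted", mondo_id = "MONDO:0000101")
  )
  panel <- apply_ledger(panel, l1)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_panel_json(panel, p1)
  back <- read_panel_json(p1)
  expect_equal(back$genes, panel$genes)
  expect_equal(back$stage, panel$stage)
  write_panel_json(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})
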