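test_that("validity scoring takes the highest curation across submitters", {
  cases <- list(
    list(cls = c("A" = "Strong", "B" = "Moderate"), score = 2L, gate = TRUE),
    list(cls = c("Definitive"), score = 2L, gate = TRUE),
    list(cls = c("Moderate"), score = 1L, gate = FALSE),
    list(cls = c("Moderate", "Limited", "Refuted Evidence"), score = 1L, gate = FALSE),
    list(cls = c("Limited"), score = 0L, gate = FALSE),
    list(cls = c("Animal Model Only", "Disputed Evidence"), score = 0L, gate = FALSE),
    list(cls = character(0), score = 0L, gate = FALSE)  # no curation at all
  )
  for (case in cases) {
    expect_equal(score_validity(case$cls), case$score)
    expect_equal(validity_gate(case$cls), case$gate)
  }
  expect_error(score_validity("Definitely"), "Definitely")
})

test_that("onset scoring selects the earliest category and falls back sensibly", {
  expect_equal(score_onset("neonatal"), 2L)
  expect_equal(score_onset(c("adult", "neonatal")), 2L)  # earliest wins
  expect_equal(score_onset(c("elderly", "adolescence")), 1L)
  expect_equal(score_onset("adolescence"), 1L)
  expect_equal(score_onset("adult"), 0L)
  expect_equal(score_onset("elderly"), 0L)
  expect_equal(score_onset("antenatal"), 2L)  # earlier than birth
  for (cat in c("birth", "infancy", "birth-to-childhood", "childhood")) {
    expect_equal(score_onset(cat), 2L)
  }
  # ASQM is the fallback when Orphanet has nothing
  expect_equal(score_onset(character(0), asqm = "adult"), 0L)
  # Orphanet takes precedence over ASQM
  expect_equal(score_onset("neonatal", asqm = "adult"), 2L)
  # no data in either resource -> automatic 1
  expect_equal(score_onset(character(0)), 1L)
  expect_error(score_onset("teenager"), "teenager")
})

test_that("severity scoring maps ASQM grades with direct category precedence", {
  expect_equal(score_severity(asqm = 0), 0L)
  expect_equal(score_severity(asqm = 1), 1L)
  expect_equal(score_severity(asqm = 2), 2L)
  expect_equal(score_severity(asqm = 3), 2L)
  expect_equal(score_severity(), 1L)  # missing -> 1
  expect_equal(score_severity(category = "not_significant"), 0L)
  expect_equal(score_severity(category = "spectrum_unpredictable"), 1L)
  # direct category beats a contradictory ASQM grade
  expect_equal(score_severity(asqm = 0, category = "significant"), 2L)
  expect_error(score_severity(asqm = 5), "out of range")
})

test_that("penetrance scoring maps categories and derives them from fractions", {
  expect_equal(score_penetrance("high"), 2L)
  expect_equal(score_penetrance("moderate"), 1L)
  expect_equal(score_penetrance("low"), 0L)
  expect_equal(score_penetrance(), 1L)  # missing -> 1
  # fraction boundaries: >= 0.80 high (inclusive), < 0.20 low
  expect_equal(score_penetrance(fraction = 0.80), 2L)
  expect_equal(score_penetrance(fraction = 0.79), 1L)
  expect_equal(score_penetrance(fraction = 0.20), 1L)
  expect_equal(score_penetrance(fraction = 0.19), 0L)
  expect_error(score_penetrance(fraction = 1.2), "outside")
})

test_that("treatability gate accepts any qualifying source and rejects empty provenance", {
  expect_true(treatability_gate("RxGenes"))
  expect_true(treatability_gate("ASQM;GTRx"))
  expect_error(treatability_gate(character(0)), "provenance")
})

test_that("score cards compose criteria, gates, and threshold correctly", {
  fx <- realize_scores(2, 2, 2, 2)
  card <- score_pairs(fx$pairs, fx$annotations, fx$validity)
  expect_equal(card$total, 8L)
  expect_true(card$included)

  # Strong validity, neonatal onset, ASQM 1 severity, high penetrance: 7
  fx <- realize_scores(2, 2, 1, 2)
  fx$annotations$severity_asqm <- 1L
  fx$validity$classification <- "Strong"
  card <- score_pairs(fx$pairs, fx$annotations, fx$validity)
  expect_equal(card$total, 7L)
  expect_true(card$included)

  # one criterion at 0 forces the total below the cutoff
  fx <- realize_scores(2, 2, 0, 2)
  card <- score_pairs(fx$pairs, fx$annotations, fx$validity)
  expect_equal(card$total, 6L)
  expect_false(card$included)

  # total 8 but feasibility gate fails -> excluded
  fx <- realize_scores(2, 2, 2, 2)
  fx$annotations$feasible <- FALSE
  fx$annotations$feasibility_reason <- "non-mendelian inheritance"
  card <- score_pairs(fx$pairs, fx$annotations, fx$validity)
  expect_equal(card$total, 8L)
  expect_false(card$included)
  expect_false(card$gate_feasibility)
})

test_that("missing-data defaults are applied and recorded on the card", {
  pairs <- tibble::tibble(hgnc_id = "HGNC:1", symbol = "G1",
                          mondo_id = "MONDO:0000001", provenance = "ASQM")
  card <- score_pairs(pairs, annotations = NULL, validity = NULL)
  expect_equal(card$s_validity, 0L)
  expect_equal(card$s_onset, 1L)
  expect_equal(card$s_severity, 1L)
  expect_equal(card$s_penetrance, 1L)
  expect_equal(card$total, 3L)
  expect_equal(
    sort(strsplit(card$notes, ";")[[1]]),
    sort(c("validity:missing_default", "onset:missing_default",
           "severity:missing_default", "penetrance:missing_default"))
  )
})

test_that("threshold partition conserves cards and orders deterministically", {
  fxs <- list(realize_scores(2, 2, 2, 2, "HGNC:3", "MONDO:0000003"),
              realize_scores(2, 2, 1, 2, "HGNC:1", "MONDO:0000001"),
              realize_scores(2, 2, 1, 1, "HGNC:2", "MONDO:0000002"))
  pairs <- dplyr::bind_rows(lapply(fxs, `[[`, "pairs"))
  ann <- dplyr::bind_rows(lapply(fxs, `[[`, "annotations"))
  val <- dplyr::bind_rows(lapply(fxs, `[[`, "validity"))
  cards <- score_pairs(pairs, ann, val)
  thr <- apply_threshold(cards)
  expect_equal(nrow(thr$retained) + nrow(thr$excluded), nrow(cards))
  expect_equal(nrow(thr$retained), 2L)
  expect_equal(thr$retained$hgnc_id, sort(thr$retained$hgnc_id))
  expect_setequal(thr$retained_genes, c("HGNC:1", "HGNC:3"))
})

test_that("exhaustive enumeration of the 81 score combinations matches a brute-force oracle", {
  grid <- expand.grid(v = 0:2, o = 0:2, s = 0:2, p = 0:2)
  included <- logical(nrow(grid))
  totals <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    fx <- realize_scores(g$v, g$o, g$s, g$p)
    cfg <- rubric_config(validity_gate_enabled = FALSE)
    card <- score_pairs(fx$pairs, fx$annotations, fx$validity, cfg)
    expect_equal(card[, c("s_validity", "s_onset", "s_severity", "s_penetrance")],
                 tibble::tibble(s_validity = g$v, s_onset = g$o,
                                s_severity = g$s, s_penetrance = g$p),
                 ignore_attr = TRUE)
    included[i] <- card$included
    totals[i] <- card$total
  }
  # independent arithmetic oracle on the same grid
  expect_equal(included, rowSums(grid) >= 7)
  expect_equal(sum(included), 5L)
  expect_equal(min(totals[included]), 7L)
  # zero-criterion lemma: any 0 forces exclusion at cutoff 7
  expect_false(any(included & apply(grid == 0, 1, any)))
})

test_that("raising the cutoff to 8 retains only all-maximal cards", {
  cfg <- rubric_config(cutoff = 8)
  for (combo in list(c(2, 2, 2, 2), c(2, 2, 1, 2), c(2, 2, 2, 1))) {
    fx <- realize_scores(combo[1], combo[2], combo[3], combo[4])
    card <- score_pairs(fx$pairs, fx$annotations, fx$validity, cfg)
    expect_equal(card$included, all(combo == 2))
  }
})

test_that("rubric configuration validates and round-trips through YAML", {
  expect_error(rubric_config(cutoff = 9))
  expect_error(rubric_config(missing_onset_score = 5))

  cfg <- rubric_config(cutoff = 8, penetrance_high_boundary = 0.9,
                       validity_gate_enabled = FALSE)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_rubric_config(cfg, path)
  back <- read_rubric_config(path)
  expect_equal(back$cutoff, 8L)
  expect_equal(back$penetrance_high_boundary, 0.9)
  expect_false(back$validity_gate_enabled)
  expect_equal(back$validity_scores, cfg$validity_scores)
})
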