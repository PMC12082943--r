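test_that("gene resolution honours tier precedence and case folding", {
  map <- tiny_symbol_map()

  expect_equal(resolve_gene("SMN1", map)$hgnc_id, "HGNC:11117")
  expect_equal(resolve_gene("smn1", map)$hgnc_id, "HGNC:11117")
  # previous symbol resolves to the current identifier
  expect_equal(resolve_gene("OLDGAA", map)$hgnc_id, "HGNC:4065")
  # current tier beats alias: SHAREDALIAS is ambiguous only at alias tier
  amb <- resolve_gene("SHAREDALIAS", map)
  expect_s3_class(amb, "tp_unresolved")
  expect_equal(amb$reason, "ambiguous alias")

  nores <- resolve_gene("NOSUCHGENE", map)
  expect_s3_class(nores, "tp_unresolved")
  expect_equal(nores$reason, "no match")
})

test_that("symbol map validation rejects duplicate current-tier tokens", {
  expect_error(
    symbol_map(token = c("gaa", "gaa"), tier = c("current", "current"),
               hgnc_id = c("HGNC:1", "HGNC:2"), symbol = c("GAA", "GAA")),
    "current-tier"
  )
  expect_error(
    symbol_map("x", "nonsense_tier", "HGNC:1", "X"),
    "unknown symbol map tier"
  )
})

test_that("disease resolution passes MONDO through, maps crosswalk tokens, and keeps unmapped labels", {
  cw <- tiny_crosswalk()
  expect_equal(resolve_disease("MONDO:0010679", cw)$mondo_id, "MONDO:0010679")
  expect_equal(resolve_disease("ORPHA:70", cw)$mondo_id, "MONDO:0010679")
  expect_equal(resolve_disease("Pompe Disease", cw)$mondo_id, "MONDO:0009290")
  unk <- resolve_disease("some unknown disease", cw)
  expect_equal(unk$mondo_id, UNMAPPED)
  expect_equal(unk$label, "some unknown disease")
})

test_that("merging unions records by identity and accumulates provenance", {
  map <- tiny_symbol_map()
  cw <- tiny_crosswalk()
  records <- tibble::tibble(
    source_name = c("RxGenes", "GTRx", "RxGenes", "ASQM"),
    gene = c("SMN1", "smn1", "GAA", "GAA"),
    disease = c("MONDO:0010679", "MONDO:0010679", "ORPHA:365", "MONDO:0016333"),
    filter_note = NA_character_
  )
  merged <- merge_sources(records, map, cw)
  expect_equal(nrow(merged$pairs), 3L)
  smn <- merged$pairs[merged$pairs$hgnc_id == "HGNC:11117", ]
  expect_equal(smn$provenance, "GTRx;RxGenes")
  # same gene, two diseases -> two pairs with the same hgnc_id
  expect_equal(sum(merged$pairs$hgnc_id == "HGNC:4065"), 2L)
  expect_equal(nrow(merged$exceptions), 0L)
})

test_that("unresolvable tokens go to the exceptions report, never lost silently", {
  map <- tiny_symbol_map()
  cw <- tiny_crosswalk()
  records <- tibble::tibble(
    source_name = c(rep("RxGenes", 5), rep("GTRx", 5)),
    gene = c("SMN1", "GAA", "IDUA", "MUT", "BOGUS1",
             "SMN1", "GAA", "IDUA", "MUT", "BOGUS2"),
    disease = sprintf("MONDO:00000%02d", 1:10),
    filter_note = NA_character_
  )
  merged <- merge_sources(records, map, cw)
  expect_equal(nrow(merged$pairs), 8L)
  expect_equal(nrow(merged$exceptions), 2L)
  expect_setequal(merged$exceptions$raw_gene, c("BOGUS1", "BOGUS2"))
  # conservation: resolved + exceptions = distinct input triples
  expect_equal(nrow(merged$pairs) + nrow(merged$exceptions), 10L)
  # every source appears in provenance or exceptions
  prov_sources <- unique(unlist(strsplit(merged$pairs$provenance, ";")))
  expect_setequal(union(prov_sources, merged$exceptions$source_name),
                  unique(records$source_name))
})

test_that("merging is idempotent and deterministic", {
  map <- tiny_symbol_map()
  cw <- tiny_crosswalk()
  records <- tibble::tibble(
    source_name = c("RxGenes", "GTRx", "RxGenes"),
    gene = c("SMN1", "SMN1", "GAA"),
    disease = c("ORPHA:70", "ORPHA:70", "ORPHA:365"),
    filter_note = NA_character_
  )
  m1 <- merge_sources(records, map, cw)
  m2 <- merge_sources(rbind(records, records), map, cw)
  expect_identical(m1$pairs, m2$pairs)
})

test_that("unmapped diseases are distinguished by label, not collapsed", {
  map <- tiny_symbol_map()
  cw <- tiny_crosswalk()
  records <- tibble::tibble(
    source_name = "RxGenes",
    gene = c("SMN1", "SMN1"),
    disease = c("mystery disease A", "mystery disease B"),
    filter_note = NA_character_
  )
  merged <- merge_sources(records, map, cw)
  expect_equal(nrow(merged$pairs), 2L)
  expect_true(all(merged$pairs$mondo_id == UNMAPPED))
})

test_that("empty input is an error and pair tables round-trip through TSV", {
  expect_error(merge_sources(tibble::tibble(), tiny_symbol_map(), tiny_crosswalk()),
               "no source records")

  records <- tibble::tibble(source_name = "RxGenes", gene = "SMN1",
                            disease = "ORPHA:70", filter_note = NA_character_)
  merged <- merge_sources(records, tiny_symbol_map(), tiny_crosswalk())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(merged$pairs, path)
  expect_equal(as.data.frame(read_pairs(path)), as.data.frame(merged$pairs))
})
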