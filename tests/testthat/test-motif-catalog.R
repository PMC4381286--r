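# ZB-motif notation parsing and gapped-pattern scanning.

test_that("motif notation parses into the expected element lists", {
  p <- parse_pattern("CxCx20-21Yx3C", "bact-I", "bacteria-GluRS")
  expect_equal(vapply(p$residue_sets, paste, "", collapse = ""),
               c("C", "C", "Y", "C"))
  expect_equal(p$gap_min, c(1L, 20L, 3L))
  expect_equal(p$gap_max, c(1L, 21L, 3L))

  q <- parse_pattern("CxCx14CxC")
  expect_equal(q$gap_min, c(1L, 14L, 1L))
  expect_equal(q$gap_max, c(1L, 14L, 1L))

  ## underscore / uppercase-X / en-dash spellings are equivalent
  expect_equal(format(parse_pattern("CXCX_20–21_YX_3_C")),
               "CxCx20-21Yx3C")

  ## bracketed residue sets
  b <- parse_pattern("Cx2[CH]")
  expect_equal(b$residue_sets[[2]], c("C", "H"))
})

test_that("malformed notation is rejected with the offending token", {
  expect_error(parse_pattern(""), "empty")
  expect_error(parse_pattern("Cx"), "dangling gap")
  expect_error(parse_pattern("CxCx5-2C"), "5-2")
  expect_error(parse_pattern("CxBx3C"), "'B'")
  expect_error(parse_pattern("x3C"), "leading gap")
})

test_that("patterns round-trip through their notation", {
  for (taxon in c("bacteria-GluRS", "bacteria-GluQRS", "archaea-GluRS",
                  "eukarya-GluRS")) {
    for (p in zb_catalog(taxon)) {
      q <- parse_pattern(format(p), p$name, p$taxon)
      expect_equal(q$residue_sets, p$residue_sets)
      expect_equal(q$gap_min, p$gap_min)
      expect_equal(q$gap_max, p$gap_max)
    }
  }
})

test_that("a planted canonical motif is found at its coordinates", {
  seq <- paste0("AA", "CAC", strrep("A", 20), "Y", "AAA", "C", "AA")
  hits <- scan_sequence(seq, zb_catalog("bacteria-GluRS"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pattern, "bact-I")
  expect_equal(hits$start, 2L)
  expect_equal(hits$anchored_positions, "2,4,25,29")
  expect_equal(hits$gaps, "1,20,3")

  arch <- paste0("CAC", strrep("A", 14), "CAC")
  h2 <- scan_sequence(arch, parse_pattern("CxCx14CxC", "arch-I"))
  expect_equal(h2$gaps, "1,14,1")
  expect_equal(h2$start, 0L)
})

test_that("the disrupted chimera motif does not match the canonical pattern", {
  ## CxMx20Yx3W: third and fourth anchors broken
  seq <- paste0("CAM", strrep("A", 20), "Y", "AAA", "W")
  bact <- zb_catalog("bacteria-GluRS")
  expect_equal(nrow(scan_sequence(seq, bact)), 0L)
  ## but the near-miss report sees the two intact anchors
  near <- find_disrupted(seq, bact[[1]], min_matches = 2L)
  expect_gt(nrow(near), 0L)
  expect_true(any(near$start == 0 & near$n_matched == 2))
})

test_that("sequence validation and window semantics behave", {
  expect_error(scan_sequence("ACZ", zb_catalog("bacteria-GluRS")), "Z")
  ## X never matches an anchor but may sit inside a gap
  p <- parse_pattern("CxC", "toy")
  expect_equal(nrow(scan_sequence("CXC", p)), 1L)  # X consumed by the gap
  expect_equal(nrow(scan_sequence("XAC", p)), 0L)  # X cannot anchor
  ## case-insensitive input
  expect_equal(nrow(scan_sequence("cac", p)), 1L)
  ## window: all anchors must fall inside; overlapping matches all reported
  seq <- "CACAC"
  expect_equal(nrow(scan_sequence(seq, p)), 2L)
  expect_equal(nrow(scan_sequence(seq, p, window = c(0, 4))), 1L)
  expect_equal(nrow(scan_sequence(seq, p, window = c(2, 5))), 1L)
  expect_error(scan_sequence(seq, p, window = c(0, 9)), "window")
})

test_that("classification picks the highest-priority matching pattern", {
  bact <- zb_catalog("bacteria-GluRS")
  ## sequence matching both patterns: YY lets bact-II use the gap-20 route
  ## to an H while bact-I uses the gap-21 route to a C
  seq <- paste0("CAC", strrep("A", 20), "YY", "AA", "H", "C")
  hits <- scan_sequence(seq, bact)
  expect_setequal(unique(hits$pattern), c("bact-I", "bact-II"))
  ## independent check that both genuinely match
  okeys <- hit_keys(oracle_scan(seq, bact))
  expect_true(any(grepl("bact-I\\|", okeys)) && any(grepl("bact-II", okeys)))
  expect_equal(classify_motif(hits, bact), "bact-I")
  expect_equal(classify_motif(hits[0, ], bact), "none")
})

test_that("scanner agrees with the naive enumerator on random sequences", {
  set.seed(42)
  pats <- c(zb_catalog("bacteria-GluRS"),
            list(parse_pattern("CxCx2-4Yx2C", "short-I"),
                 parse_pattern("Cx1-3[CH]", "short-II")))
  for (rep in 1:300) {
    s <- random_string(sample(5:40, 1), c("A", "C", "Y", "H"))
    expect_identical(hit_keys(scan_sequence(s, pats)),
                     hit_keys(oracle_scan(s, pats)))
  }
})

test_that("planted motif instances are recovered exactly, any seed", {
  bact1 <- zb_catalog("bacteria-GluRS")[[1]]
  for (seed in c(1, 7, 99)) {
    k <- 3L
    pl <- gen_planted_sequence(bact1, k, seed = seed)
    hits <- scan_sequence(pl$seq, bact1)
    expect_equal(nrow(hits), k)
    expect_equal(hits$start, pl$truth$start)
    expect_equal(hits$end, pl$truth$end)
    expect_equal(hits$gaps, pl$truth$gaps)
  }
})

test_that("catalog YAML override round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("- name: my-I", "  taxon: custom", "  notation: CxCx5Yx2C",
               "- name: my-II", "  taxon: custom", "  notation: CxCx5Hx2C"),
             path)
  cat <- read_catalog_yaml(path)
  expect_length(cat, 2L)
  expect_equal(cat[[1]]$name, "my-I")
  expect_equal(format(cat[[2]]), "CxCx5Hx2C")
})

test_that("FASTA scanning attaches record ids", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", paste0("AA", "CAC", strrep("A", 20), "Y", "AAAC"),
               ">s2", "AAAAAAA"), path)
  hits <- scan_fasta(path, zb_catalog("bacteria-GluRS"))
  expect_equal(unique(hits$seq_id), "s1")
})
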