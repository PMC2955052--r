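test_that("consensus backtranslates reference-anchored columns", {
  aln <- tibble::tibble(id = c("r", "a", "b"),
                        seq = c("HGW", "HGW", "HGW"))
  cons <- build_consensus(aln, "r")
  expect_equal(cons$seq, "CAYGGITGG")
  expect_equal(nrow(cons$codon_map), 3)

  aln2 <- tibble::tibble(id = c("x", "y"), seq = c("MW", "MW"))
  expect_equal(build_consensus(aln2, "x")$seq, "ATGTGG")
})

test_that("columns gapped in the reference are skipped", {
  aln <- tibble::tibble(id = c("ref", "other"),
                        seq = c("AC-D", "ACED"))
  cons <- build_consensus(aln, "ref")
  expect_equal(nchar(cons$seq), 9)
  expect_equal(cons$codon_map$aln_column, c(1L, 2L, 4L))
  expect_equal(cons$codon_map$ref_residue, 1:3)
  # gapped non-reference rows contribute only their present residues
  aln3 <- tibble::tibble(id = c("ref", "gapped"), seq = c("MW", "M-"))
  expect_equal(build_consensus(aln3, "ref")$seq, "ATGTGG")
})

test_that("consensus construction validates its inputs", {
  aln <- tibble::tibble(id = c("a", "b"), seq = c("MW", "MWE"))
  expect_error(build_consensus(aln, "a"), "equal length")
  expect_error(build_consensus(tibble::tibble(id = "a", seq = "MW"), "z"),
               "not found")
  # column empty after exclusions is an error naming the column
  aln_x <- tibble::tibble(id = c("r", "o"), seq = c("XW", "XW"))
  expect_error(build_consensus(aln_x, "r"), "column 1")
})

test_that("consensus is invariant to duplicated alignment rows", {
  aln <- tibble::tibble(id = c("r", "a"), seq = c("HGWK", "HDWK"))
  dup <- dplyr::bind_rows(aln, aln[2, ])
  expect_equal(build_consensus(aln, "r")$seq, build_consensus(dup, "r")$seq)
})

test_that("window enumeration honours thresholds inclusively", {
  cons <- fake_consensus("ACGTACGTAC")
  p <- design_params(probe_length = 4, degeneracy_max = 1,
                     inosine_max_fraction = 0, trim_last_base = FALSE)
  cands <- enumerate_probes(cons, p)
  expect_equal(nrow(cands), 7)
  expect_equal(cands$start_nt, 1:7)
  expect_equal(cands$end_nt - cands$start_nt + 1,
               rep(4L, 7))

  # windows containing inosine rejected at inosine_max 0
  cons2 <- fake_consensus("AYIACG")
  p2 <- design_params(probe_length = 3, degeneracy_max = 100,
                      inosine_max_fraction = 0)
  cands2 <- enumerate_probes(cons2, p2)
  has_I <- grepl("I", c("AYI", "YIA", "IAC", "ACG"))
  expect_equal(nrow(cands2), sum(!has_I))
  expect_false(any(grepl("I", cands2$seq)))

  # no thresholds: every window kept
  p3 <- design_params(probe_length = 3, degeneracy_max = Inf,
                      inosine_max_fraction = 1)
  expect_equal(nrow(enumerate_probes(cons2, p3)), 4)

  # boundary: degeneracy exactly at the threshold is kept
  consY <- fake_consensus("AYYA")
  pY <- design_params(probe_length = 4, degeneracy_max = 4,
                      inosine_max_fraction = 0)
  expect_equal(nrow(enumerate_probes(consY, pY)), 1)
})

test_that("short consensus yields an empty candidate list with a warning", {
  cons <- fake_consensus("ACG")
  expect_warning(out <- enumerate_probes(cons, design_params(24, 10, 0)),
                 "shorter")
  expect_equal(nrow(out), 0)
})

test_that("raising either threshold never shrinks the candidate set", {
  set.seed(23)
  for (rep in 1:10) {
    cons <- fake_consensus(random_degenerate(40))
    L <- 10
    base <- nrow(enumerate_probes(cons, design_params(L, 8, 0.1)))
    more_deg <- nrow(enumerate_probes(cons, design_params(L, 64, 0.1)))
    more_ino <- nrow(enumerate_probes(cons, design_params(L, 8, 0.5)))
    expect_gte(more_deg, base)
    expect_gte(more_ino, base)
  }
})

test_that("maximum total degeneracy follows the threshold arithmetic", {
  expect_equal(max_total_degeneracy(design_params(24, 129, 0.25)), 528384)
  expect_equal(max_total_degeneracy(design_params(24, 258, 0.09)), 4128)
  expect_equal(max_total_degeneracy(design_params(24, 77, 0)), 77)
})

test_that("last-base trimming shortens probes and updates metrics", {
  cons <- fake_consensus("GTITGYAAYTAYCAYGGITGGGTI")
  p <- design_params(probe_length = 24, degeneracy_max = 129,
                     inosine_max_fraction = 0.25, trim_last_base = FALSE)
  cands <- enumerate_probes(cons, p)
  trimmed <- trim_probes(cands)
  expect_equal(trimmed$seq[[1]], "GTITGYAAYTAYCAYGGITGGGT")
  expect_equal(trimmed$end_nt, cands$end_nt - 1L)
  expect_equal(trimmed$total_degeneracy[[1]], 256)
  twice <- trim_probes(trimmed)
  expect_equal(nchar(twice$seq), nchar(cands$seq) - 2L)
  # trimming a terminal Y halves the degeneracy
  endY <- tibble::tibble(probe_id = "y", seq = "ACGTAY", start_nt = 1L,
                         end_nt = 6L, degeneracy = 2, inosine_count = 0L,
                         total_degeneracy = 2, crosshyb_count = NA_integer_)
  expect_equal(trim_probes(endY)$degeneracy, 1)
  one <- dplyr::mutate(cands[1, ], seq = "A")
  expect_error(trim_probes(one), "length-1")
})

test_that("ranking orders by cross-hybridization, degeneracy, then spacing", {
  cands <- tibble::tibble(
    probe_id = c("p1", "p2"), seq = c("ACGT", "ACGT"),
    start_nt = c(1L, 5L), end_nt = c(4L, 8L),
    degeneracy = c(1, 1), inosine_count = c(0L, 0L),
    total_degeneracy = c(1, 1), crosshyb_count = c(3L, 0L)
  )
  expect_equal(rank_probes(cands)$probe_id, c("p2", "p1"))

  cands$crosshyb_count <- c(0L, 0L)
  cands$total_degeneracy <- c(1024, 128)
  expect_equal(rank_probes(cands)$probe_id, c("p2", "p1"))

  spaced <- tibble::tibble(
    probe_id = c("a", "b", "c"), seq = "ACGT",
    start_nt = c(10L, 15L, 300L), end_nt = c(13L, 18L, 303L),
    degeneracy = 1, inosine_count = 0L, total_degeneracy = 1,
    crosshyb_count = 0L
  )
  picked <- rank_probes(spaced, k = 2)
  expect_setequal(picked$probe_id, c("a", "c"))
})

test_that("published degenerate probes expand to the printed counts", {
  tbl <- published_probes()
  consistent <- tbl$probe_id != "bphB_MD_B"
  counts <- vapply(tbl$seq, function(s) length(expand_probe(s)), numeric(1),
                   USE.NAMES = FALSE)
  expect_equal(counts[consistent], tbl$n_specific[consistent])
  expect_equal(counts, total_degeneracy(tbl$seq))
})

test_that("candidate expansion carries variant ordinals per probe", {
  cands <- tibble::tibble(probe_id = c("g_MD_001", "g_MD_002"),
                          seq = c("AY", "AIC"))
  ex <- expand_probes(cands, "keep")
  expect_equal(ex$variant_id, c("g_MD_001_0001", "g_MD_001_0002",
                                "g_MD_002_0001"))
  ex2 <- expand_probes(cands, "expand")
  expect_equal(nrow(ex2), 2 + 4)
})
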