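test_that("background records are CDSs extended by truncated flanks", {
  parent <- random_dna(400)
  genome <- tibble::tibble(id = "chr", seq = parent)
  feats <- tibble::tibble(seqid = "chr", start = 101L, end = 200L,
                          strand = "+", id = "cdsA")
  db <- build_crosshyb_db(genome, feats, flank = 100)
  expect_equal(nchar(db$seq), 300)
  expect_equal(db$seq, substr(parent, 1, 300))
  expect_equal(db$flank5, 100)

  # CDS at the sequence start: 5' flank truncated, never padded
  feats2 <- tibble::tibble(seqid = "chr", start = 1L, end = 60L,
                           strand = "+", id = "cdsB")
  db2 <- build_crosshyb_db(genome, feats2, flank = 100)
  expect_equal(nchar(db2$seq), 160)
  expect_equal(db2$flank5, 0)

  # minus strand: reverse complement of the plus-strand slice
  feats3 <- tibble::tibble(seqid = "chr", start = 101L, end = 200L,
                           strand = "-", id = "cdsC")
  db3 <- build_crosshyb_db(genome, feats3, flank = 50)
  slice <- substr(parent, 51, 250)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(slice)))
  expect_equal(db3$seq, rc)
})

test_that("database construction fails on bad coordinates or parents", {
  genome <- tibble::tibble(id = "chr", seq = random_dna(100))
  expect_error(build_crosshyb_db(
    genome, tibble::tibble(seqid = "chr", start = 50L, end = 150L,
                           strand = "+", id = "x")), "outside")
  expect_error(build_crosshyb_db(
    genome, tibble::tibble(seqid = "nope", start = 1L, end = 10L,
                           strand = "+", id = "x")), "not in genome")
})

test_that("GFF3 and FASTA inputs give the same database as in-memory tables", {
  set.seed(31)
  parent <- random_dna(500)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 test", parent), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t51\t350\t.\t+\t.\tID=gene1",
    "chr1\ttest\tCDS\t101\t300\t.\t+\t0\tID=cds1",
    "chr1\ttest\tCDS\t351\t450\t.\t-\t0\tID=cds2"
  ), gff)
  db_file <- build_crosshyb_db(fa, gff, flank = 100)
  db_mem <- build_crosshyb_db(
    tibble::tibble(id = "chr1", seq = parent),
    tibble::tibble(seqid = "chr1", start = c(101L, 351L),
                   end = c(300L, 450L), strand = c("+", "-"),
                   id = c("cds1", "cds2")),
    flank = 100)
  expect_equal(db_file$seq, db_mem$seq)
  expect_equal(nrow(db_file), 2)  # the gene feature is not extracted
})

test_that("kane_check finds embedded probes and ignores spaced mismatches", {
  set.seed(41)
  probe <- random_dna(23)
  target <- paste0(random_dna(80), probe, random_dna(80))
  res <- kane_check(probe, target)
  expect_equal(res$identity_pct, 100)
  expect_equal(res$longest_stretch, 23)
  expect_equal(res$position, 81)
  expect_equal(res$strand, "+")

  # 6 substitutions spaced across a 23-mer: 17/23 = 73.9%, stretch < 15
  ch <- strsplit(probe, "")[[1]]
  for (p in c(2, 6, 10, 14, 18, 22)) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  decoy_target <- paste0(random_dna(40), paste(ch, collapse = ""),
                         random_dna(40))
  res2 <- kane_check(probe, decoy_target)
  expect_equal(res2$identity_pct, 100 * 17 / 23, tolerance = 1e-10)
  expect_lt(res2$longest_stretch, 15)

  # exact 15-mer share flags the stretch criterion only
  kmer <- substr(probe, 5, 19)
  stretch_target <- paste0(random_dna(90), kmer, random_dna(95))
  res3 <- kane_check(probe, stretch_target)
  expect_gte(res3$longest_stretch, 15)
})

test_that("kane_check matches the brute-force oracle on random instances", {
  set.seed(53)
  for (rep in 1:150) {
    L <- sample(8:30, 1)
    probe <- random_degenerate(L, alphabet = c("A", "C", "G", "T", "I"))
    target <- random_dna(sample((L + 5):300, 1))
    got <- kane_check(probe, target)
    want <- oracle_kane(probe, target)
    expect_equal(got$identity_pct, want$identity_pct)
    expect_equal(got$longest_stretch, want$longest_stretch)
    expect_equal(got$position, want$position)
    expect_equal(got$strand, want$strand)
  }
})

test_that("probe inosine substitution never lowers identity or stretch", {
  set.seed(59)
  for (rep in 1:40) {
    probe <- random_dna(20)
    target <- random_dna(100)
    base <- kane_check(probe, target)
    p <- sample(20, 1)
    probe_i <- paste0(substr(probe, 1, p - 1), "I", substr(probe, p + 1, 20))
    with_i <- kane_check(probe_i, target)
    expect_gte(with_i$identity_pct, base$identity_pct)
    expect_gte(with_i$longest_stretch, base$longest_stretch)
  }
})

test_that("family membership recognizes backtranslated references only", {
  set.seed(61)
  ref <- random_protein(120)
  code <- genetic_code()
  cds <- paste(vapply(strsplit(ref, "")[[1]], function(a) {
    names(code)[code == a][1]
  }, character(1)), collapse = "")
  expect_true(family_membership(cds, ref))
  expect_false(family_membership(random_dna(nchar(cds)), ref))
  # minus-strand genes are found through the reverse-complement frames
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  expect_true(family_membership(rc, ref))
  # stop-rich sequences are still evaluated over all six frames
  stop_rich <- paste0(paste(rep("TAA", 20), collapse = ""), cds)
  expect_true(family_membership(stop_rich, ref))
})

test_that("screening rescues the source gene and counts planted decoys", {
  fam <- simulate_protein_family(seed = 71, reference_length = 40,
                                 n_members = 3, substitution_rate = 0.03,
                                 indel_rate = 0)
  ref_prot <- fam$proteins$seq[fam$proteins$id == "REF"]
  ref_cds <- fam$cds$seq[fam$cds$id == "REF"]
  d <- design_probes(fam$proteins, "REF",
                     design_params(24, 258, 0.09), gene = "g")
  cand <- d$candidates[1, ]

  # database holding only the source gene: everything is family, count 0
  db_self <- tibble::tibble(id = "self", seq = ref_cds)
  hits_self <- screen_probes(cand, db_self, ref_prot)
  expect_gt(nrow(hits_self), 0)
  expect_true(all(hits_self$classification == "target_family"))
  expect_true(any(hits_self$identity_pct == 100))
  counted <- add_crosshyb_counts(cand, hits_self)
  expect_equal(counted$crosshyb_count, 0L)

  # one planted decoy sharing a 16-mer, unrelated to the reference
  bg <- simulate_background_db(
    seed = 73, n_records = 3, length_range = c(200, 300),
    planted = tibble::tibble(probe = cand$seq, type = "stretch",
                             value = 16))
  db <- dplyr::bind_rows(db_self, bg$db)
  hits <- screen_probes(cand, db, ref_prot)
  decoy_hits <- dplyr::filter(hits, .data$target_id == bg$truth$id[[1]])
  expect_gt(nrow(decoy_hits), 0)
  expect_true(all(decoy_hits$classification == "cross_hybridization"))
  counted2 <- add_crosshyb_counts(cand, hits)
  expect_equal(counted2$crosshyb_count, 1L)
})

test_that("screening output does not depend on database record order", {
  fam <- simulate_protein_family(seed = 79, reference_length = 30,
                                 n_members = 2, substitution_rate = 0.05,
                                 indel_rate = 0)
  ref_prot <- fam$proteins$seq[fam$proteins$id == "REF"]
  cand <- design_probes(fam$proteins, "REF",
                        design_params(24, 258, 0.25),
                        gene = "g")$candidates[1, ]
  db <- tibble::tibble(
    id = c("self", "other"),
    seq = c(fam$cds$seq[fam$cds$id == "REF"],
            fam$cds$seq[fam$cds$id == "member_01"]))
  h1 <- screen_probes(cand, db, ref_prot)
  h2 <- screen_probes(cand, db[2:1, ], ref_prot)
  key <- function(h) dplyr::arrange(h, .data$target_id, .data$variant_seq,
                                    .data$target_start)[
    , c("variant_seq", "target_id", "strand", "target_start",
        "identity_pct", "longest_stretch", "classification")]
  expect_equal(key(h1), key(h2))
})

test_that("hit clustering links identical regions and separates unrelated ones", {
  seq_a <- random_dna(200)
  db <- tibble::tibble(id = c("t1", "t2", "t3"),
                       seq = c(seq_a, seq_a, random_dna(200)))
  hits <- tibble::tibble(
    probe_id = "p", variant_seq = substr(seq_a, 50, 72),
    target_id = c("t1", "t2", "t3"), strand = "+",
    target_start = c(50L, 50L, 50L),
    identity_pct = c(100, 100, 80), longest_stretch = c(23L, 23L, 10L),
    classification = "cross_hybridization"
  )
  out <- cluster_hits(hits, db, min_identity = 90)
  expect_equal(out$cluster_id[1], out$cluster_id[2])
  expect_false(out$cluster_id[3] == out$cluster_id[1])

  singleton <- cluster_hits(hits[1, ], db, min_identity = 90)
  expect_equal(singleton$cluster_id, 1L)
})
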