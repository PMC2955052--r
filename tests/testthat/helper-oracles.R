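# Independent oracles used to check the package implementations.

.oracle_sets <- local({
  s <- lapply(Biostrings::IUPAC_CODE_MAP, function(x) strsplit(x, "")[[1]])
  s$I <- c("A", "C", "G", "T")
  s
})

# brute-force cartesian expansion via expand.grid
oracle_expand <- function(seq, inosine_mode = "expand") {
  sets <- .oracle_sets
  if (inosine_mode == "keep") sets$I <- "I"
  cols <- lapply(strsplit(seq, "")[[1]], function(ch) sets[[ch]])
  grid <- expand.grid(rev(cols), stringsAsFactors = FALSE)
  sort(unique(apply(grid[, rev(seq_along(cols)), drop = FALSE], 1,
                    paste, collapse = "")))
}

# exhaustive all-offsets / both-strands ungapped scan
oracle_kane <- function(probe, target) {
  p <- strsplit(probe, "")[[1]]
  L <- length(p)
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  best_ident <- -1
  best_pos <- NA_integer_
  best_strand <- NA_character_
  best_stretch <- 0L
  for (strand in c("+", "-")) {
    t <- strsplit(if (strand == "+") target else rc(target), "")[[1]]
    if (length(t) < L) stop("probe longer than target")
    for (off in 0:(length(t) - L)) {
      hit <- p == "I" | p == t[(off + 1):(off + L)]
      ident <- 100 * sum(hit) / L
      if (ident > best_ident) {
        best_ident <- ident
        best_pos <- off + 1L
        best_strand <- strand
      }
      r <- rle(hit)
      runs <- r$lengths[r$values]
      if (length(runs) > 0L && max(runs) > best_stretch) {
        best_stretch <- max(runs)
      }
    }
  }
  list(identity_pct = best_ident, longest_stretch = best_stretch,
       position = best_pos, strand = best_strand)
}

# local Smith-Waterman with affine gaps (Gotoh); gap of length g costs
# open + g * ext, matching the scoring used by score_homologs()
oracle_sw <- function(a, b, open = 11, ext = 1) {
  mat <- .blosum62()
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                          Iy[i - 1, j - 1]) + mat[A[i - 1], B[j - 1]])
    best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
  }
  best
}

.blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      data("BLOSUM62", package = "Biostrings", envir = env)
      env$m <- env$BLOSUM62
    }
    env$m
  }
})

random_degenerate <- function(len, alphabet = names(.oracle_sets)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# fabricate a consensus object from a raw degenerate string (codon map is
# irrelevant to window enumeration)
fake_consensus <- function(seq) {
  structure(list(seq = seq,
                 codon_map = tibble::tibble(codon_index = integer(),
                                            aln_column = integer(),
                                            ref_residue = integer(),
                                            aa_set = list(),
                                            codon = character()),
                 reference_id = "ref", code_id = "1"),
            class = "degenerate_consensus")
}

# the published 23-mer degenerate probe set (printed probe table), with
# the printed specific-probe counts; bphB_MD_B carries an inconsistency
# between its printed sequence and count and is excluded where noted
published_probes <- function() {
  tibble::tibble(
    probe_id = c("phnA1a_MD_A", "phnA1a_MD_B", "phnA2a_MD_A",
                 "phnA2a_MD_B", "ahdA1c_MD_A", "ahdA1c_MD_B",
                 "ahdA2c_MD_A", "ahdA2c_MD_B", "bphB_MD_A", "bphB_MD_B",
                 "bphC_MD_A", "bphC_MD_B", "bphA3_MD_A", "bphA3_MD_B",
                 "ahdA4_MD_A", "ahdA4_MD_B"),
    seq = c("GTITGYAAYTAYCAYGGITGGGT", "CAYGARATHGARGTITGGACITA",
            "GARGAYATHCAYTAYTGGATGCC", "GGICARGTITGGATGGARGAYCC",
            "GARTGYGTITAYCAYCARTGGGC", "GAYGCIGCIGAYAARCARGCITA",
            "GAYGAYMGIYTIGARGARTGGCC", "ATHGAYACIATGATGGTIMGICC",
            "AAYGTIGGIATHTGGGAYTWYAT", "AAYBTIAARGGITAYTTYTTYGG",
            "CCITAYTTYATGCAYTGYAAYGA", "TGGYTITGGGARTTYGGITGGGG",
            "ATHATHGARTGYCCITTYCAYGG", "ATHGAIGAYGGITGGGTITGYAT",
            "GCIAAYGTICCIGAYAAYTTYTT", "CARGARACITAYCARAAYGCIGC"),
    n_specific = c(256, 384, 48, 128, 128, 1024, 1024, 768, 768, 384,
                   128, 128, 576, 768, 1024, 512)
  )
}
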