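# Homolog mining against a local protein database: local alignment
# scoring with Karlin-Altschul E-value estimates, threshold selection,
# and the size-divergence prefilter applied before multiple alignment.

.ka_lambda <- 0.267  # gapped BLOSUM62 (gap open 11 / extend 1)
.ka_K <- 0.041

.check_protein <- function(seq, ids = NULL) {
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYBZX*]+$", seq)
  if (!all(ok)) {
    who <- if (is.null(ids)) seq[!ok][[1]] else ids[!ok][[1]]
    abort(sprintf("illegal residues in protein record '%s'", who))
  }
  invisible(seq)
}

#' Score a protein database against a reference query
#'
#' Computes, for every subject, the best local (Smith-Waterman, affine
#' gaps) alignment score against the reference protein, converts it to a
#' bit score with Karlin-Altschul statistics and estimates an expectation
#' value over the search space. E-values are estimates on a fixed
#' statistical scale (lambda = 0.267, K = 0.041, the standard gapped
#' BLOSUM62 constants); they are comparable across runs of this function
#' but are not NCBI BLAST E-values.
#'
#' @param db Tibble with columns `id`, `seq` (protein sequences).
#' @param reference Reference protein sequence (single string).
#' @param matrix Substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_ext Affine gap penalties (a gap of length g costs
#'   `gap_open + g * gap_ext`).
#' @param lambda,K Karlin-Altschul constants for the bit-score transform
#'   `bit = (lambda * raw - ln K) / ln 2`.
#' @param search_space Effective search space `m * n`; defaults to
#'   `nchar(reference)` times the total subject length.
#' @return Tibble with columns `subject_id`, `raw_score`, `bitscore`,
#'   `evalue_est`, `subject_length`, sorted by increasing `evalue_est`
#'   (ties broken by `subject_id`).
#' @export
score_homologs <- function(db, reference, matrix = "BLOSUM62",
                           gap_open = 11, gap_ext = 1,
                           lambda = .ka_lambda, K = .ka_K,
                           search_space = NULL) {
  stopifnot(is.data.frame(db), all(c("id", "seq") %in% names(db)),
            length(reference) == 1L, nchar(reference) > 0L)
  if (nrow(db) == 0L) abort("empty protein database")
  .check_protein(reference, "reference")
  .check_protein(db$seq, db$id)
  search_space <- search_space %||% (nchar(reference) * sum(nchar(db$seq)))
  raw <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(db$seq),
    subject = Biostrings::AAString(reference),
    type = "local", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_ext,
    scoreOnly = TRUE
  )
  raw <- pmax(raw, 0)
  bit <- (lambda * raw - log(K)) / log(2)
  tibble(
    subject_id = db$id,
    raw_score = raw,
    bitscore = bit,
    evalue_est = search_space * 2^(-bit),
    subject_length = nchar(db$seq)
  ) |>
    dplyr::arrange(.data$evalue_est, .data$subject_id)
}

#' Select hits under an E-value threshold
#'
#' @param hits Hit tibble from [score_homologs()].
#' @param evalue_max Maximum estimated E-value (inclusive).
#' @return The filtered tibble, input order preserved.
#' @export
select_by_threshold <- function(hits, evalue_max) {
  stopifnot(is.data.frame(hits), "evalue_est" %in% names(hits))
  dplyr::filter(hits, .data$evalue_est <= evalue_max)
}

#' Prefilter sequences by size divergence from the reference
#'
#' Before multiple alignment, sequences whose length diverges strongly
#' from the reference are excluded to limit indel-rich alignment regions.
#' A sequence is kept iff `|len - len(ref)| <= tolerance * len(ref)`
#' (inclusive); a record identical to the reference is always kept.
#'
#' @param seqs Tibble with columns `id`, `seq`.
#' @param reference Reference protein sequence.
#' @param tolerance Fraction of the reference length (default 0.20).
#' @return The filtered tibble.
#' @export
filter_by_size_divergence <- function(seqs, reference, tolerance = 0.20) {
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)),
            tolerance >= 0, tolerance <= 1)
  ref_len <- nchar(reference)
  dplyr::filter(
    seqs,
    abs(nchar(.data$seq) - ref_len) <= tolerance * ref_len |
      .data$seq == reference
  )
}
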