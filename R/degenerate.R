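# Core degenerate-codon algebra: backtranslation of amino-acid sets into
# IUPAC/inosine codons, degeneracy arithmetic, probe expansion and
# in-frame translation of degenerate windows.

#' Backtranslate a set of amino acids into a degenerate codon
#'
#' Takes the union of all codons of all amino acids in `aas` and collapses
#' it position-wise into IUPAC ambiguity codes. Any codon position whose
#' base set is all four bases (IUPAC `N`) is rewritten to inosine `I`, the
#' universal base used at fully degenerate positions. Stop codons never
#' enter the union. The amino-acid ambiguity symbols `B` (Asp/Asn) and `Z`
#' (Glu/Gln) are expanded to their constituent residues.
#'
#' @param aas Character vector of one-letter amino-acid symbols (a set; an
#'   ambiguity symbol `B`/`Z` is allowed, `X` and gaps are not).
#' @param code Genetic code from [genetic_code()].
#' @return A 3-character degenerate codon string.
#' @examples
#' backtranslate_column("W")            # "TGG"
#' backtranslate_column("G")            # "GGI": GGN rewritten to GGI
#' backtranslate_column(c("D", "E"))    # "GAI"
#' @export
backtranslate_column <- function(aas, code = genetic_code()) {
  aas <- unique(toupper(aas))
  if (length(aas) == 0L) abort("empty amino-acid set")
  expanded <- unlist(lapply(aas, function(a) {
    if (a %in% names(.aa_ambiguity)) .aa_ambiguity[[a]] else a
  }))
  unknown <- setdiff(expanded, c(.standard_aas, "*"))
  if (length(unknown) > 0L) {
    abort(sprintf("unknown amino-acid symbol: '%s'", unknown[[1]]))
  }
  expanded <- setdiff(expanded, "*")  # stop codons excluded from unions
  if (length(expanded) == 0L) {
    abort("amino-acid set contains only STOP")
  }
  codons <- names(code)[code %in% expanded]
  if (length(codons) == 0L) {
    abort(sprintf("no codons for amino acids: %s",
                  paste(expanded, collapse = ",")))
  }
  mat <- do.call(rbind, strsplit(codons, ""))
  triplet <- vapply(1:3, function(p) {
    key <- paste(sort(unique(mat[, p])), collapse = "")
    sym <- .iupac_lookup[[key]]
    if (identical(sym, "N")) "I" else sym
  }, character(1))
  paste(triplet, collapse = "")
}

#' Degeneracy of a degenerate sequence
#'
#' Product over positions of the base-set cardinality, with inosine
#' counted as 1: an inosine position is a single synthesized residue, so
#' it does not multiply the number of oligos in the design sense.
#'
#' @param seq Character vector of degenerate sequences.
#' @return Numeric vector of degeneracies (>= 1).
#' @examples
#' degeneracy("AYI")  # 2
#' @seealso [total_degeneracy()] for the synthesis-side count with I = 4.
#' @export
degeneracy <- function(seq) {
  check_degenerate(seq)
  sizes <- c(vapply(.degen_sets, length, integer(1)))
  sizes["I"] <- 1L
  vapply(strsplit(seq, ""), function(ch) {
    if (length(ch) == 0L) return(1)
    prod(sizes[ch])
  }, numeric(1))
}

#' Total degeneracy (inosine counted as four-fold)
#'
#' Product over positions of the base-set cardinality with inosine counted
#' as 4. This equals the number of fully specified probe variants produced
#' by in-situ expansion, where every inosine is synthesized as each of the
#' four bases.
#'
#' @inheritParams degeneracy
#' @return Numeric vector.
#' @examples
#' total_degeneracy("GTITGYAAYTAYCAYGGITGGGT")  # 256
#' @export
total_degeneracy <- function(seq) {
  check_degenerate(seq)
  sizes <- c(vapply(.degen_sets, length, integer(1)))
  vapply(strsplit(seq, ""), function(ch) {
    if (length(ch) == 0L) return(1)
    prod(sizes[ch])
  }, numeric(1))
}

#' Number of inosine residues
#'
#' @inheritParams degeneracy
#' @return Integer vector.
#' @export
inosine_count <- function(seq) {
  check_degenerate(seq)
  stringr::str_count(seq, stringr::fixed("I"))
}

#' Expand a degenerate sequence into fully specified variants
#'
#' @param seq A single degenerate sequence.
#' @param inosine_mode `"expand"` substitutes each inosine by all four
#'   bases (in-situ synthesis; `total_degeneracy(seq)` variants);
#'   `"keep"` retains `I` as a literal residue (ex-situ synthesis with
#'   inosine; `degeneracy(seq)` variants).
#' @param cap Refuse expansions larger than this many variants.
#' @return Character vector of distinct variants, lexicographically
#'   sorted.
#' @examples
#' expand_probe("AY")           # "AC" "AT"
#' expand_probe("AIC", "keep")  # "AIC"
#' @export
expand_probe <- function(seq, inosine_mode = c("expand", "keep"),
                         cap = 1e6) {
  stopifnot(length(seq) == 1L)
  inosine_mode <- match.arg(inosine_mode)
  check_degenerate(seq)
  n_var <- if (inosine_mode == "expand") total_degeneracy(seq) else degeneracy(seq)
  if (n_var > cap) {
    abort(sprintf(
      "expansion of '%s' yields %s variants, above the cap of %s",
      seq, format(n_var, big.mark = ","), format(cap, big.mark = ",")))
  }
  sets <- .degen_sets
  if (inosine_mode == "keep") sets$I <- "I"
  out <- ""
  for (ch in strsplit(seq, "")[[1]]) {
    bases <- sets[[ch]]
    out <- paste0(rep(out, each = length(bases)), bases)
  }
  sort(unique(out))
}

#' Translate a degenerate window in a fixed frame
#'
#' Translates every expanded variant (inosine as any base) of the complete
#' codons inside the window, in the given frame; leading and trailing
#' partial codons are dropped. Peptides whose variant contains an in-frame
#' stop are reported separately, not silently discarded.
#'
#' @param seq A single degenerate sequence (e.g. a probe window).
#' @param frame_offset 0, 1 or 2: number of leading bases skipped.
#' @param code Genetic code from [genetic_code()].
#' @return A list with `peptides` (distinct stop-free peptides) and
#'   `stopped` (distinct peptides containing `*`).
#' @examples
#' translate_in_frame("CAYTGG")$peptides  # "HW"
#' @export
translate_in_frame <- function(seq, frame_offset = 0, code = genetic_code()) {
  stopifnot(length(seq) == 1L, frame_offset %in% 0:2)
  check_degenerate(seq)
  n <- nchar(seq)
  n_codons <- (n - frame_offset) %/% 3
  if (n_codons < 1L) {
    abort(sprintf(
      "window of %d nt has no complete codon in frame %d", n, frame_offset))
  }
  # per-codon amino-acid sets; the cartesian product over codons equals
  # translating every expanded variant because translation factorizes
  aa_sets <- lapply(seq_len(n_codons), function(i) {
    codon <- substr(seq, frame_offset + 3L * (i - 1L) + 1L,
                    frame_offset + 3L * i)
    unique(unname(code[expand_probe(codon, "expand")]))
  })
  peps <- Reduce(function(acc, aas) {
    as.vector(outer(acc, aas, paste0))
  }, aa_sets, accumulate = FALSE, init = "")
  peps <- sort(unique(peps))
  has_stop <- grepl("*", peps, fixed = TRUE)
  list(peptides = peps[!has_stop], stopped = peps[has_stop])
}
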