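# Degenerate nucleotide alphabet: the 15 IUPAC codes plus inosine (I).
# I represents a universal base: it pairs with any of A/C/G/T during
# hybridization and matching, but counts as a single synthesized residue,
# so it contributes 1 to the design degeneracy and 4 to the total
# degeneracy used at synthesis.

#' IUPAC + inosine base sets
#'
#' Mapping from each symbol of the degenerate probe alphabet
#' (`A C G T R Y S W K M B D H V N I`) to the set of unambiguous bases it
#' stands for. Inosine (`I`) maps to all four bases for matching and
#' expansion purposes.
#'
#' @return A named list of character vectors.
#' @examples
#' degenerate_base_sets()[["Y"]]
#' @export
degenerate_base_sets <- function() {
  sets <- lapply(Biostrings::IUPAC_CODE_MAP, function(x) strsplit(x, "")[[1]])
  sets$I <- c("A", "C", "G", "T")
  sets
}

# single source of truth used internally (built once at load)
.degen_sets <- NULL
.iupac_lookup <- NULL

.onLoad <- function(libname, pkgname) {
  sets <- lapply(Biostrings::IUPAC_CODE_MAP, function(x) strsplit(x, "")[[1]])
  sets$I <- c("A", "C", "G", "T")
  utils::assignInMyNamespace(".degen_sets", sets)
  # reverse map: sorted base-set string -> IUPAC code (N, not I: the N->I
  # rewrite is a design-layer decision, see backtranslate_column())
  base_sets <- vapply(
    Biostrings::IUPAC_CODE_MAP,
    function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""),
    character(1)
  )
  utils::assignInMyNamespace(".iupac_lookup",
                             stats::setNames(names(base_sets), base_sets))
}

#' Load a genetic code table
#'
#' Returns the codon table for an NCBI translation-table identifier as a
#' named character vector mapping each of the 64 codons (DNA alphabet) to
#' an amino acid one-letter symbol or `*` for stop.
#'
#' @param id NCBI translation-table identifier (default `"1"`, the
#'   standard code).
#' @return Named character vector of length 64.
#' @examples
#' code <- genetic_code()
#' code[["TGG"]]
#' @export
genetic_code <- function(id = "1") {
  code <- Biostrings::getGeneticCode(as.character(id))
  stopifnot(length(code) == 64L)
  attr(code, "id") <- as.character(id)
  code
}

# amino-acid ambiguity symbols expandable to standard residues
.aa_ambiguity <- list(B = c("D", "N"), Z = c("E", "Q"))

.standard_aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                   "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Validate a degenerate sequence
#'
#' Checks that every character of `seq` belongs to the degenerate probe
#' alphabet (IUPAC codes plus `I`).
#'
#' @param seq Character vector of sequences.
#' @return Invisibly, `seq`; errors on the first offending symbol.
#' @keywords internal
check_degenerate <- function(seq) {
  ok <- grepl("^[ACGTRYSWKMBDHVNI]*$", seq)
  if (!all(ok)) {
    bad <- seq[!ok][[1]]
    abort(sprintf("not a degenerate nucleotide sequence: '%s'", bad))
  }
  invisible(seq)
}
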