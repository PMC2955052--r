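# Degenerate consensus construction from a protein multiple alignment,
# probe-window enumeration under degeneracy/inosine thresholds, last-base
# trimming and multi-criteria ranking.

#' Probe design parameters
#'
#' @param probe_length Probe window length in nucleotides (default 24, a
#'   compromise between specificity and sensitivity for short oligo
#'   arrays).
#' @param degeneracy_max Maximum design degeneracy (inosine counted as 1).
#'   The two published strategies are 129 with 25% inosine and 258 with
#'   9% inosine.
#' @param inosine_max_fraction Maximum inosine content as a fraction of
#'   probe length.
#' @param trim_last_base Whether the last base of each probe (usually a
#'   degenerate base or inosine arising from third-codon-position
#'   redundancy) is removed before synthesis.
#' @param expansion_mode `"expand"` (in-situ synthesis: inosine expanded
#'   to all four bases) or `"keep"` (ex-situ: inosine retained).
#' @param expansion_cap Refuse probe expansions above this variant count.
#' @return A `design_params` list.
#' @examples
#' design_params(degeneracy_max = 258, inosine_max_fraction = 0.09)
#' @export
design_params <- function(probe_length = 24, degeneracy_max = 129,
                          inosine_max_fraction = 0.25,
                          trim_last_base = TRUE,
                          expansion_mode = c("expand", "keep"),
                          expansion_cap = 1e6) {
  expansion_mode <- match.arg(expansion_mode)
  stopifnot(probe_length >= 3, degeneracy_max >= 1,
            inosine_max_fraction >= 0, inosine_max_fraction <= 1)
  structure(
    list(probe_length = as.integer(probe_length),
         degeneracy_max = degeneracy_max,
         inosine_max_fraction = inosine_max_fraction,
         trim_last_base = isTRUE(trim_last_base),
         expansion_mode = expansion_mode,
         expansion_cap = expansion_cap),
    class = "design_params"
  )
}

#' Maximum total degeneracy attainable under design parameters
#'
#' A probe passing the thresholds has design degeneracy at most
#' `degeneracy_max` and at most `floor(probe_length *
#' inosine_max_fraction)` inosines, each worth a factor 4 at expansion,
#' so the largest possible variant count is
#' `degeneracy_max * 4^floor(probe_length * inosine_max_fraction)`.
#'
#' @param params A [design_params()] object.
#' @return Integer-valued numeric.
#' @examples
#' max_total_degeneracy(design_params(24, 129, 0.25))  # 528384
#' max_total_degeneracy(design_params(24, 258, 0.09))  # 4128
#' @export
max_total_degeneracy <- function(params) {
  stopifnot(inherits(params, "design_params"))
  n_inosine <- floor(params$probe_length * params$inosine_max_fraction +
                       sqrt(.Machine$double.eps))
  params$degeneracy_max * 4^n_inosine
}

#' Build a degenerate nucleic consensus from a protein alignment
#'
#' Every alignment column where the reference has a residue is
#' backtranslated: the column's amino-acid set (gaps and `X` excluded)
#' is mapped to the IUPAC union of all its codons via
#' [backtranslate_column()], with fully degenerate positions written as
#' inosine. Columns where the reference is gapped are skipped, so the
#' consensus coordinate system is the ungapped reference CDS (3 nt per
#' reference residue).
#'
#' @param aln Tibble with columns `id`, `seq`: aligned protein sequences
#'   of equal length, gaps as `-`.
#' @param reference_id `id` of the reference row.
#' @param code Genetic code from [genetic_code()].
#' @return A `degenerate_consensus` object with elements `seq` (the
#'   degenerate nucleotide string), `codon_map` (tibble: codon index,
#'   alignment column, reference residue index, amino-acid set, codon)
#'   and `reference_id`.
#' @export
build_consensus <- function(aln, reference_id, code = genetic_code()) {
  stopifnot(is.data.frame(aln), all(c("id", "seq") %in% names(aln)),
            nrow(aln) >= 1L)
  if (!reference_id %in% aln$id) {
    abort(sprintf("reference '%s' not found in alignment", reference_id))
  }
  widths <- unique(nchar(aln$seq))
  if (length(widths) != 1L) abort("aligned sequences must have equal length")
  aln <- dplyr::distinct(aln, .data$id, .data$seq)  # duplicates carry no info
  mat <- do.call(rbind, strsplit(toupper(aln$seq), ""))
  ref_row <- mat[match(reference_id, aln$id), ]
  keep_cols <- which(!ref_row %in% c("-", "."))
  if (length(keep_cols) == 0L) abort("reference is all gaps")
  codons <- character(length(keep_cols))
  aa_sets <- vector("list", length(keep_cols))
  for (k in seq_along(keep_cols)) {
    col <- keep_cols[[k]]
    aas <- setdiff(unique(mat[, col]), c("-", ".", "X"))
    if (length(aas) == 0L) {
      abort(sprintf("alignment column %d empty after gap/X exclusion", col))
    }
    aa_sets[[k]] <- aas
    codons[[k]] <- backtranslate_column(aas, code)
  }
  structure(
    list(
      seq = paste(codons, collapse = ""),
      codon_map = tibble(
        codon_index = seq_along(keep_cols),
        aln_column = keep_cols,
        ref_residue = seq_along(keep_cols),
        aa_set = aa_sets,
        codon = codons
      ),
      reference_id = reference_id,
      code_id = attr(code, "id") %||% "1"
    ),
    class = "degenerate_consensus"
  )
}

#' @export
print.degenerate_consensus <- function(x, ...) {
  cat(sprintf(
    "Degenerate consensus (%d nt, %d codons) on reference '%s'\n",
    nchar(x$seq), nrow(x$codon_map), x$reference_id))
  cat(sprintf("  degeneracy %s, total degeneracy %s, %d inosines\n",
              format(degeneracy(x$seq), big.mark = ","),
              format(total_degeneracy(x$seq), big.mark = ","),
              inosine_count(x$seq)))
  invisible(x)
}

#' Enumerate candidate probe windows from a consensus
#'
#' Slides a window of `probe_length` nucleotides along the consensus at
#' step 1 (windows need not be codon-aligned) and keeps every window
#' whose design degeneracy and inosine fraction are within the thresholds
#' (inclusive). Coordinates are 1-based inclusive on the ungapped
#' reference CDS.
#'
#' @param consensus A [build_consensus()] result.
#' @param params A [design_params()] object.
#' @param gene Gene name used to format probe ids (`<gene>_<region>_<i>`).
#' @param region Region label within the probe id (default `"MD"`).
#' @return Tibble of candidates: `probe_id`, `seq`, `start_nt`, `end_nt`,
#'   `degeneracy`, `inosine_count`, `total_degeneracy`, `crosshyb_count`
#'   (`NA` until screened), ordered by `start_nt`.
#' @export
enumerate_probes <- function(consensus, params = design_params(),
                             gene = "gene", region = "MD") {
  stopifnot(inherits(consensus, "degenerate_consensus"),
            inherits(params, "design_params"))
  L <- params$probe_length
  s <- consensus$seq
  n <- nchar(s)
  if (n < L) {
    warn(sprintf("consensus (%d nt) shorter than probe length %d", n, L))
    return(tibble(probe_id = character(), seq = character(),
                  start_nt = integer(), end_nt = integer(),
                  degeneracy = numeric(), inosine_count = integer(),
                  total_degeneracy = numeric(), crosshyb_count = integer()))
  }
  starts <- seq_len(n - L + 1L)
  windows <- stringr::str_sub(s, starts, starts + L - 1L)
  deg <- degeneracy(windows)
  ino <- inosine_count(windows)
  keep <- deg <= params$degeneracy_max &
    ino / L <= params$inosine_max_fraction + sqrt(.Machine$double.eps)
  out <- tibble(
    probe_id = character(sum(keep)),
    seq = windows[keep],
    start_nt = starts[keep],
    end_nt = starts[keep] + L - 1L,
    degeneracy = deg[keep],
    inosine_count = ino[keep],
    total_degeneracy = total_degeneracy(windows[keep]),
    crosshyb_count = NA_integer_
  )
  out$probe_id <- sprintf("%s_%s_%03d", gene, region, seq_len(nrow(out)))
  out
}

#' Trim the last base of each candidate probe
#'
#' The final nucleotide of an enumerated probe is usually a degenerate
#' base or an inosine (third codon position), so removing it shrinks the
#' synthesized probe set at negligible cost in coverage. Degeneracy
#' metrics are recomputed and `end_nt` decremented.
#'
#' @param candidates Candidate tibble from [enumerate_probes()].
#' @return The trimmed candidate tibble.
#' @export
trim_probes <- function(candidates) {
  stopifnot(is.data.frame(candidates), "seq" %in% names(candidates))
  if (nrow(candidates) == 0L) return(candidates)
  if (any(nchar(candidates$seq) < 2L)) {
    abort("cannot trim a length-1 probe")
  }
  dplyr::mutate(
    candidates,
    seq = stringr::str_sub(.data$seq, 1L, -2L),
    end_nt = .data$end_nt - 1L,
    degeneracy = degeneracy(.data$seq),
    inosine_count = inosine_count(.data$seq),
    total_degeneracy = total_degeneracy(.data$seq)
  )
}

#' Rank candidate probes and optionally select spaced representatives
#'
#' Candidates are ordered by (1) ascending cross-hybridization count, so
#' the most specific probes come first, then (2) ascending total
#' degeneracy, to limit the number of synthesized variants, and (3) when
#' `k` probes are requested, a greedy spacing rule over reference
#' coordinates: the first-ranked candidate is fixed, and each subsequent
#' pick maximizes the minimum start-coordinate distance to the probes
#' already picked (within the (1)-(2) ordering).
#'
#' @param candidates Candidate tibble with `crosshyb_count` populated
#'   (`NA` is treated as 0, i.e. unscreened candidates are assumed
#'   specific).
#' @param k Number of probes to select; `NULL` returns the full ranking.
#' @return Reordered (and possibly subset) candidate tibble.
#' @export
rank_probes <- function(candidates, k = NULL) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) return(candidates)
  cands <- dplyr::mutate(
    candidates,
    .xh = dplyr::coalesce(.data$crosshyb_count, 0L)
  ) |>
    dplyr::arrange(.data$.xh, .data$total_degeneracy, .data$start_nt)
  if (is.null(k)) {
    return(dplyr::select(cands, -".xh"))
  }
  k <- min(k, nrow(cands))
  picked <- 1L
  while (length(picked) < k) {
    remaining <- setdiff(seq_len(nrow(cands)), picked)
    # lexicographic objective: score rank, then max-min spacing
    min_dist <- vapply(remaining, function(i) {
      min(abs(cands$start_nt[i] - cands$start_nt[picked]))
    }, numeric(1))
    key <- order(cands$.xh[remaining], cands$total_degeneracy[remaining],
                 -min_dist, cands$start_nt[remaining])
    picked <- c(picked, remaining[key[[1]]])
  }
  dplyr::select(cands[picked, ], -".xh")
}

#' Expand candidate probes into fully specified probe sets
#'
#' @param candidates Candidate tibble from [enumerate_probes()].
#' @param inosine_mode,cap See [expand_probe()].
#' @return Tibble with `probe_id`, `variant_id` (probe id suffixed with a
#'   4-digit ordinal), `variant_seq`.
#' @export
expand_probes <- function(candidates, inosine_mode = c("expand", "keep"),
                          cap = 1e6) {
  inosine_mode <- match.arg(inosine_mode)
  stopifnot(is.data.frame(candidates),
            all(c("probe_id", "seq") %in% names(candidates)))
  purrr::map2_dfr(candidates$probe_id, candidates$seq, function(id, s) {
    variants <- expand_probe(s, inosine_mode, cap)
    tibble(
      probe_id = id,
      variant_id = sprintf("%s_%04d", id, seq_along(variants)),
      variant_seq = variants
    )
  })
}

#' @export
tidy.degenerate_consensus <- function(x, ...) {
  dplyr::mutate(
    x$codon_map,
    degeneracy = degeneracy(.data$codon),
    inosine_count = inosine_count(.data$codon)
  )
}

#' @export
glance.degenerate_consensus <- function(x, ...) {
  tibble(
    reference_id = x$reference_id,
    length_nt = nchar(x$seq),
    n_codons = nrow(x$codon_map),
    degeneracy = degeneracy(x$seq),
    total_degeneracy = total_degeneracy(x$seq),
    inosine_count = inosine_count(x$seq)
  )
}
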