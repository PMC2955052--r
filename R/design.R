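# High-level pipeline wrappers tying the stages together: alignment ->
# consensus -> candidate enumeration -> trimming -> expansion, and
# candidate screening -> counting -> ranking.

#' Design degenerate probes from a protein multiple alignment
#'
#' Runs [build_consensus()], [enumerate_probes()], optional last-base
#' trimming ([trim_probes()]) and expansion ([expand_probes()]).
#'
#' @param aln Alignment tibble (`id`, `seq`; see [read_alignment()]).
#' @param reference_id Reference row id.
#' @param params A [design_params()] object.
#' @param gene Gene name for probe ids.
#' @param code Genetic code.
#' @return List: `consensus` (a `degenerate_consensus`), `candidates`
#'   (tibble, trimmed if requested), `expanded` (tibble of fully
#'   specified variants).
#' @export
design_probes <- function(aln, reference_id, params = design_params(),
                          gene = "gene", code = genetic_code()) {
  consensus <- build_consensus(aln, reference_id, code)
  candidates <- enumerate_probes(consensus, params, gene = gene)
  if (params$trim_last_base && nrow(candidates) > 0L) {
    candidates <- trim_probes(candidates)
  }
  expanded <- expand_probes(candidates, params$expansion_mode,
                            params$expansion_cap)
  list(consensus = consensus, candidates = candidates, expanded = expanded)
}

#' Screen, count and rank designed probes
#'
#' Runs [screen_probes()], fills per-candidate cross-hybridization
#' cluster counts with [add_crosshyb_counts()], and orders candidates
#' with [rank_probes()].
#'
#' @param candidates Candidate tibble.
#' @param db Background database tibble (see [build_crosshyb_db()]).
#' @param reference_protein Reference protein sequence.
#' @param params A [screen_params()] object.
#' @param k Number of spaced probes to select (`NULL` = full ranking).
#' @return List: `hits` (flagged hit tibble), `candidates` (ranked, with
#'   `crosshyb_count`).
#' @export
screen_and_rank <- function(candidates, db, reference_protein,
                            params = screen_params(), k = NULL) {
  hits <- screen_probes(candidates, db, reference_protein, params)
  counted <- add_crosshyb_counts(candidates, hits)
  list(hits = hits, candidates = rank_probes(counted, k))
}

#' Probe-map plot of candidates along the reference
#'
#' Draws each candidate as a segment over its reference coordinates at
#' its total degeneracy (log scale), coloured by cross-hybridization
#' count when available.
#'
#' @param candidates Candidate tibble.
#' @return A ggplot object.
#' @export
plot_probe_map <- function(candidates) {
  stopifnot(is.data.frame(candidates), nrow(candidates) > 0L)
  cands <- dplyr::mutate(
    candidates,
    crosshyb = factor(dplyr::coalesce(.data$crosshyb_count, 0L)))
  ggplot2::ggplot(cands,
                  ggplot2::aes(x = .data$start_nt, xend = .data$end_nt,
                               y = .data$total_degeneracy,
                               yend = .data$total_degeneracy,
                               colour = .data$crosshyb)) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "reference CDS position (nt)",
                  y = "total degeneracy",
                  colour = "cross-hyb\nclusters") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.degenerate_consensus <- function(object, ...) {
  per_codon <- tidy(object)
  ggplot2::ggplot(per_codon,
                  ggplot2::aes(x = .data$ref_residue,
                               y = .data$degeneracy)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = dplyr::filter(per_codon,
                                             .data$inosine_count > 0),
                        colour = "firebrick", size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "reference residue", y = "codon degeneracy",
                  title = "Consensus degeneracy profile (inosine codons in red)") +
    ggplot2::theme_minimal()
}
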