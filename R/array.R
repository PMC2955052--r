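# Spatially segmented SNR' analysis of spotted-array feature tables.
# Background noise is measured from random control probes within each of
# (by default) 16 sub-squares of the array surface; each spot's signal is
# reduced-centralized as SNR' = (intensity - Bposition) / Bdispersion and
# probes are called positive when the replicate-median SNR' exceeds 3.

#' Assign features to spatial sub-squares
#'
#' The `[min, max]` range of `x` and of `y` is divided into `cols` and
#' `rows` equal intervals, half-open on the right except the last, which
#' is closed; a feature on an internal boundary therefore falls in the
#' higher-index interval. `square_index = row * cols + col` (0-based).
#'
#' @param features Feature tibble with columns `x`, `y` (at least).
#' @param rows,cols Grid dimensions (default 4 x 4 = 16 sub-squares).
#' @return `features` with a `square_index` column.
#' @export
segment_grid <- function(features, rows = 4, cols = 4) {
  stopifnot(is.data.frame(features), nrow(features) >= 1L,
            all(c("x", "y") %in% names(features)),
            all(is.finite(features$x)), all(is.finite(features$y)))
  cut_axis <- function(v, n) {
    rng <- range(v)
    if (rng[1] == rng[2]) {
      if (n > 1L) {
        abort("all features at a single point; cannot segment the grid")
      }
      return(rep(0L, length(v)))
    }
    idx <- floor((v - rng[1]) / (rng[2] - rng[1]) * n)
    pmin(as.integer(idx), n - 1L)  # closed last interval
  }
  dplyr::mutate(features,
                square_index = cut_axis(.data$y, rows) * cols +
                  cut_axis(.data$x, cols))
}

#' Background statistics per sub-square from random control probes
#'
#' `b_position` is the median intensity of the random probes in the
#' square; `b_dispersion` is a robust scale estimate of the same values
#' (by default 1.4826 x median absolute deviation), floored at
#' `floor_eps`. Squares with fewer than `min_random` random probes fall
#' back to whole-array random-probe statistics with a warning.
#'
#' @param features Segmented feature tibble (see [segment_grid()]) with
#'   `intensity` and `probe_class` (`"target"` / `"random"`).
#' @param min_random Minimum random probes per square (default 10).
#' @param dispersion Scale estimator: `"mad"` (1.4826 MAD), `"iqr"`
#'   (IQR/1.349) or `"sd"`.
#' @param floor_eps Lower bound on `b_dispersion` (must be > 0).
#' @return Tibble: `square_index`, `b_position`, `b_dispersion`,
#'   `n_random`.
#' @export
background_stats <- function(features, min_random = 10,
                             dispersion = c("mad", "iqr", "sd"),
                             floor_eps = 1e-6) {
  dispersion <- match.arg(dispersion)
  stopifnot(is.data.frame(features),
            all(c("square_index", "intensity", "probe_class") %in%
                  names(features)),
            floor_eps > 0)
  disp_fun <- switch(dispersion,
                     mad = function(v) stats::mad(v, constant = 1.4826),
                     iqr = function(v) stats::IQR(v) / 1.349,
                     sd = stats::sd)
  rand <- dplyr::filter(features, .data$probe_class == "random")
  if (nrow(rand) == 0L) {
    abort("no random control probes: background is not measurable")
  }
  global <- tibble(
    b_position = stats::median(rand$intensity),
    b_dispersion = max(disp_fun(rand$intensity), floor_eps)
  )
  out <- rand |>
    dplyr::group_by(.data$square_index) |>
    dplyr::summarise(
      b_position = stats::median(.data$intensity),
      b_dispersion = max(disp_fun(.data$intensity), floor_eps),
      n_random = dplyr::n(), .groups = "drop"
    )
  # squares present in the data but short of random probes
  all_sq <- sort(unique(features$square_index))
  out <- dplyr::left_join(tibble(square_index = all_sq), out,
                          by = "square_index")
  low <- is.na(out$n_random) | out$n_random < min_random
  if (any(low)) {
    warn(sprintf(
      "%d sub-square(s) have fewer than %d random probes; using whole-array background there",
      sum(low), min_random))
    out$b_position[low] <- global$b_position
    out$b_dispersion[low] <- global$b_dispersion
    out$n_random[low] <- dplyr::coalesce(out$n_random[low], 0L)
  }
  out
}

#' Compute SNR' for every feature
#'
#' `SNR' = (intensity - b_position) / b_dispersion`, using the background
#' statistics of the feature's own sub-square.
#'
#' @param features Segmented feature tibble.
#' @param stats Background tibble from [background_stats()].
#' @return `features` with an `snr` column.
#' @export
compute_snr <- function(features, stats) {
  stopifnot(all(c("square_index", "intensity") %in% names(features)),
            all(c("square_index", "b_position", "b_dispersion") %in%
                  names(stats)))
  missing_sq <- setdiff(features$square_index, stats$square_index)
  if (length(missing_sq) > 0L) {
    abort(sprintf("no background stats for sub-square %d", missing_sq[[1]]))
  }
  features |>
    dplyr::left_join(
      dplyr::select(stats, "square_index", "b_position", "b_dispersion"),
      by = "square_index") |>
    dplyr::mutate(snr = (.data$intensity - .data$b_position) /
                    .data$b_dispersion) |>
    dplyr::select(-"b_position", -"b_dispersion")
}

#' Summarize per-feature SNR' over replicates and call positives
#'
#' For each target probe the median SNR' across its replicates is taken
#' and the probe is called positive when the median strictly exceeds
#' `threshold` (an intensity exactly 3 dispersions above background is
#' not positive).
#'
#' @param features Feature tibble with `snr` (see [compute_snr()]).
#' @param threshold Positive-call threshold on the median SNR'
#'   (default 3).
#' @return Tibble: `probe_id`, `median_snr`, `n_replicates`, `positive`.
#' @export
summarize_replicates <- function(features, threshold = 3) {
  stopifnot(all(c("probe_id", "snr", "probe_class") %in% names(features)))
  recs <- features |>
    dplyr::filter(.data$probe_class == "target") |>
    dplyr::group_by(.data$probe_id) |>
    dplyr::summarise(median_snr = stats::median(.data$snr),
                     n_replicates = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(positive = .data$median_snr > threshold)
  n_single <- sum(recs$n_replicates == 1L)
  if (n_single > 0L) {
    warn(sprintf("%d probe(s) have a single replicate", n_single))
  }
  recs
}

#' Full SNR' analysis of an array feature table
#'
#' Chains [segment_grid()], [background_stats()], [compute_snr()] and
#' [summarize_replicates()].
#'
#' @param features Feature tibble: `probe_id`, `x`, `y`, `intensity`,
#'   `probe_class` (`"target"`/`"random"`), `replicate`.
#' @param rows,cols Grid segmentation (default 4 x 4).
#' @param threshold Positive-call threshold (default 3).
#' @param dispersion,min_random,floor_eps See [background_stats()].
#' @return An `snr_analysis` object with elements `records` (per-probe
#'   calls), `features` (with `square_index` and `snr`), `background`
#'   (per-square statistics) and `params`.
#' @export
array_snr <- function(features, rows = 4, cols = 4, threshold = 3,
                      dispersion = "mad", min_random = 10,
                      floor_eps = 1e-6) {
  stopifnot(is.data.frame(features),
            all(c("probe_id", "x", "y", "intensity", "probe_class") %in%
                  names(features)))
  bad <- setdiff(unique(features$probe_class), c("target", "random"))
  if (length(bad) > 0L) {
    row <- which(features$probe_class == bad[[1]])[[1]]
    abort(sprintf("unknown probe_class '%s' (row %d)", bad[[1]], row))
  }
  if (any(features$intensity < 0)) abort("negative intensities")
  seg <- segment_grid(features, rows, cols)
  bg <- background_stats(seg, min_random, dispersion, floor_eps)
  snr <- compute_snr(seg, bg)
  recs <- summarize_replicates(snr, threshold)
  structure(
    list(records = recs, features = snr, background = bg,
         params = list(rows = rows, cols = cols, threshold = threshold,
                       dispersion = dispersion, min_random = min_random,
                       floor_eps = floor_eps)),
    class = "snr_analysis"
  )
}

#' @export
print.snr_analysis <- function(x, ...) {
  cat(sprintf(
    "SNR' analysis: %d probes, %d positive (median SNR' > %g), %d sub-squares\n",
    nrow(x$records), sum(x$records$positive), x$params$threshold,
    nrow(x$background)))
  invisible(x)
}

#' @export
tidy.snr_analysis <- function(x, ...) x$records

#' @export
glance.snr_analysis <- function(x, ...) {
  tibble(
    n_probes = nrow(x$records),
    n_positive = sum(x$records$positive),
    n_squares = nrow(x$background),
    median_background = stats::median(x$background$b_position),
    threshold = x$params$threshold
  )
}

#' @export
autoplot.snr_analysis <- function(object, ...) {
  feats <- object$features |>
    dplyr::left_join(dplyr::select(object$records, "probe_id", "positive"),
                     by = "probe_id") |>
    dplyr::mutate(positive = dplyr::coalesce(.data$positive, FALSE))
  ggplot2::ggplot(feats, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$snr,
                                     shape = .data$positive),
                        size = 1) +
    ggplot2::scale_colour_viridis_c(name = "SNR'") +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17),
                                name = "positive") +
    ggplot2::labs(x = "array X", y = "array Y",
                  title = "Spatially segmented SNR'") +
    ggplot2::theme_minimal()
}
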