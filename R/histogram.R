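#' Compose a symmetric K_i voxel histogram
#'
#' Bins voxel-wise leakage rates with uniform-width half-open bins
#' `[lo, hi)` whose edges sit at integer multiples of the bin width, so the
#' negative side mirrors exactly onto the positive side about zero. The range
#' always covers `max(|ki|)`.
#'
#' When `bin_width` is `NULL` the Freedman-Diaconis rule is applied to the
#' negative-side values reflected about zero (a noise-scaled width); when no
#' negative values exist, a default of 1e-4 min^-1 is used.
#'
#' @param ki_values voxel-wise K_i estimates, min^-1 (finite, non-empty;
#'   negative values expected and required by the correction).
#' @param bin_width bin width in min^-1, or `NULL` for the data-driven rule.
#' @return a `leakage_histogram`: `bin_edges`, `raw_counts`,
#'   `n_total_voxels`, `bin_width`; `corrected_counts` is `NULL` until
#'   [noise_correct()] is applied.
#' @export
build_histogram <- function(ki_values, bin_width = NULL) {
  ki_values <- ki_values[is.finite(ki_values)]
  if (length(ki_values) == 0) stop("ki_values is empty")
  if (is.null(bin_width)) {
    neg <- ki_values[ki_values < 0]
    if (length(neg) >= 2) {
      sym <- c(neg, -neg)
      bin_width <- 2 * stats::IQR(sym) / length(sym)^(1 / 3)
    }
    if (is.null(bin_width) || !is.finite(bin_width) || bin_width <= 0) {
      bin_width <- 1e-4
    }
  }
  stopifnot(bin_width > 0)
  nb <- floor(max(abs(ki_values)) / bin_width) + 1
  edges <- (-nb:nb) * bin_width
  idx <- findInterval(ki_values, edges)   # half-open [edges[i], edges[i+1])
  raw <- tabulate(idx, nbins = 2 * nb)
  structure(list(bin_edges = edges, raw_counts = raw,
                 corrected_counts = NULL, bin_width = bin_width,
                 n_total_voxels = length(ki_values)),
            class = "leakage_histogram")
}

#' Mirror-subtract noise correction of a K_i histogram
#'
#' The negative half of the K_i distribution is assumed to be pure,
#' symmetric estimation noise. It is mirrored about zero and subtracted from
#' the positive half; what remains reflects detectable leakage. Per bin the
#' corrected count is floored at zero (a count cannot be negative).
#'
#' @param hist a `leakage_histogram` from [build_histogram()].
#' @return the histogram with `corrected_counts` filled in (one count per
#'   positive-side bin).
#' @export
noise_correct <- function(hist) {
  stopifnot(inherits(hist, "leakage_histogram"))
  nb <- length(hist$raw_counts) / 2
  pos <- hist$raw_counts[(nb + 1):(2 * nb)]
  neg_mirrored <- hist$raw_counts[nb:1]
  hist$corrected_counts <- pmax(pos - neg_mirrored, 0)
  hist
}

#' Mean K_i and fractional leakage volume from a corrected histogram
#'
#' Mean K_i is the count-weighted average of the positive bin midpoints of
#' the corrected histogram (0 when no corrected counts remain). The
#' fractional leakage volume v_L is the remaining area under the corrected
#' histogram — the corrected count total — relative to the number of tissue
#' voxels.
#'
#' @param hist a noise-corrected `leakage_histogram`.
#' @param tissue_label optional label (`"NAWM"`, `"WMH"`).
#' @return a `leakage_summary`: `mean_ki` (min^-1), `v_l` (fraction),
#'   `tissue_label`, `n_voxels`.
#' @export
summarize_leakage <- function(hist, tissue_label = NA_character_) {
  stopifnot(inherits(hist, "leakage_histogram"))
  if (is.null(hist$corrected_counts)) {
    stop("histogram has not been noise-corrected; call noise_correct() first")
  }
  if (hist$n_total_voxels == 0) stop("histogram covers zero voxels")
  nb <- length(hist$corrected_counts)
  mids <- (seq_len(nb) - 0.5) * hist$bin_width
  tot <- sum(hist$corrected_counts)
  mean_ki <- if (tot > 0) sum(hist$corrected_counts * mids) / tot else 0
  structure(list(mean_ki = mean_ki,
                 v_l = tot / hist$n_total_voxels,
                 tissue_label = tissue_label,
                 n_voxels = hist$n_total_voxels),
            class = "leakage_summary")
}

#' One-call leakage summary for a set of voxel K_i values
#'
#' Convenience wrapper: [build_histogram()], [noise_correct()],
#' [summarize_leakage()].
#'
#' @inheritParams build_histogram
#' @inheritParams summarize_leakage
#' @return a `leakage_summary`.
#' @export
leakage_summary <- function(ki_values, bin_width = NULL,
                            tissue_label = NA_character_) {
  summarize_leakage(noise_correct(build_histogram(ki_values, bin_width)),
                    tissue_label)
}

#' Export a histogram as a data frame
#'
#' @param hist a `leakage_histogram` (corrected or not).
#' @return data frame with `bin_lo`, `bin_hi`, `raw` and (where available)
#'   `corrected` (NA on negative-side bins).
#' @export
histogram_table <- function(hist) {
  stopifnot(inherits(hist, "leakage_histogram"))
  nb <- length(hist$raw_counts) / 2
  out <- data.frame(bin_lo = hist$bin_edges[-length(hist$bin_edges)],
                    bin_hi = hist$bin_edges[-1],
                    raw = hist$raw_counts)
  out$corrected <- NA_integer_
  if (!is.null(hist$corrected_counts)) {
    out$corrected[(nb + 1):(2 * nb)] <- hist$corrected_counts
  }
  out
}
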