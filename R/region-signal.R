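# Region-level analysis signals: discrete multiunit spike counts and the
# continuous averaged somatic voltage of a region's principal cells.

#' Extract a region multiunit activity series from a simulation
#'
#' The region's principal-cell spike trains are pooled and binned; counts
#' are clipped to a small alphabet.  This discrete multiunit series is the
#' default target of the complexity analyses: in a strongly theta-locked
#' network the per-cycle count pattern is nearly stereotyped, so its
#' delay-embedded dynamics are close to a (quantised) limit cycle, while
#' degenerate, cycle-skipping networks produce diverging patterns.
#'
#' @param sim A `simulation_result`.
#' @param regions Character vector of regions to pool (e.g. `"CA3"` or
#'   `c("CA3", "CA1")`).
#' @param bin_width Bin width, ms.
#' @param clip Count alphabet clip (counts above are truncated).
#' @param discard Initial transient discarded, ms.
#' @return Integer series with attribute `sample_dt` (= `bin_width`).
#' @export
region_activity <- function(sim, regions, bin_width = 5, clip = 2,
                            discard = 500) {
  cl <- sim$config$cells
  members <- cl$label[cl$region %in% regions & cl$principal]
  if (!length(members)) stopf("no principal cells in region(s)")
  ba <- bin_activity(sim$spikes[members], bin_width, sim$config$duration)
  x <- pmin(ba$counts, clip)
  x <- x[(round(discard / bin_width) + 1):length(x)]
  attr(x, "sample_dt") <- bin_width
  x
}

#' Extract a region voltage signal from a simulation
#'
#' The continuous counterpart of [region_activity()]: each principal cell's
#' somatic voltage is z-scored (so no cell dominates through its DC level),
#' the region's cells are averaged, the average is smoothed with a short
#' Gaussian kernel (suppressing the stereotyped spike-reset transients that
#' would otherwise dominate the embedding) and resampled at `sample_every`
#' ms.  An initial transient is discarded.
#'
#' @inheritParams region_activity
#' @param sample_every Output sampling interval, ms.
#' @param smooth_sd Gaussian smoothing SD, ms (0 disables).
#' @return Numeric series with attribute `sample_dt` (ms).
#' @export
region_voltage <- function(sim, regions, sample_every = 1, smooth_sd = 2,
                           discard = 500) {
  cl <- sim$config$cells
  members <- cl$label[cl$region %in% regions & cl$principal]
  if (!length(members)) stopf("no principal cells in region(s)")
  v <- sim$voltage[, members, drop = FALSE]
  z <- scale(v)
  sig <- rowMeans(z)
  dt <- sim$config$dt
  if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd / dt)
    kern <- exp(-0.5 * ((-half:half) * dt / smooth_sd)^2)
    kern <- kern / sum(kern)
    sig <- as.numeric(stats::filter(sig, kern, sides = 2))
  }
  keep <- seq(from = max(1L, round(discard / dt) + 1L), to = length(sig),
              by = max(1L, round(sample_every / dt)))
  out <- sig[keep]
  out <- out[is.finite(out)]
  attr(out, "sample_dt") <- sample_every
  out
}
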