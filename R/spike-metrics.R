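# Burst statistics: number of spikes, spikes per burst, burst duration and
# inter-burst interval, per cell and aggregated over regions.

#' Construct a spike train object
#'
#' @param times Strictly increasing spike times in ms, within
#'   `[0, duration)`.
#' @param duration Observation duration, ms.
#' @param cell_id Optional cell label.
#' @return A list of class `spike_train`.
#' @export
spike_train <- function(times, duration, cell_id = NA_character_) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE) && length(times) > 1)
    stopf("spike times must be strictly increasing")
  if (length(times) && (min(times) < 0 || max(times) >= duration))
    stopf("spike times must lie in [0, duration)")
  structure(list(cell_id = cell_id, times = times, duration = duration),
            class = "spike_train")
}

#' Detect spikes in a voltage trace
#'
#' One spike per upward threshold crossing; crossings closer than the
#' refractory window to the previous accepted spike are merged into it.
#'
#' @param voltage_trace Numeric vector of membrane potential samples, mV.
#' @param dt Sampling interval, ms.
#' @param threshold Detection threshold, mV.
#' @param refractory Merge window, ms.
#' @return A `spike_train` (times at the crossing samples).
#' @export
detect_spikes <- function(voltage_trace, dt, threshold = -50,
                          refractory = 2) {
  if (any(!is.finite(voltage_trace))) stopf("voltage trace has non-finite samples")
  v <- as.numeric(voltage_trace)
  up <- which(v[-1] >= threshold & v[-length(v)] < threshold)
  times <- up * dt
  keep <- c()
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory) {
      keep <- c(keep, t)
      last <- t
    }
  }
  spike_train(keep %||% numeric(0), duration = length(v) * dt)
}

#' Segment a spike train into bursts
#'
#' A burst is a maximal run of at least two spikes whose consecutive
#' inter-spike intervals are all `<= isi_threshold`.  Isolated spikes are
#' not bursts.
#'
#' @param train A `spike_train` (or numeric spike-time vector).
#' @param isi_threshold Maximum within-burst ISI, ms.
#' @return Data frame with one row per burst: `start`, `end` (first/last
#'   spike time, ms) and `n_spikes`.
#' @export
#' @examples
#' segment_bursts(c(0, 5, 8, 100, 104), isi_threshold = 20)
segment_bursts <- function(train, isi_threshold) {
  assert_scalar_num(isi_threshold, "isi_threshold", lower = 1e-12)
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  if (length(times) < 2) return(empty)
  grp <- cumsum(c(1, diff(times) > isi_threshold))
  runs <- split(times, grp)
  runs <- runs[lengths(runs) >= 2]
  if (!length(runs)) return(empty)
  out <- data.frame(start = vapply(runs, min, 0), end = vapply(runs, max, 0),
                    n_spikes = lengths(runs))
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

#' Burst statistics of a spike train
#'
#' Computes the four per-cell statistics of the study: total number of
#' spikes, mean spikes per burst, mean burst duration (last minus first
#' spike, ms) and mean inter-burst interval (burst offset to next burst
#' onset, ms; this convention makes duration + IBI approximately one theta
#' cycle for theta-locked trains).  Undefined means are `NA`, never 0.
#'
#' @inheritParams segment_bursts
#' @return A list of class `burst_stats`: `n_spikes`, `n_bursts`,
#'   `spikes_per_burst`, `burst_duration`, `inter_burst_interval`.
#' @export
#' @examples
#' burst_statistics(c(0, 5, 8, 100, 104), isi_threshold = 20)
burst_statistics <- function(train, isi_threshold = 31.25) {
  times <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  b <- segment_bursts(times, isi_threshold)
  nb <- nrow(b)
  structure(list(
    n_spikes = length(times), n_bursts = nb,
    spikes_per_burst = if (nb >= 1) mean(b$n_spikes) else NA_real_,
    burst_duration = if (nb >= 1) mean(b$end - b$start) else NA_real_,
    inter_burst_interval = if (nb >= 2)
      mean(b$start[-1] - b$end[-nb]) else NA_real_
  ), class = "burst_stats")
}

.burst_stat_names <- c("n_spikes", "spikes_per_burst", "burst_duration",
                       "inter_burst_interval")

# regions and region unions reported by the study
.region_groups <- function() {
  list(DG = "DG", CA3 = "CA3", CA1 = "CA1",
       `CA3-CA1` = c("CA3", "CA1"),
       `DG-CA3-CA1` = c("DG", "CA3", "CA1"))
}

#' Aggregate per-cell burst statistics over regions
#'
#' Unweighted mean of each statistic over the principal cells (granule and
#' pyramidal) of each region and of the region unions `CA3-CA1` and
#' `DG-CA3-CA1`.  `NA` statistics (e.g. the IBI of a single-burst train) are
#' excluded from the means.
#'
#' @param stats Named list of `burst_stats`, one per cell.
#' @param cells Cell table (as in `network_config$cells`) mapping labels to
#'   `region` and `principal`.
#' @param principal_only Aggregate over principal cells only (default TRUE,
#'   matching the study's reporting).
#' @return Data frame: `region`, one column per statistic.
#' @export
region_aggregate <- function(stats, cells, principal_only = TRUE) {
  groups <- .region_groups()
  rows <- lapply(names(groups), function(gname) {
    members <- cells$label[cells$region %in% groups[[gname]] &
                             (!principal_only | cells$principal)]
    if (!length(members)) stopf("region '%s' has no member cells", gname)
    s <- stats[members]
    vals <- vapply(.burst_stat_names, function(m) {
      x <- vapply(s, function(z) as.numeric(z[[m]]), 0)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, 0)
    data.frame(region = gname, t(vals))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Burst statistics of a simulation, per cell and per region
#'
#' @param sim A `simulation_result`.
#' @param isi_threshold Within-burst ISI threshold, ms; the default is a
#'   quarter of the (first drive's) theta period, consistent with
#'   theta-cycle bursts.
#' @return List with `per_cell` (named list of `burst_stats`) and
#'   `per_region` (data frame from [region_aggregate()]).
#' @export
simulation_burst_stats <- function(sim, isi_threshold = NULL) {
  theta <- sim$config$drives[[1]]$theta_frequency
  isi_threshold <- isi_threshold %||% (1000 / theta / 4)
  per_cell <- lapply(sim$spikes, burst_statistics,
                     isi_threshold = isi_threshold)
  list(per_cell = per_cell,
       per_region = region_aggregate(per_cell, sim$config$cells))
}
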