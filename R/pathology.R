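# Staged entorhinal synapse deletion modelling AD-like degeneration.

#' Define a staged synaptic-deletion schedule
#'
#' The degeneration model inactivates a growing fraction of the entorhinal
#' layer-II (EC2) synapses -- the connections lost earliest in Alzheimer-like
#' pathology -- in a fixed cumulative order, so the synapses removed at a
#' lower fraction are always a subset of those removed at a higher one.
#'
#' @param fractions Strictly increasing deletion fractions in `[0, 1]`;
#'   default `c(0.09, 0.18, 0.26, 0.35)`, the four pathology stages of the
#'   study design.
#' @param target_pathways Pathway tags eligible for deletion; default all
#'   tags beginning `"EC2_"`.
#' @param order_policy `"indexed"` (deterministic synapse-table order, the
#'   default; the builder interleaves EC2 contacts across target cells so
#'   index order spreads deletions over cells and regions) or
#'   `"seeded_random"` (a seeded permutation, for sensitivity runs).
#' @param seed Seed for the `"seeded_random"` policy.
#' @return A list of class `deletion_schedule`.
#' @export
deletion_schedule <- function(fractions = c(0.09, 0.18, 0.26, 0.35),
                              target_pathways = NULL,
                              order_policy = c("indexed", "seeded_random"),
                              seed = 1L) {
  order_policy <- match.arg(order_policy)
  target_pathways <- target_pathways %||%
    grep("^EC2_", .pathway_vocabulary, value = TRUE)
  if (!length(target_pathways) ||
      !all(target_pathways %in% .pathway_vocabulary))
    stopf("target_pathways must be non-empty tags from the closed vocabulary")
  if (length(fractions)) {
    if (any(fractions < 0 | fractions > 1) || any(diff(fractions) <= 0))
      stopf("fractions must be strictly increasing values in [0, 1]")
  }
  structure(list(fractions = fractions, target_pathways = target_pathways,
                 order_policy = order_policy, seed = as.integer(seed)),
            class = "deletion_schedule")
}

.deletion_order <- function(config, schedule) {
  idx <- which(config$synapses$pathway %in% schedule$target_pathways)
  if (!length(idx)) stopf("no synapses match the deletion target pathways")
  if (schedule$order_policy == "seeded_random")
    idx <- withr::with_seed(schedule$seed, sample(idx))
  idx
}

# round-half-up, used for fraction * N_target (documented: R's round() is
# round-half-even, which would tie-break 0.5 downwards half the time)
round_half_up <- function(x) floor(x + 0.5)

#' Apply a single deletion stage to a network configuration
#'
#' Inactivates exactly `round(fraction * N_target)` target-pathway synapses
#' (round half up), taken from the front of the schedule's fixed order, so
#' deletions are cumulative across fractions.  Only the `active` flag
#' changes; synapse count, parameters and every non-target synapse are
#' untouched.  The input configuration is not modified.
#'
#' @param config A `network_config`.
#' @param fraction Deletion fraction in `[0, 1]`.
#' @param schedule A `deletion_schedule`.
#' @return A new `network_config` with the deletions applied.
#' @export
#' @examples
#' cfg <- build_default_network(seed = 1)
#' del <- apply_deletion(cfg, 0.35, deletion_schedule())
#' sum(!del$synapses$active)
apply_deletion <- function(config, fraction, schedule = deletion_schedule()) {
  assert_scalar_num(fraction, "fraction", lower = 0, upper = 1)
  ord <- .deletion_order(config, schedule)
  n_off <- round_half_up(fraction * length(ord))
  out <- config
  if (n_off > 0) out$synapses$active[ord[seq_len(n_off)]] <- FALSE
  out
}

#' Build the control-plus-pathology configuration series
#'
#' @param config Base (control) `network_config`.
#' @param schedule A `deletion_schedule`.
#' @return A named list of `network_config`s: the control (fraction 0)
#'   followed by one entry per scheduled fraction.  Deleted sets are nested
#'   across the series.
#' @export
#' @examples
#' series <- deletion_series(build_default_network(1))
#' names(series)
deletion_series <- function(config, schedule = deletion_schedule()) {
  fr <- c(0, schedule$fractions)
  out <- lapply(fr, apply_deletion, config = config, schedule = schedule)
  names(out) <- sprintf("del_%02d", round(100 * fr))
  out
}

#' Manifest of deleted synapses across a schedule
#'
#' @param config Base `network_config`.
#' @param schedule A `deletion_schedule`.
#' @return Data frame (`pathway`, `pre`, `post`, `comp`, `receptor`,
#'   `fraction_at_which_deleted`) for every synapse removed by the final
#'   stage, suitable for CSV export.
#' @export
deletion_manifest <- function(config, schedule = deletion_schedule()) {
  ord <- .deletion_order(config, schedule)
  n_per <- round_half_up(schedule$fractions * length(ord))
  first_fraction <- rep(NA_real_, length(ord))
  for (k in rev(seq_along(schedule$fractions)))
    first_fraction[seq_len(n_per[k])] <- schedule$fractions[k]
  keep <- !is.na(first_fraction)
  sy <- config$synapses[ord[keep], c("pathway", "pre", "post", "comp",
                                     "receptor")]
  sy$fraction_at_which_deleted <- first_fraction[keep]
  rownames(sy) <- NULL
  sy
}
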