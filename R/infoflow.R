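# Region-level information flow: plug-in Shannon entropy, mutual
# information and Schreiber transfer entropy on binned spike counts, with
# control-normalised flow ratios.  All quantities are in bits.

#' Bin region spike activity
#'
#' Sums the spikes of a region's (principal) cells into consecutive bins.
#'
#' @param trains List of spike-time vectors (ms), one per cell.
#' @param bin_width Bin width, ms.
#' @param duration Total duration, ms; the number of bins is
#'   `floor(duration / bin_width)`.
#' @param region Optional region label.
#' @return List of class `binned_activity`: `region`, `bin_width`, `counts`.
#' @export
#' @examples
#' bin_activity(list(c(1, 2, 15)), bin_width = 10, duration = 30)$counts
bin_activity <- function(trains, bin_width, duration, region = NA_character_) {
  assert_scalar_num(bin_width, "bin_width", lower = 1e-9)
  n_bins <- floor(duration / bin_width)
  times <- unlist(trains, use.names = FALSE)
  times <- times[times < n_bins * bin_width]
  counts <- tabulate(pmin(n_bins, floor(times / bin_width) + 1L),
                     nbins = n_bins)
  structure(list(region = region, bin_width = bin_width, counts = counts),
            class = "binned_activity")
}

.as_counts <- function(x) {
  if (inherits(x, "binned_activity")) x$counts else as.integer(x)
}

.clip_counts <- function(x, clip) pmin(as.integer(x), as.integer(clip))

#' Plug-in Shannon entropy of a symbol sequence (bits)
#'
#' Empirical (maximum-likelihood) entropy of the symbol distribution.
#'
#' @param counts Integer sequence (e.g. binned spike counts) or a
#'   `binned_activity`.
#' @param clip Symbols are clipped at this value (alphabet `0..clip`),
#'   bounding the plug-in bias; `Inf` disables clipping.
#' @return Entropy in bits.
#' @export
#' @examples
#' shannon_entropy(c(0, 1, 2, 3))  # 2 bits
shannon_entropy <- function(counts, clip = 3) {
  x <- .as_counts(counts)
  if (!length(x)) stopf("empty input")
  if (is.finite(clip)) x <- .clip_counts(x, clip)
  histogram_entropy(table(x))
}

#' Plug-in mutual information between two symbol sequences (bits)
#'
#' `MI = H(X) + H(Y) - H(X, Y)` on the joint empirical histogram; symmetric
#' and non-negative, with `MI(X, X) = H(X)` exactly.
#'
#' @param x_counts,y_counts Equal-length integer sequences or
#'   `binned_activity` objects.
#' @param clip Alphabet clip, as in [shannon_entropy()].
#' @return Mutual information in bits.
#' @export
mutual_information <- function(x_counts, y_counts, clip = 3) {
  x <- .as_counts(x_counts); y <- .as_counts(y_counts)
  if (length(x) != length(y)) stopf("sequences must have equal length")
  if (is.finite(clip)) {
    x <- .clip_counts(x, clip); y <- .clip_counts(y, clip)
  }
  joint <- table(x, y)
  histogram_entropy(table(x)) + histogram_entropy(table(y)) -
    histogram_entropy(joint)
}

# encode parallel columns of non-negative integers as one symbol vector
.encode_cols_list <- function(cols) {
  code <- 0
  for (col in cols) code <- code * (max(col) + 1L) + as.integer(col)
  code
}

#' Schreiber transfer entropy between two symbol sequences (bits)
#'
#' `TE(source -> target) = I(target_next ; source_past | target_past)` with
#' plug-in joint histograms over `k_history` target lags and `l_history`
#' source lags.  Non-negative and directional.
#'
#' @param source_counts,target_counts Equal-length integer sequences or
#'   `binned_activity` objects.
#' @param k_history Target history length (>= 1).
#' @param l_history Source history length (>= 1).
#' @param clip Alphabet clip, as in [shannon_entropy()].
#' @return Transfer entropy in bits.
#' @export
#' @examples
#' x <- rbinom(5000, 1, 0.5)
#' y <- c(0L, x[-5000])                 # copy channel with lag 1
#' transfer_entropy(x, y)               # about 1 bit
transfer_entropy <- function(source_counts, target_counts, k_history = 1,
                             l_history = 1, clip = 3) {
  x <- .as_counts(source_counts); y <- .as_counts(target_counts)
  if (length(x) != length(y)) stopf("sequences must have equal length")
  k <- as.integer(k_history); l <- as.integer(l_history)
  stopifnot(k >= 1, l >= 1)
  h <- max(k, l)
  n <- length(y) - h
  if (n < 1) stopf("series shorter than history + 1")
  if (is.finite(clip)) {
    x <- .clip_counts(x, clip); y <- .clip_counts(y, clip)
  }
  idx <- (h + 1):length(y)
  ynext <- y[idx]
  ypast <- .encode_cols_list(lapply(seq_len(k), function(j) y[idx - j]))
  xpast <- .encode_cols_list(lapply(seq_len(l), function(j) x[idx - j]))
  # TE = H(ynext, ypast) - H(ypast) - H(ynext, ypast, xpast) + H(ypast, xpast)
  H <- function(...) histogram_entropy(table(.encode_cols_list(list(...))))
  H(ynext, ypast) - H(ypast) - H(ynext, ypast, xpast) + H(ypast, xpast)
}

#' Exact transfer entropy of a known discrete joint distribution
#'
#' Enumeration oracle: given the stationary joint probability table
#' `p(y_next, y_past, x_past)` of a first-order process, returns the exact
#' `TE(X -> Y)` in bits.  Used to validate the plug-in estimator.
#'
#' @param p 3-d array `[y_next, y_past, x_past]` of probabilities summing
#'   to 1.
#' @return Exact transfer entropy in bits.
#' @export
exact_transfer_entropy <- function(p) {
  stopifnot(length(dim(p)) == 3, abs(sum(p) - 1) < 1e-12)
  te <- 0
  p_yx <- apply(p, c(2, 3), sum)      # p(y_past, x_past)
  p_y <- apply(p, 2, sum)             # p(y_past)
  p_ny <- apply(p, c(1, 2), sum)      # p(y_next, y_past)
  for (a in seq_len(dim(p)[1])) for (b in seq_len(dim(p)[2]))
    for (c in seq_len(dim(p)[3])) {
      pr <- p[a, b, c]
      if (pr <= 0) next
      te <- te + pr * log2((pr / p_yx[b, c]) / (p_ny[a, b] / p_y[b]))
    }
  te
}

#' Control-normalised transfer entropy
#'
#' @param te_pathology Transfer entropy of a pathology condition, bits.
#' @param te_control Transfer entropy of the control condition, bits.
#' @return `100 * te_pathology / te_control` (percent of control), or `NA`
#'   with a warning when the control TE is zero.
#' @export
control_normalize <- function(te_pathology, te_control) {
  if (!is.finite(te_control) || te_control <= 0) {
    warning("control transfer entropy is zero; ratio undefined")
    return(NA_real_)
  }
  100 * te_pathology / te_control
}

#' Region-level information-flow metrics of a simulation
#'
#' Bins the principal-cell spike counts of DG, CA3 and CA1, then computes
#' the per-region Shannon entropy, the mutual information of each region
#' pair, and the transfer entropy of every ordered pair along the
#' trisynaptic pathway (DG<->CA3, CA3<->CA1).
#'
#' @param sim A `simulation_result`.
#' @param bin_width Bin width in ms.
#' @param clip Alphabet clip for the histogram estimators.
#' @param k_history,l_history Transfer-entropy history lengths.
#' @return List of class `infoflow_metrics`: `entropy` (named, bits), `mi`
#'   (named by `"A|B"`), `te` (named by `"A->B"`), `bin_width`.
#' @export
simulation_infoflow <- function(sim, bin_width = 10, clip = 3,
                                k_history = 1, l_history = 1) {
  cl <- sim$config$cells
  binned <- lapply(c("DG", "CA3", "CA1"), function(r) {
    members <- cl$label[cl$region == r & cl$principal]
    bin_activity(sim$spikes[members], bin_width, sim$config$duration,
                 region = r)
  })
  names(binned) <- c("DG", "CA3", "CA1")
  ent <- vapply(binned, shannon_entropy, 0, clip = clip)
  pairs <- list(c("DG", "CA3"), c("CA3", "CA1"))
  mi <- vapply(pairs, function(p)
    mutual_information(binned[[p[1]]], binned[[p[2]]], clip = clip), 0)
  names(mi) <- vapply(pairs, paste, "", collapse = "|")
  dirs <- list(c("DG", "CA3"), c("CA3", "DG"), c("CA3", "CA1"),
               c("CA1", "CA3"))
  te <- vapply(dirs, function(p)
    transfer_entropy(binned[[p[1]]], binned[[p[2]]], k_history, l_history,
                     clip = clip), 0)
  names(te) <- vapply(dirs, paste, "", collapse = "->")
  structure(list(entropy = ent, mi = mi, te = te, bin_width = bin_width),
            class = "infoflow_metrics")
}
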