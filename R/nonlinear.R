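# Delay-embedding reconstruction and complexity measures: AMI delay, FNN
# dimension, Grassberger-Procaccia correlation dimension, recurrence-plot
# Shannon entropy and the Rosenstein maximal Lyapunov exponent.

#' Embedding parameters
#'
#' @param delay Delay in samples (>= 1).
#' @param dimension Embedding dimension (>= 1).
#' @param theiler Theiler exclusion window in samples (>= 0); pairs closer
#'   in time than this are excluded from neighbour searches.  Defaults to
#'   `delay * dimension`.
#' @return List of class `embedding_params`.
#' @export
embedding_params <- function(delay, dimension, theiler = NULL) {
  delay <- as.integer(delay)
  dimension <- as.integer(dimension)
  stopifnot(delay >= 1, dimension >= 1)
  theiler <- as.integer(theiler %||% (delay * dimension))
  stopifnot(theiler >= 0)
  structure(list(delay = delay, dimension = dimension, theiler = theiler),
            class = "embedding_params")
}

#' Delay-embed a scalar series
#'
#' Row `i` of the result is `(x[i], x[i + delay], ..., x[i + (m-1) delay])`.
#'
#' @param x Numeric series.
#' @param delay Delay in samples.
#' @param dimension Embedding dimension.
#' @return Matrix with `length(x) - (dimension - 1) * delay` rows.
#' @export
embed_delay <- function(x, delay, dimension) {
  n <- length(x) - (dimension - 1) * delay
  if (n < 2) stopf("series too short for this embedding")
  sapply(seq_len(dimension), function(k) x[(1:n) + (k - 1) * delay])
}

# equal-width discretisation used by the AMI estimator
.discretise <- function(x, n_bins) {
  r <- range(x)
  if (r[1] == r[2]) stopf("constant series")
  pmin(n_bins, 1L + as.integer(floor((x - r[1]) / diff(r) * n_bins)))
}

#' Optimal embedding delay by auto mutual information
#'
#' Computes the mutual information (bits, equal-width binning) between the
#' series and its lagged copy for lags `1..max_lag` and returns the first
#' local minimum of the lightly smoothed curve (histogram AMI curves of
#' near-periodic signals carry binning ripple that a raw first-minimum rule
#' latches onto).  A series with no detectable lag structure (AMI below 0.05
#' bits everywhere) yields delay 1; if the curve has no local minimum, the
#' first lag where AMI drops below `1/e` of its lag-1 value is used.  Both
#' fallbacks are flagged.
#'
#' @param series Numeric series (non-constant).
#' @param max_lag Largest lag to scan.
#' @param n_bins Number of histogram bins.
#' @param smooth Moving-average window (lags) applied before the
#'   minimum search.
#' @return List of class `ami_delay`: `delay`, `ami` (the raw curve),
#'   `fallback` (logical).
#' @export
#' @examples
#' x <- sin(2 * pi * (1:2000) / 100) + rnorm(2000, 0, 0.1)
#' ami_delay(x, max_lag = 60)$delay  # about a quarter period
ami_delay <- function(series, max_lag = 50, n_bins = 16, smooth = 5) {
  x <- as.numeric(series)
  if (length(x) <= max_lag + 10) stopf("series too short for max_lag")
  d <- .discretise(x, n_bins)
  ami <- vapply(seq_len(max_lag), function(lag) {
    n <- length(d) - lag
    mutual_information(d[1:n], d[(1 + lag):(n + lag)], clip = n_bins)
  }, 0)
  fallback <- FALSE
  if (max(ami) < 0.05) {
    # no lag structure at all: serially independent series
    delay <- 1L
    fallback <- TRUE
  } else {
    s <- as.numeric(stats::filter(ami, rep(1 / smooth, smooth), sides = 2))
    cand <- which(diff(sign(diff(s))) > 0) + 1L
    cand <- cand[!is.na(s[cand])]
    if (length(cand)) {
      delay <- cand[1]
    } else {
      below <- which(ami < ami[1] / exp(1))
      fallback <- TRUE
      delay <- if (length(below)) below[1] else 1L
    }
  }
  structure(list(delay = as.integer(delay), ami = ami, fallback = fallback),
            class = "ami_delay")
}

#' Minimal embedding dimension by false nearest neighbours
#'
#' Kennel criterion: a neighbour is false if appending the next delay
#' coordinate stretches the pair distance by more than `rtol`, or moves it
#' beyond `atol` standard deviations.  Returns the smallest dimension whose
#' false-neighbour fraction falls below `threshold`.
#'
#' @param series Numeric series.
#' @param delay Embedding delay in samples.
#' @param max_dim Largest dimension to test.
#' @param rtol,atol Kennel tolerances.
#' @param threshold FNN fraction below which a dimension is accepted.
#' @param theiler Temporal exclusion window (default `delay`).
#' @param max_ref Reference-point budget for the neighbour search.
#' @return List of class `fnn_dimension`: `dimension`, `fractions`.
#' @export
fnn_dimension <- function(series, delay, max_dim = 8, rtol = 15, atol = 2,
                          threshold = 0.01, theiler = NULL, max_ref = 1000) {
  x <- as.numeric(series)
  if (length(x) < (max_dim + 1) * delay + 50)
    max_dim <- max(1L, (length(x) - 50) %/% delay - 1L)
  if (max_dim < 1) stopf("series too short for FNN")
  theiler <- theiler %||% delay
  fr <- fnn_cpp(x, as.integer(delay), as.integer(max_dim), rtol, atol,
                as.integer(theiler), as.integer(max_ref))
  if (all(is.na(fr))) stopf("series too short for FNN at this delay")
  ok <- which(!is.na(fr) & fr < threshold)
  dim <- if (length(ok)) ok[1] else NA_integer_
  structure(list(dimension = as.integer(dim), fractions = fr),
            class = "fnn_dimension")
}

# longest contiguous radius window whose local slopes stay within
# `wobble` (relative) of the window median; returns indices into log_r
.scaling_region <- function(log_r, log_c, wobble = 0.10, min_len = 4) {
  ns <- length(log_r) - 1
  slope <- diff(log_c) / diff(log_r)
  best <- NULL
  for (i in seq_len(ns)) {
    for (j in seq(i + min_len - 1, ns)) {
      if (j > ns) break
      s <- slope[i:j]
      m <- median(s)
      if (m <= 0) next
      if (max(abs(s - m)) <= wobble * abs(m)) {
        if (is.null(best) || (j - i) > (best[2] - best[1])) best <- c(i, j)
      } else break
    }
  }
  best
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Estimates the correlation sum `C(r)` over log-spaced radii (all pairs,
#' Theiler window applied) and fits the slope of `log C` versus `log r`
#' over an automatically selected scaling region: the longest contiguous
#' radius window whose local slopes vary by less than 10% around their
#' median.  Radii span the 0.1%..50% quantiles of the pairwise distances.
#'
#' @param series Numeric series, or an already-embedded matrix.
#' @param embedding An `embedding_params`.
#' @param n_radii Number of log-spaced radii.
#' @param max_points Embedded points are strided down to at most this many.
#' @return List of class `complexity_estimate`: `value`, and `diagnostics`
#'   (`log_r`, `log_C`, scaling-region bounds, fit r-squared).  `value` is
#'   `NA` with a diagnostic when no scaling region exists.
#' @export
correlation_dimension <- function(series, embedding, n_radii = 24,
                                  max_points = 4000) {
  emb <- if (is.matrix(series)) series
         else embed_delay(series, embedding$delay, embedding$dimension)
  # fixed-stride thinning preserves any exact periodicity of the series
  if (nrow(emb) > max_points)
    emb <- emb[seq(1, nrow(emb), by = ceiling(nrow(emb) / max_points)),
               , drop = FALSE]
  if (nrow(emb) < 100) stopf("too few embedded points")
  th <- embedding$theiler
  ds <- pair_dist_sample_cpp(emb, max(1L, nrow(emb) %/% 500),
                             max(1L, nrow(emb) %/% 500), th)
  ds <- ds[ds > 0]
  radii <- exp(seq(log(quantile(ds, 0.001)), log(quantile(ds, 0.5)),
                   length.out = n_radii))
  cnt <- corr_count_cpp(emb, radii, as.integer(th))
  keep <- cnt >= 10
  if (sum(keep) < 5)
    return(structure(list(value = NA_real_,
                          diagnostics = list(reason = "too few pairs")),
                     class = "complexity_estimate"))
  log_r <- log(radii[keep]); log_c <- log(cnt[keep])
  reg <- .scaling_region(log_r, log_c)
  if (is.null(reg))
    return(structure(list(value = NA_real_,
                          diagnostics = list(reason = "no scaling region",
                                             log_r = log_r, log_C = log_c)),
                     class = "complexity_estimate"))
  idx <- reg[1]:(reg[2] + 1)
  fit <- stats::lm.fit(cbind(1, log_r[idx]), log_c[idx])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((log_c[idx] - mean(log_c[idx]))^2)
  structure(list(
    value = unname(fit$coefficients[2]),
    diagnostics = list(log_r = log_r, log_C = log_c,
                       region = range(exp(log_r[idx])),
                       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA)
  ), class = "complexity_estimate")
}

#' Recurrence-plot Shannon entropy
#'
#' Builds a recurrence plot at the radius that achieves a target recurrence
#' rate (radius = the corresponding quantile of the pairwise distances, so
#' the achieved rate is within the requested tolerance by construction) and
#' returns the Shannon entropy (bits) of the normalised diagonal-line-length
#' histogram for lines of length `>= lmin`.  Lines truncated by the plot
#' border are censored from the histogram, which removes the length spread a
#' strictly periodic signal would otherwise inherit from the border.
#'
#' @param series Numeric series or embedded matrix.
#' @param embedding An `embedding_params`.
#' @param target_recurrence_rate Target fraction of recurrent pairs (0-1).
#' @param lmin Minimal diagonal line length counted.
#' @param max_points Stride the embedding down to at most this many points.
#' @return List of class `rqa_entropy`: `entropy` (bits), `radius`,
#'   `recurrence_rate`, `histogram` (table of line lengths).
#' @export
rqa_entropy <- function(series, embedding, target_recurrence_rate = 0.1,
                        lmin = 2, max_points = 3000) {
  if (target_recurrence_rate <= 0 || target_recurrence_rate >= 1)
    stopf("target recurrence rate must lie in (0, 1)")
  emb <- if (is.matrix(series)) series
         else embed_delay(series, embedding$delay, embedding$dimension)
  if (nrow(emb) > max_points)
    emb <- emb[seq(1, nrow(emb), by = ceiling(nrow(emb) / max_points)),
               , drop = FALSE]
  th <- embedding$theiler
  ds <- pair_dist_sample_cpp(emb, max(1L, nrow(emb) %/% 700),
                             max(1L, nrow(emb) %/% 700), th)
  if (!length(ds) || all(ds == 0)) stopf("degenerate recurrence plot")
  radius <- quantile(ds, target_recurrence_rate, names = FALSE)
  if (radius <= 0) radius <- min(ds[ds > 0])
  # nudge off any exact distance plateau (periodic signals quantise the
  # distance distribution; a radius sitting on a plateau would let rounding
  # noise flip individual recurrences along a diagonal)
  radius <- radius * (1 + 1e-6)
  dl <- diag_lines_cpp(emb, radius, as.integer(th))
  if (!is.finite(dl$recurrence_rate) ||
      dl$recurrence_rate <= 0 || dl$recurrence_rate >= 1)
    stopf("degenerate recurrence plot (rate %s)", dl$recurrence_rate)
  lens <- dl$lengths[dl$lengths >= lmin]
  hist <- table(lens)
  structure(list(entropy = histogram_entropy(as.numeric(hist)),
                 radius = radius, recurrence_rate = dl$recurrence_rate,
                 histogram = hist),
            class = "rqa_entropy")
}

#' Shannon entropy of a count histogram (bits)
#'
#' @param counts Non-negative counts of each class.
#' @return Entropy in bits; 0 for empty or single-class histograms.
#' @export
#' @examples
#' histogram_entropy(c(8, 8))  # 1 bit
histogram_entropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

#' Maximal Lyapunov exponent (Rosenstein method)
#'
#' For each reference point the nearest neighbour outside the Theiler window
#' is tracked forward, and the mean log pair distance is recorded as a
#' function of the look-ahead.  The exponent is the least-squares slope of
#' this divergence curve over `fit_window` (in samples).  When no window is
#' given, the fit spans from the first step to 70% of the rise towards the
#' curve's saturation plateau, a standard heuristic for the linear region.
#'
#' @param series Numeric series or embedded matrix.
#' @param embedding An `embedding_params`.
#' @param fit_window Integer vector `c(first, last)` look-ahead, in samples,
#'   or `NULL` for automatic selection.
#' @param kmax Largest look-ahead evaluated.
#' @param max_ref Reference-point budget.
#' @param dist_floor Distances below this are clipped to it.  For quantised
#'   series (spike counts) set it to half the quantisation step, so exactly
#'   coinciding states count as "indistinguishable" rather than log(0).
#' @return List of class `lyapunov_estimate`: `value` (per sample),
#'   `curve` (mean log divergence), `fit_window`.
#' @export
#' @examples
#' x <- logistic_map(r = 4, x0 = 0.3, n = 3000)$values
#' max_lyapunov(x, embedding_params(1, 2, theiler = 5))$value  # about ln 2
max_lyapunov <- function(series, embedding, fit_window = NULL, kmax = 60,
                         max_ref = 2000, dist_floor = 0) {
  emb <- if (is.matrix(series)) series
         else embed_delay(series, embedding$delay, embedding$dimension)
  if (nrow(emb) < 100) stopf("too few embedded points")
  div <- nn_divergence_cpp(emb, as.integer(embedding$theiler),
                           as.integer(kmax), as.integer(max_ref), dist_floor)
  curve <- div$log_divergence
  if (all(!is.finite(curve))) stopf("insufficient neighbours")
  if (is.null(fit_window)) {
    lo <- min(curve, na.rm = TRUE)
    hi <- max(curve, na.rm = TRUE)
    sat <- which(curve >= lo + 0.7 * (hi - lo))[1] - 1L  # 0-based look-ahead
    fit_window <- c(1L, max(4L, sat))
  }
  fit_window[2] <- min(fit_window[2], kmax)
  j <- fit_window[1]:fit_window[2]
  y <- curve[j + 1L]
  ok <- is.finite(y)
  if (sum(ok) < 3) stopf("insufficient neighbours in fit window")
  fit <- stats::lm.fit(cbind(1, j[ok]), y[ok])
  structure(list(value = unname(fit$coefficients[2]), curve = curve,
                 fit_window = fit_window),
            class = "lyapunov_estimate")
}

#' Choose embedding parameters for a series
#'
#' Delay from the first AMI minimum, dimension from the FNN criterion
#' (capped), Theiler window `delay * dimension`.
#'
#' @param series Numeric series.
#' @param max_lag,max_dim Caps for the two searches.
#' @return An `embedding_params` with attributes `ami` and `fnn`.
#' @export
choose_embedding <- function(series, max_lag = 50, max_dim = 6) {
  a <- ami_delay(series, max_lag = max_lag)
  f <- fnn_dimension(series, delay = a$delay, max_dim = max_dim)
  dim <- f$dimension
  if (is.na(dim)) dim <- max_dim
  ep <- embedding_params(a$delay, dim)
  attr(ep, "ami") <- a
  attr(ep, "fnn") <- f
  ep
}

#' All complexity metrics of one series
#'
#' @param series Numeric series.
#' @param embedding Optional `embedding_params`; chosen automatically
#'   otherwise.
#' @param sample_dt Sampling interval of the series in ms (for the per-ms
#'   Lyapunov conversion); optional.
#' @param ... Passed on to the individual estimators.
#' @return List of class `complexity_metrics`: `embedding`,
#'   `correlation_dimension`, `rqa_entropy` (bits), `max_lyapunov`
#'   (per sample), `max_lyapunov_per_ms` (if `sample_dt` given), plus the
#'   full per-estimator objects under `detail`.
#' @export
complexity_metrics <- function(series, embedding = NULL, sample_dt = NULL,
                               ...) {
  embedding <- embedding %||% choose_embedding(series)
  d2 <- correlation_dimension(series, embedding, ...)
  rq <- tryCatch(rqa_entropy(series, embedding),
                 error = function(e) list(entropy = NA_real_))
  ly <- max_lyapunov(series, embedding)
  structure(list(
    embedding = embedding,
    correlation_dimension = d2$value,
    rqa_entropy = rq$entropy,
    max_lyapunov = ly$value,
    max_lyapunov_per_ms = if (!is.null(sample_dt)) ly$value / sample_dt,
    detail = list(correlation_dimension = d2, rqa = rq, lyapunov = ly)
  ), class = "complexity_metrics")
}
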