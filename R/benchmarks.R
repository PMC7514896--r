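# Synthetic benchmark series with analytically or numerically known
# dynamical/informational properties, used to validate every estimator
# without external data.

new_benchmark_series <- function(name, parameters, seed, values,
                                 known_properties = list()) {
  stopifnot(all(is.finite(values)))
  structure(list(name = name, parameters = parameters, seed = seed,
                 values = as.numeric(values),
                 known_properties = known_properties),
            class = "benchmark_series")
}

#' @export
print.benchmark_series <- function(x, ...) {
  cat(sprintf("<benchmark_series> %s, n = %d\n", x$name, length(x$values)))
  for (p in names(x$known_properties)) {
    kp <- x$known_properties[[p]]
    cat(sprintf("  %s = %g (tol %g; %s)\n", p, kp$value, kp$tolerance,
                kp$note))
  }
  invisible(x)
}

#' Logistic map series
#'
#' Iterates `x[t+1] = r x[t] (1 - x[t])` from `x0` (the transient from `x0`
#' is part of the series).  At r = 4 the maximal Lyapunov exponent is
#' exactly ln 2 per iterate; at r = 3.2 the attractor is a stable
#' period-2 cycle with a negative exponent, both recorded in
#' `known_properties`.
#'
#' @param r Growth parameter, in `(0, 4]`.
#' @param x0 Initial condition in `(0, 1)`.
#' @param n Series length.
#' @return A `benchmark_series`.
#' @export
#' @examples
#' logistic_map(4, 0.3, 5)$values
logistic_map <- function(r, x0, n) {
  if (x0 <= 0 || x0 >= 1) stopf("x0 must lie in (0, 1)")
  if (r <= 0 || r > 4) stopf("r must lie in (0, 4]")
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  kp <- list()
  if (r == 4)
    kp$max_lyapunov <- list(value = log(2), tolerance = 0.1 * log(2),
                            note = "analytic, fully chaotic logistic map")
  if (r > 3 && r < 1 + sqrt(6)) {
    # stable period-2 cycle: lambda = log|f'(x1) f'(x2)| / 2
    x1 <- (r + 1 + sqrt((r - 3) * (r + 1))) / (2 * r)
    x2 <- (r + 1 - sqrt((r - 3) * (r + 1))) / (2 * r)
    lam <- log(abs(r * (1 - 2 * x1) * r * (1 - 2 * x2))) / 2
    kp$max_lyapunov <- list(value = lam, tolerance = abs(lam),
                            note = "analytic, stable period-2 cycle")
  }
  new_benchmark_series("logistic_map", list(r = r, x0 = x0), NA_integer_, x,
                       kp)
}

#' Henon map series
#'
#' Standard recursion `x[t+1] = 1 - a x[t]^2 + y[t]`, `y[t+1] = b x[t]`,
#' returning the x component after a transient discard of 1000 steps.  The
#' initial condition is jittered from the seed; diverging orbits restart
#' (bounded retries).  For the canonical `a = 1.4, b = 0.3` the correlation
#' dimension is about 1.22 (numeric oracle), recorded in
#' `known_properties`.
#'
#' @param a,b Map parameters.
#' @param n Series length (>= 1000).
#' @param seed Seed for the initial condition.
#' @return A `benchmark_series`.
#' @export
henon_map <- function(a = 1.4, b = 0.3, n = 10000, seed = 1L) {
  stopifnot(n >= 1000)
  transient <- 1000L
  withr::with_seed(seed, {
    for (try in 1:20) {
      x <- runif(1, -0.1, 0.1); y <- runif(1, -0.1, 0.1)
      out <- numeric(n)
      ok <- TRUE
      for (t in seq_len(transient + n)) {
        xn <- 1 - a * x^2 + y
        y <- b * x
        x <- xn
        if (!is.finite(x) || abs(x) > 1e6) { ok <- FALSE; break }
        if (t > transient) out[t - transient] <- x
      }
      if (ok) break
    }
    if (!ok) stopf("Henon orbit diverged for all retries")
  })
  kp <- list()
  if (a == 1.4 && b == 0.3)
    kp$correlation_dimension <- list(value = 1.22, tolerance = 0.12,
                                     note = "numeric oracle, canonical attractor")
  new_benchmark_series("henon_map", list(a = a, b = b), seed, out, kp)
}

#' Lorenz system x-component
#'
#' Fixed-step 4th-order Runge-Kutta integration (via `deSolve`) of the
#' Lorenz equations; the x component is returned after discarding a 10
#' time-unit transient.
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @param dt Integration/sampling step (<= 0.02 time units).
#' @param n Number of returned samples.
#' @param x0 Initial state (length 3).
#' @return A `benchmark_series`.
#' @export
lorenz_series <- function(sigma = 10, rho = 28, beta = 8 / 3, dt = 0.01,
                          n = 5000, x0 = c(1, 1, 1)) {
  if (dt > 0.02) stopf("dt must be <= 0.02 for a faithful orbit")
  transient <- ceiling(10 / dt)
  times <- seq(0, (transient + n) * dt, by = dt)
  deriv <- function(t, s, p) {
    list(c(sigma * (s[2] - s[1]),
           s[1] * (rho - s[3]) - s[2],
           s[1] * s[2] - beta * s[3]))
  }
  sol <- deSolve::rk4(y = x0, times = times, func = deriv, parms = NULL)
  x <- sol[, 2]
  if (any(!is.finite(x))) stopf("non-finite Lorenz state")
  x <- x[(transient + 1):(transient + n)]
  new_benchmark_series("lorenz", list(sigma = sigma, rho = rho, beta = beta,
                                      dt = dt), NA_integer_, x)
}

#' Unidirectionally coupled binary processes
#'
#' `X` is i.i.d. fair binary; `Y[t+1]` copies `X[t]` with probability
#' `coupling` and is a fair coin otherwise.  The exact transfer entropies
#' are computed by enumeration of the stationary joint distribution
#' (`TE(X->Y) = 1 - H_b((1 + coupling)/2)` bits, `TE(Y->X) = 0`) and stored
#' in `known_properties`.
#'
#' @param coupling Copy probability in `[0, 1]`.
#' @param n Length of the realisation.
#' @param seed Seed.
#' @return List with `x` and `y` (`benchmark_series`); the known properties
#'   live on `y`.
#' @export
#' @examples
#' cb <- coupled_binary_processes(0.5, 1000, seed = 1)
#' cb$y$known_properties$te_x_to_y$value  # 1 - H_b(0.75) = 0.1887 bits
coupled_binary_processes <- function(coupling, n, seed = 1L) {
  assert_scalar_num(coupling, "coupling", lower = 0, upper = 1)
  withr::with_seed(seed, {
    x <- rbinom(n, 1, 0.5)
    flip <- rbinom(n, 1, coupling) == 1
    y <- integer(n)
    if (n > 1) {
      rnd <- rbinom(n, 1, 0.5)
      y[1] <- rnd[1]
      y[-1] <- ifelse(flip[-1], x[-n], rnd[-1])
    }
  })
  # enumeration oracle: stationary joint p(y_next, y_past, x_past);
  # y_next depends on x_past only, and (x, y) are independent at equal times
  p <- array(0, dim = c(2, 2, 2))
  for (yn in 0:1) for (yp in 0:1) for (xp in 0:1) {
    p_trans <- if (yn == xp) (1 + coupling) / 2 else (1 - coupling) / 2
    p[yn + 1, yp + 1, xp + 1] <- 0.25 * p_trans
  }
  te_xy <- exact_transfer_entropy(p)
  kp <- list(
    te_x_to_y = list(value = te_xy, tolerance = 0.01,
                     note = "enumeration of the exact joint distribution"),
    te_y_to_x = list(value = 0, tolerance = 0.01,
                     note = "Y never influences X")
  )
  list(x = new_benchmark_series("coupled_binary_x",
                                list(coupling = coupling), seed, x),
       y = new_benchmark_series("coupled_binary_y",
                                list(coupling = coupling), seed, y, kp))
}

#' Theta-nested Poisson spike trains
#'
#' Exposes the simulator's drive generator as a benchmark fixture: an
#' inhomogeneous Poisson process with a theta envelope and gamma carrier,
#' mirroring the entorhinal input statistics, for validating the burst and
#' information-flow estimators.
#'
#' @param theta_freq,gamma_freq Envelope and carrier frequencies, Hz.
#' @param rate Mean rate, spikes/s (0 allowed: empty trains).
#' @param duration Duration, ms.
#' @param n_trains Number of independent trains.
#' @param seed Seed.
#' @return List of spike-time vectors.
#' @export
theta_poisson_trains <- function(theta_freq = 8, gamma_freq = 40, rate = 40,
                                 duration = 10000, n_trains = 1, seed = 1L) {
  if (rate <= 0) return(rep(list(numeric(0)), n_trains))
  d <- drive_spec("EC2", theta_frequency = theta_freq,
                  gamma_frequency = gamma_freq, mean_rate = rate)
  generate_drive_trains(d, n_trains, duration, seed = seed)
}
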