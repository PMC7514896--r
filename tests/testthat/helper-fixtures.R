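# Shared fixtures.  Expensive objects are built once per test run and
# memoised in this environment.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a short control simulation used by several suites
short_control_sim <- function(seed = 1, duration = 3000) {
  memo(sprintf("sim_%d_%d", seed, duration), {
    integrate_network(build_default_network(seed = seed,
                                            duration = duration))
  })
}

# the full study design: control + 4 deletion levels x 10 seeds at the
# default duration, with burst statistics per region and the CA3-CA1
# multiunit Lyapunov exponent per run
study_results <- function() {
  memo("study", {
    rows <- list()
    for (f in c(0, 0.09, 0.18, 0.26, 0.35)) {
      for (s in 1:10) {
        cfg <- apply_deletion(build_default_network(seed = s),
                              f, deletion_schedule())
        sim <- integrate_network(cfg)
        bs <- simulation_burst_stats(sim)$per_region
        bs$f <- f
        bs$seed <- s
        bs$lambda <- NA_real_
        bs$lambda[bs$region == "CA3-CA1"] <-
          region_complexity(sim, c("CA3", "CA1"),
                            voltage_metrics = FALSE)$max_lyapunov
        rows[[length(rows) + 1L]] <- bs
      }
    }
    do.call(rbind, rows)
  })
}

study_medians <- function(region) {
  tab <- study_results()
  sub <- tab[tab$region == region, ]
  stats::aggregate(
    cbind(n_spikes, spikes_per_burst, burst_duration, inter_burst_interval,
          lambda) ~ f, sub, stats::median, na.action = stats::na.pass)
}
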