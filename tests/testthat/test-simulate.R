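silence_drives <- function(cfg) {
  cfg$synapses$active[!is.na(cfg$synapses$drive)] <- FALSE
  cfg
}

test_that("NMDA gating is a sigmoid with the right asymptotes", {
  expect_lt(nmda_gating(-1000), 0.001)
  expect_gt(nmda_gating(200), 0.99)
  g <- nmda_gating(c(-60, 0, 40))
  expect_true(g[1] < g[2] && g[2] < g[3])
  expect_true(all(g >= 0 & g <= 1))
  expect_error(nmda_gating(Inf), "finite")
  expect_error(nmda_gating(NA_real_), "finite")
})

test_that("a silenced network stays at rest", {
  cfg <- silence_drives(build_default_network(seed = 1, duration = 500))
  sim <- integrate_network(cfg)
  expect_equal(sum(lengths(sim$spikes)), 0)
  el <- cfg$cells$el[match(colnames(sim$voltage), cfg$cells$label)]
  dev <- sweep(sim$voltage, 2, el)
  expect_lt(max(abs(dev)), 0.1)
})

test_that("identical configuration and seed give bit-identical results", {
  cfg <- build_default_network(seed = 4, duration = 2000)
  a <- integrate_network(cfg)
  b <- integrate_network(cfg)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$voltage, b$voltage)
  expect_identical(a$final_weights, b$final_weights)
})

test_that("per-cell inter-spike intervals respect the refractory period", {
  sim <- short_control_sim()
  cl <- sim$config$cells
  for (lab in cl$label) {
    st <- sim$spikes[[lab]]
    if (length(st) > 1)
      expect_gte(min(diff(st)), cl$refractory[cl$label == lab] - 1e-9)
  }
})

test_that("single-compartment step response matches the analytic RC curve", {
  pars <- default_network_parameters()
  for (class in names(pars$cells)) pars$cells[[class]]$ga <- 0  # decouple
  cfg <- silence_drives(build_default_network(seed = 1, duration = 300,
                                              parameters = pars))
  cfg$cells$threshold[] <- 100  # never spike
  amp <- 0.5
  sim <- integrate_network(cfg, step_current = list(
    cell = 1, comp = 1, amplitude = amp, on = 50, off = 300))
  cell <- cfg$cells[1, ]
  t <- seq(cfg$dt, 300, by = cfg$dt) - 50
  analytic <- ifelse(t <= 0, cell$el,
                     cell$el + amp / cell$gl * (1 - exp(-t * cell$gl / cell$cm)))
  measured <- sim$voltage[, cfg$cells$label[1]]
  # compare after 5 membrane time constants
  idx <- which(t > 5 * cell$cm / cell$gl)
  rel_err <- abs(measured[idx] - analytic[idx]) /
    abs(analytic[idx] - cell$el)
  expect_lt(max(rel_err), 0.01)
})

test_that("control principal cells burst at the theta rhythm", {
  sim <- short_control_sim(seed = 1, duration = 5000)
  theta <- sim$config$drives$EC2$theta_frequency
  onsets <- lapply(sim$config$cells$label[sim$config$cells$principal &
                                            sim$config$cells$region == "CA1"],
                   function(lab) {
    b <- segment_bursts(sim$spikes[[lab]], isi_threshold = 1000 / theta / 4)
    diff(b$start)
  })
  med <- median(unlist(onsets))
  expect_lt(abs(med - 1000 / theta) / (1000 / theta), 0.2)
})

test_that("the LTP rule potentiates on coincidences and saturates", {
  lp <- list(learning_rate = 0.1, weight_ceiling = 2, coincidence_window = 10)
  # no coincidences: unchanged
  expect_equal(apply_ltp(0.5, c(100, 200), c(50, 300), lp), 0.5)
  # at the ceiling: unchanged
  expect_equal(apply_ltp(2, c(10), c(12), lp), 2)
  # k coincidences apply the soft-bounded update sequentially
  w <- 0.2
  for (i in 1:3) w <- w + 0.1 * (1 - w / 2)
  expect_equal(apply_ltp(0.2, c(10, 30, 50), c(12, 32, 52), lp), w)
  # potentiation-only: never decreases, bounded by the ceiling
  out <- apply_ltp(c(0, 1, 1.9), list(1:50 * 10), list(1:50 * 10 + 1), lp)
  expect_true(all(out >= c(0, 1, 1.9)))
  expect_true(all(out <= 2))
  expect_error(apply_ltp(1, 1, 2, list(learning_rate = -1, weight_ceiling = 2,
                                       coincidence_window = 10)))
})

test_that("online LTP weights are non-decreasing and bounded", {
  sim <- short_control_sim()
  cfg <- sim$config
  w0 <- cfg$synapses$weight
  wf <- sim$final_weights
  plastic <- cfg$synapses$plastic
  expect_true(all(wf[plastic] >= w0[plastic] - 1e-12))
  expect_true(all(wf[plastic] <= cfg$ltp$weight_ceiling + 1e-12))
  expect_identical(wf[!plastic], w0[!plastic])
})

test_that("spike and voltage exports round-trip as plain text with sidecar", {
  sim <- short_control_sim()
  csv <- withr::local_tempfile(fileext = ".csv")
  export_spikes(sim, csv)
  df <- read.csv(csv)
  expect_named(df, c("cell_id", "time_ms"))
  expect_equal(nrow(df), sum(lengths(sim$spikes)))
  meta <- jsonlite::read_json(paste0(csv, ".json"))
  expect_equal(meta$dt, sim$config$dt)
  vcsv <- withr::local_tempfile(fileext = ".csv")
  export_voltage(sim, vcsv, every = 100)
  vdf <- read.csv(vcsv, check.names = FALSE)
  expect_equal(ncol(vdf), 22)  # time + 21 cells
})
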