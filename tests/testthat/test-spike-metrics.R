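test_that("spike detection finds one spike per upward crossing, merged", {
  dt <- 0.5
  flat <- rep(-65, 200)
  expect_equal(detect_spikes(flat, dt, -50)$times, numeric(0))
  # three separated square pulses
  v <- rep(-65, 600)
  for (on in c(100, 300, 500)) v[on:(on + 10)] <- -40
  st <- detect_spikes(v, dt, -50, refractory = 2)
  expect_length(st$times, 3)
  # onsets to within one sample
  expect_equal(st$times, (c(100, 300, 500) - 1) * dt, tolerance = 1e-9)
  # rapid pulse train (0.5 ms spacing) merged by a 2 ms refractory window
  v2 <- rep(-65, 40)
  v2[seq(10, 16, by = 2)] <- -40
  v2[seq(11, 17, by = 2)] <- -65
  st2 <- detect_spikes(v2, dt = 0.25, -50, refractory = 2)
  expect_length(st2$times, 1)
  expect_error(detect_spikes(c(-65, NaN), dt), "non-finite")
})

test_that("burst segmentation matches hand-computed runs", {
  b <- segment_bursts(c(0, 5, 8, 100, 104), isi_threshold = 20)
  expect_equal(nrow(b), 2)
  expect_equal(b$start, c(0, 100))
  expect_equal(b$end, c(8, 104))
  expect_equal(b$n_spikes, c(3L, 2L))
  expect_equal(nrow(segment_bursts(numeric(0), 20)), 0)
  expect_equal(nrow(segment_bursts(c(0, 50, 100), 20)), 0)  # all isolated
  expect_error(segment_bursts(c(0, 1), 0))
})

test_that("burst statistics reproduce the worked example", {
  s <- burst_statistics(c(0, 5, 8, 100, 104), isi_threshold = 20)
  expect_equal(s$n_spikes, 5)
  expect_equal(s$n_bursts, 2)
  expect_equal(s$spikes_per_burst, 2.5)
  expect_equal(s$burst_duration, 6.0)
  expect_equal(s$inter_burst_interval, 92)
  empty <- burst_statistics(numeric(0), 20)
  expect_equal(empty$n_spikes, 0)
  expect_true(is.na(empty$spikes_per_burst))
  expect_true(is.na(empty$inter_burst_interval))
  single <- burst_statistics(c(0, 5), 20)
  expect_false(is.na(single$burst_duration))
  expect_true(is.na(single$inter_burst_interval))
})

test_that("statistics are invariant under time shifts", {
  base <- c(3, 9, 14, 140, 147, 152, 300, 306)
  a <- burst_statistics(base, 30)
  b <- burst_statistics(base + 57.3, 30)
  for (m in c("n_spikes", "spikes_per_burst", "burst_duration",
              "inter_burst_interval"))
    expect_equal(a[[m]], b[[m]])
})

test_that("burst spike counts never exceed the train's spike count", {
  withr::with_seed(5, {
    for (rep in 1:20) {
      times <- sort(runif(sample(0:40, 1), 0, 1000))
      times <- times[c(TRUE, diff(times) > 0)]
      b <- segment_bursts(times, isi_threshold = runif(1, 5, 50))
      expect_lte(sum(b$n_spikes), length(times))
      if (nrow(b) > 0) expect_true(all(b$n_spikes >= 2))
      if (nrow(b) > 1) expect_true(all(diff(b$start) > 0))
    }
  })
})

test_that("region aggregation averages principal cells and skips NAs", {
  cells <- build_default_network(seed = 1)$cells
  stats <- setNames(vector("list", nrow(cells)), cells$label)
  for (lab in cells$label)
    stats[[lab]] <- structure(list(n_spikes = 10, n_bursts = 2,
                                   spikes_per_burst = 3, burst_duration = 20,
                                   inter_burst_interval = 100),
                              class = "burst_stats")
  stats[["G1"]]$n_spikes <- 20                 # DG mean becomes 12.5
  stats[["P1"]]$inter_burst_interval <- NA     # excluded from CA3 mean
  agg <- region_aggregate(stats, cells)
  expect_equal(agg$n_spikes[agg$region == "DG"], 12.5)
  expect_equal(agg$inter_burst_interval[agg$region == "CA3"], 100)
  # union = mean over the 12 principal cells
  expect_equal(agg$n_spikes[agg$region == "DG-CA3-CA1"],
               mean(c(20, rep(10, 11))))
  # interneuron stats are excluded by default
  stats[["B1"]]$n_spikes <- 1e6
  agg2 <- region_aggregate(stats, cells)
  expect_equal(agg2$n_spikes[agg2$region == "DG"], 12.5)
})

test_that("theta-locked trains close the burst cycle", {
  # bursts of 4 spikes every 125 ms: duration + IBI = one cycle
  onsets <- seq(0, 4000, by = 125)
  times <- as.vector(outer(onsets, c(0, 8, 16, 24), `+`))
  s <- burst_statistics(sort(times), isi_threshold = 31.25)
  expect_equal(s$burst_duration + s$inter_burst_interval, 125)
})
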