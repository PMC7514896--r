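# Integration of a network_config into a simulation_result.

#' Voltage dependence of the NMDA receptor (magnesium block)
#'
#' Jahr-Stevens style sigmoid: `1 / (1 + [Mg]/3.57 * exp(-0.062 V))`.
#' Monotone increasing in voltage, 0 as `V -> -Inf`, 1 as `V -> +Inf`.
#'
#' @param voltage Membrane potential(s), mV.  Must be finite.
#' @param mg Extracellular magnesium concentration, mM.
#' @return Unitless gating factor(s) in `[0, 1]`.
#' @export
#' @examples
#' nmda_gating(c(-80, -40, 0))
nmda_gating <- function(voltage, mg = 1) {
  if (!is.numeric(voltage) || any(!is.finite(voltage)))
    stopf("nmda_gating: voltage must be finite")
  nmda_gating_cpp(as.numeric(voltage), mg)
}

#' Simulate a network configuration
#'
#' Integrates the compartmental network with exponential-Euler steps of
#' `config$dt` ms: passive compartments with axial coupling, AMPA/NMDA/GABA-A
#' difference-of-exponentials conductances (NMDA gated by [nmda_gating()]),
#' threshold-reset spiking at the soma with an absolute refractory period,
#' and the online potentiation-only LTP rule of [apply_ltp()].  Drive spike
#' trains are generated from `config$seed`; trains are drawn for every drive
#' synapse whether active or not, so deleting synapses never reshuffles the
#' input realisation of the survivors.  Identical configurations (including
#' seed) give bit-identical results.
#'
#' @param config A validated `network_config`.
#' @param step_current Optional list `(cell, comp, amplitude, on, off)`
#'   injecting a constant current (uA/cm^2) into one compartment between
#'   `on` and `off` ms; used for calibration and passive-response checks.
#' @return An object of class `simulation_result`: `voltage` (matrix of
#'   somatic potentials, `duration/dt` rows by one column per cell, labelled),
#'   `spikes` (named list of sorted spike-time vectors, ms), `final_weights`
#'   (numeric, one per synapse) and `config` (the configuration as run).
#' @export
#' @examples
#' cfg <- build_default_network(seed = 1, duration = 500)
#' sim <- integrate_network(cfg)
#' lengths(sim$spikes)
integrate_network <- function(config, step_current = NULL) {
  validate_network_config(config)
  cl <- config$cells
  sy <- config$synapses
  n_steps <- as.integer(round(config$duration / config$dt))

  drive_steps <- vector("list", nrow(sy))
  for (src in names(config$drives)) {
    idx <- which(!is.na(sy$drive) & sy$drive == src)
    if (!length(idx)) next
    drv <- config$drives[[src]]
    drv$source <- src
    trains <- generate_drive_trains(
      drv, n_targets = length(idx), duration = config$duration,
      dt = config$dt,
      seed = derive_seed(config$seed, drv$seed_offset %||% 0))
    for (k in seq_along(idx))
      drive_steps[[idx[k]]] <- as.integer(floor(trains[[k]] / config$dt))
  }

  cur <- c(-1, -1, 0, 0, 0)
  if (!is.null(step_current))
    cur <- c(step_current$cell - 1L, step_current$comp - 1L,
             step_current$amplitude, step_current$on, step_current$off)

  pre0 <- ifelse(is.na(sy$pre), -1L, as.integer(sy$pre - 1L))
  rec <- match(sy$receptor, .receptor_types) - 1L  # 0 AMPA, 1 NMDA, 2 GABA_A

  raw <- simulate_network_cpp(
    n_cells = nrow(cl), n_comp = 16L,
    cm = cl$cm, gl = cl$gl, el = cl$el, ga = cl$ga, parent = .parent_vec(),
    thr = cl$threshold, vreset = cl$reset, refr = cl$refractory,
    syn_pre = pre0, syn_post = as.integer(sy$post - 1L),
    syn_comp = as.integer(sy$comp), syn_rec = rec,
    syn_w = sy$weight, syn_gmax = sy$gmax, syn_taur = sy$tau_rise,
    syn_taud = sy$tau_decay, syn_erev = sy$reversal,
    syn_delay = as.integer(round(sy$delay / config$dt)),
    syn_active = sy$active, syn_plastic = sy$plastic,
    drive_steps = drive_steps,
    ltp_lr = config$ltp$learning_rate, ltp_ceiling = config$ltp$weight_ceiling,
    ltp_window = config$ltp$coincidence_window,
    dt = config$dt, n_steps = n_steps, mg_conc = config$mg,
    step_current = cur)

  colnames(raw$voltage) <- cl$label
  names(raw$spikes) <- cl$label
  structure(list(voltage = raw$voltage, spikes = raw$spikes,
                 final_weights = raw$final_weights, config = config),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d cells, %g ms at dt = %g ms\n",
              ncol(x$voltage), x$config$duration, x$config$dt))
  cat(sprintf("  total spikes: %d\n", sum(lengths(x$spikes))))
  invisible(x)
}

#' Potentiation-only LTP update from spike trains
#'
#' The offline counterpart of the integrator's online rule.  Every
#' coincidence -- a presynaptic spike within `coincidence_window` ms at or
#' before a postsynaptic spike -- potentiates the weight by
#' `learning_rate * (1 - w / weight_ceiling)`, applied sequentially in
#' postsynaptic spike order, so weights are non-decreasing and saturate
#' softly at the ceiling.  No depression term exists.
#'
#' @param weights Numeric vector of non-negative synaptic weights.
#' @param pre_spike_times,post_spike_times Either single numeric vectors
#'   (applied to every weight) or lists with one vector per weight.
#' @param ltp_params List with `learning_rate` (>= 0), `weight_ceiling` and
#'   `coincidence_window` (ms).
#' @return Updated weight vector.
#' @export
#' @examples
#' apply_ltp(0.5, pre_spike_times = c(10, 30), post_spike_times = c(12, 35),
#'           ltp_params = list(learning_rate = 0.1, weight_ceiling = 2,
#'                             coincidence_window = 10))
apply_ltp <- function(weights, pre_spike_times, post_spike_times, ltp_params) {
  lr <- ltp_params$learning_rate
  if (lr < 0) stopf("learning_rate must be non-negative")
  ceil <- ltp_params$weight_ceiling
  win <- ltp_params$coincidence_window
  if (any(weights < 0)) stopf("weights must be non-negative")
  if (!is.list(pre_spike_times)) pre_spike_times <- list(pre_spike_times)
  if (!is.list(post_spike_times)) post_spike_times <- list(post_spike_times)
  pre_spike_times <- rep_len(pre_spike_times, length(weights))
  post_spike_times <- rep_len(post_spike_times, length(weights))
  out <- weights
  for (i in seq_along(out)) {
    w <- out[i]
    for (tp in sort(post_spike_times[[i]])) {
      pre <- pre_spike_times[[i]]
      k <- sum(pre >= tp - win & pre <= tp)
      for (j in seq_len(k)) w <- min(ceil, w + lr * (1 - w / ceil))
    }
    out[i] <- w
  }
  out
}

#' Export spike times / voltage traces to plain-text files
#'
#' Spike times go to a two-column CSV (`cell_id`, `time_ms`); voltage traces
#' to a wide CSV (`time_ms` plus one column per cell), both with a JSON
#' sidecar (`<path>.json`) recording `dt`, `seed` and the configuration hash.
#'
#' @param sim A `simulation_result`.
#' @param path Output CSV path.
#' @param every Write every `every`-th voltage sample (default all).
#' @return `path`, invisibly.
#' @export
export_spikes <- function(sim, path) {
  df <- data.frame(
    cell_id = rep(names(sim$spikes), lengths(sim$spikes)),
    time_ms = unlist(sim$spikes, use.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  .write_sidecar(sim, path)
  invisible(path)
}

#' @rdname export_spikes
#' @export
export_voltage <- function(sim, path, every = 1L) {
  idx <- seq(1L, nrow(sim$voltage), by = every)
  df <- data.frame(time_ms = (idx - 1) * sim$config$dt * 1 + sim$config$dt,
                   sim$voltage[idx, , drop = FALSE], check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  .write_sidecar(sim, path)
  invisible(path)
}

.write_sidecar <- function(sim, path) {
  meta <- list(dt = sim$config$dt, seed = sim$config$seed,
               duration = sim$config$duration,
               config_hash = config_hash(sim$config))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
}
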