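# Orchestration of the full study design: control plus staged-deletion
# simulations over replicate seeds, burst / complexity / information-flow
# metrics per region, and rank-correlation trend summaries.

#' Specify a full degeneration experiment
#'
#' @param base_seed First simulation seed; replicate `i` uses
#'   `base_seed + i - 1`.
#' @param n_seeds Number of replicate seeds per deletion level.
#' @param duration Simulation duration, ms.
#' @param schedule A [deletion_schedule()].
#' @param isi_threshold Burst ISI threshold, ms (`NULL`: quarter theta
#'   period).
#' @param bin_width Information-flow bin width, ms.
#' @param discard Initial transient discarded from analysis signals, ms.
#' @param complexity Compute the (costlier) complexity metrics (logical).
#' @param out_dir Output directory for resumable runs (`NULL`: in-memory
#'   only).
#' @param parameters Network parameter list (see
#'   [default_network_parameters()]).
#' @return List of class `experiment_spec`.
#' @export
experiment_spec <- function(base_seed = 1L, n_seeds = 10L, duration = 16000,
                            schedule = deletion_schedule(),
                            isi_threshold = NULL, bin_width = 10,
                            discard = 500, complexity = TRUE, out_dir = NULL,
                            parameters = default_network_parameters()) {
  stopifnot(n_seeds >= 1)
  structure(list(base_seed = as.integer(base_seed),
                 n_seeds = as.integer(n_seeds), duration = duration,
                 schedule = schedule, isi_threshold = isi_threshold,
                 bin_width = bin_width, discard = discard,
                 complexity = complexity, out_dir = out_dir,
                 parameters = parameters),
            class = "experiment_spec")
}

.result_row <- function(region, fraction, seed, metric, value, units) {
  data.frame(region = region, deletion_fraction = fraction, seed = seed,
             metric = metric, value = as.numeric(value), units = units)
}

#' Complexity metrics of one simulated region
#'
#' Computes the three complexity measures for a region (or region union) of
#' a simulation.  The maximal Lyapunov exponent is estimated on the
#' discrete multiunit count series ([region_activity()]) with a fixed
#' short-delay planar embedding, a Theiler window of one theta period and a
#' fit window inside the first period -- the regime in which a stereotyped
#' theta-locked network yields a non-positive slope (distinct count
#' patterns relax back to the common cycle) while cycle-skipping degenerate
#' networks yield a positive one.  The correlation dimension and
#' recurrence-plot entropy are estimated on the continuous averaged voltage
#' ([region_voltage()]), whose amplitudes suit distance-based estimators.
#'
#' @param sim A `simulation_result`.
#' @param regions Regions to pool.
#' @param bin_width,clip,discard Activity-series settings, see
#'   [region_activity()].
#' @param lyap_fit Fit window (in bins) for the Lyapunov slope.
#' @param voltage_metrics Also compute the voltage-based correlation
#'   dimension and recurrence entropy (slower); `FALSE` returns only the
#'   Lyapunov exponent.
#' @return List: `max_lyapunov` (per bin), `max_lyapunov_per_ms`,
#'   `correlation_dimension`, `rqa_entropy` (bits), plus `detail`.
#' @export
region_complexity <- function(sim, regions, bin_width = 5, clip = 2,
                              discard = 500, lyap_fit = c(3, 15),
                              voltage_metrics = TRUE) {
  theta <- sim$config$drives[[1]]$theta_frequency
  period_bins <- max(2L, round(1000 / theta / bin_width))
  act <- region_activity(sim, regions, bin_width, clip, discard)
  emb_a <- embedding_params(5, 2, theiler = period_bins)
  ly <- max_lyapunov(act, emb_a, fit_window = lyap_fit,
                     kmax = max(lyap_fit[2], period_bins), dist_floor = 0.5)
  d2 <- list(value = NA_real_)
  rq <- list(entropy = NA_real_)
  emb_v <- NULL
  if (isTRUE(voltage_metrics)) {
    volt <- region_voltage(sim, regions, sample_every = 1, smooth_sd = 2,
                           discard = discard)
    del <- ami_delay(volt, max_lag = round(1000 / theta / 2))$delay
    emb_v <- embedding_params(del, 3, theiler = round(1000 / theta))
    d2 <- tryCatch(correlation_dimension(volt, emb_v),
                   error = function(e) list(value = NA_real_))
    rq <- tryCatch(rqa_entropy(volt, emb_v),
                   error = function(e) list(entropy = NA_real_))
  }
  list(max_lyapunov = ly$value, max_lyapunov_per_ms = ly$value / bin_width,
       correlation_dimension = d2$value, rqa_entropy = rq$entropy,
       detail = list(lyapunov = ly, correlation_dimension = d2, rqa = rq,
                     activity_embedding = emb_a, voltage_embedding = emb_v))
}

# all metrics of one simulated condition -> tidy rows
.analyse_condition <- function(sim, spec, fraction, seed) {
  rows <- list()
  bs <- simulation_burst_stats(sim, isi_threshold = spec$isi_threshold)
  units <- c(n_spikes = "count", spikes_per_burst = "count",
             burst_duration = "ms", inter_burst_interval = "ms")
  for (i in seq_len(nrow(bs$per_region))) {
    for (m in .burst_stat_names) {
      rows[[length(rows) + 1L]] <- .result_row(
        bs$per_region$region[i], fraction, seed, m,
        bs$per_region[[m]][i], units[[m]])
    }
  }
  flow <- simulation_infoflow(sim, bin_width = spec$bin_width)
  for (r in names(flow$entropy))
    rows[[length(rows) + 1L]] <- .result_row(
      r, fraction, seed, "shannon_entropy", flow$entropy[[r]], "bits")
  for (p in names(flow$mi))
    rows[[length(rows) + 1L]] <- .result_row(
      p, fraction, seed, "mutual_information", flow$mi[[p]], "bits")
  for (p in names(flow$te))
    rows[[length(rows) + 1L]] <- .result_row(
      p, fraction, seed, "transfer_entropy", flow$te[[p]], "bits")
  if (isTRUE(spec$complexity)) {
    for (g in names(.region_groups())) {
      cm <- region_complexity(sim, .region_groups()[[g]],
                              discard = spec$discard)
      rows[[length(rows) + 1L]] <- .result_row(
        g, fraction, seed, "correlation_dimension",
        cm$correlation_dimension, "unitless")
      rows[[length(rows) + 1L]] <- .result_row(
        g, fraction, seed, "rqa_entropy", cm$rqa_entropy, "bits")
      rows[[length(rows) + 1L]] <- .result_row(
        g, fraction, seed, "max_lyapunov", cm$max_lyapunov, "per_bin")
    }
  }
  do.call(rbind, rows)
}

#' Run the full control-versus-deletion experiment
#'
#' For every deletion level (control plus each scheduled fraction) and every
#' replicate seed: build the network, apply the deletion, simulate, and
#' compute burst statistics, information-flow metrics and (optionally)
#' complexity metrics per region and region union.  Transfer entropies are
#' additionally control-normalised within each seed.  With `out_dir` set,
#' finished levels are written to per-level CSV chunks guarded by a
#' configuration hash and skipped on re-run, making long runs resumable;
#' a hash mismatch on resume aborts.
#'
#' @param spec An [experiment_spec()].
#' @param verbose Print progress.
#' @return A tidy data frame of class `result_table` with columns `region`,
#'   `deletion_fraction`, `seed`, `metric`, `value`, `units`, and metadata
#'   attributes (`config_hash`, `created`).
#' @export
run_experiment <- function(spec = experiment_spec(), verbose = FALSE) {
  fractions <- c(0, spec$schedule$fractions)
  hash <- config_hash(spec[setdiff(names(spec), "out_dir")])
  use_disk <- !is.null(spec$out_dir)
  if (use_disk) {
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
    meta_path <- file.path(spec$out_dir, "experiment-meta.json")
    if (file.exists(meta_path)) {
      meta <- jsonlite::read_json(meta_path)
      if (!identical(meta$config_hash, hash))
        stopf("resume aborted: existing results were produced by a different spec (hash mismatch)")
    } else {
      jsonlite::write_json(list(config_hash = hash,
                                created = format(Sys.time())),
                           meta_path, auto_unbox = TRUE)
    }
  }
  level_tables <- list()
  for (fr in fractions) {
    tag <- sprintf("level_%02d", round(100 * fr))
    chunk <- if (use_disk) file.path(spec$out_dir, paste0(tag, ".csv"))
    if (use_disk && file.exists(chunk)) {
      if (verbose) message("resuming: skipping ", tag)
      level_tables[[tag]] <- read.csv(chunk)
      next
    }
    rows <- list()
    for (i in seq_len(spec$n_seeds)) {
      seed <- spec$base_seed + i - 1L
      cfg <- build_default_network(seed = seed, duration = spec$duration,
                                   parameters = spec$parameters)
      cfg <- apply_deletion(cfg, fr, spec$schedule)
      res <- tryCatch(
        .analyse_condition(integrate_network(cfg), spec, fr, seed),
        error = function(e) {
          warning(sprintf("level %s seed %d failed: %s", tag, seed,
                          conditionMessage(e)))
          NULL
        })
      rows[[length(rows) + 1L]] <- res
      if (verbose) message(sprintf("  %s seed %d done", tag, seed))
    }
    tab <- do.call(rbind, rows)
    if (use_disk) write.csv(tab, chunk, row.names = FALSE)
    level_tables[[tag]] <- tab
  }
  out <- do.call(rbind, level_tables)
  rownames(out) <- NULL
  out <- .add_control_ratios(out)
  attr(out, "config_hash") <- hash
  attr(out, "created") <- format(Sys.time())
  class(out) <- c("result_table", "data.frame")
  out
}

# control-normalised transfer entropy, within seed and directed pair
.add_control_ratios <- function(tab) {
  te <- tab[tab$metric == "transfer_entropy", ]
  if (!nrow(te)) return(tab)
  ctrl <- te[te$deletion_fraction == 0, ]
  key <- paste(te$region, te$seed)
  ckey <- paste(ctrl$region, ctrl$seed)
  ref <- ctrl$value[match(key, ckey)]
  ratio <- ifelse(is.finite(ref) & ref > 0, 100 * te$value / ref, NA_real_)
  extra <- te
  extra$metric <- "te_control_ratio"
  extra$value <- ratio
  extra$units <- "percent"
  rbind(tab, extra)
}

#' Rank-correlation trends across deletion levels
#'
#' For every metric and region, the Spearman correlation between deletion
#' fraction and metric value, pooled over seeds, with a direction flag.
#'
#' @param table A `result_table` from [run_experiment()].
#' @return Data frame: `region`, `metric`, `rho`, `p_value`, `direction`
#'   (`"increasing"`, `"decreasing"` or `"flat"`/`NA`).
#' @export
summarize_trends <- function(table) {
  if (length(unique(table$deletion_fraction)) < 2)
    stopf("need at least two deletion levels")
  combos <- unique(table[, c("region", "metric")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- table[table$region == combos$region[i] &
                   table$metric == combos$metric[i], ]
    sub <- sub[is.finite(sub$value), ]
    rho <- p <- NA_real_
    if (nrow(sub) >= 3 && var(sub$value) > 0 &&
        length(unique(sub$deletion_fraction)) >= 2) {
      ct <- suppressWarnings(
        cor.test(sub$deletion_fraction, sub$value, method = "spearman"))
      rho <- unname(ct$estimate)
      p <- ct$p.value
    }
    data.frame(region = combos$region[i], metric = combos$metric[i],
               rho = rho, p_value = p,
               direction = if (!is.finite(rho)) NA_character_
                           else if (rho > 0) "increasing"
                           else if (rho < 0) "decreasing" else "flat")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
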