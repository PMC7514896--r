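# Construction of the default 21-cell DG-CA3-CA1 network configuration.
#
# Topology (wiring and target compartments) is structural and fixed here;
# every quantitative parameter comes from the versioned YAML defaults.

.make_cells <- function(defaults) {
  lab <- .default_cell_labels
  class <- c(rep("granule", 4), rep("basket", 2), "mossy",
             rep("pyramidal", 4), rep("basket", 2), "olm",
             rep("pyramidal", 4), rep("basket", 2), "olm")
  region <- c(rep("DG", 7), rep("CA3", 7), rep("CA1", 7))
  pars <- lapply(class, cell_parameters, defaults = defaults)
  data.frame(
    id = seq_along(lab), label = lab, class = class, region = region,
    principal = class %in% c("granule", "pyramidal"),
    cm = vapply(pars, `[[`, 0, "cm"), gl = vapply(pars, `[[`, 0, "gl"),
    el = vapply(pars, `[[`, 0, "el"), ga = vapply(pars, `[[`, 0, "ga"),
    threshold = vapply(pars, `[[`, 0, "threshold"),
    reset = vapply(pars, `[[`, 0, "reset"),
    refractory = vapply(pars, `[[`, 0, "refractory")
  )
}

# one excitatory contact = AMPA synapse (+ NMDA twin when nmda_ratio > 0);
# `weight_scale` thins selected contacts (e.g. collaterals onto interneurons)
.syn_rows <- function(pre, post, comp, pathway, defaults, drive = NA_character_,
                      receptors = c("AMPA", "NMDA"), weight_scale = 1) {
  pw <- defaults$pathways[[pathway]]
  if (is.null(pw)) stopf("no default parameters for pathway '%s'", pathway)
  rows <- list()
  for (rec in receptors) {
    if (rec == "NMDA" && pw$nmda_ratio <= 0) next
    rc <- defaults$receptors[[rec]]
    rows[[length(rows) + 1L]] <- data.frame(
      pre = pre, post = post, comp = comp, receptor = rec,
      weight = pw$weight * weight_scale,
      gmax = if (rec == "NMDA") pw$gmax * pw$nmda_ratio else pw$gmax,
      tau_rise = rc$tau_rise, tau_decay = rc$tau_decay,
      reversal = rc$reversal, delay = pw$delay, pathway = pathway,
      active = TRUE, plastic = isTRUE(pw$plastic) && rec != "GABA_A",
      drive = drive
    )
  }
  do.call(rbind, rows)
}

.make_synapses <- function(cells, defaults) {
  id <- function(lab) cells$id[match(lab, cells$label)]
  G <- id(c("G1", "G2", "G3", "G4")); Bdg <- id(c("B1", "B2")); MC <- id("MC")
  P3 <- id(c("P1", "P2", "P3", "P4")); B3 <- id(c("B3", "B4")); O3 <- id("OLM1")
  P1 <- id(c("P5", "P6", "P7", "P8")); B1c <- id(c("B5", "B6")); O1 <- id("OLM2")
  syn <- list()
  add <- function(x) syn[[length(syn) + 1L]] <<- x

  # --- EC2 perforant-path contacts -------------------------------------
  # Contacts are laid down in rounds across all target cells (contact 1 of
  # every cell, then contact 2, ...), so the index-ordered deletion of the
  # degeneration model thins every target's entorhinal drive in lockstep,
  # the diffuse denervation regime of early AD-like pathology.
  ec2_targets <- list(
    list(post = G[1], comp = c(11, 12, 13, 14), pw = "EC2_to_DG_granule"),
    list(post = P3[1], comp = c(11, 12, 13, 14), pw = "EC2_to_CA3_pyramidal"),
    list(post = G[2], comp = c(11, 12, 13, 14), pw = "EC2_to_DG_granule"),
    list(post = P3[2], comp = c(11, 12, 13, 14), pw = "EC2_to_CA3_pyramidal"),
    list(post = G[3], comp = c(11, 12, 13, 14), pw = "EC2_to_DG_granule"),
    list(post = P3[3], comp = c(11, 12, 13, 14), pw = "EC2_to_CA3_pyramidal"),
    list(post = Bdg[1], comp = c(8, 9), pw = "EC2_to_DG_basket"),
    list(post = G[4], comp = c(11, 12, 13, 14), pw = "EC2_to_DG_granule"),
    list(post = P3[4], comp = c(11, 12, 13, 14), pw = "EC2_to_CA3_pyramidal"),
    list(post = B3[1], comp = c(8, 9), pw = "EC2_to_CA3_basket"),
    list(post = Bdg[2], comp = c(8, 9), pw = "EC2_to_DG_basket"),
    list(post = B3[2], comp = c(8, 9), pw = "EC2_to_CA3_basket")
  )
  max_contacts <- max(vapply(ec2_targets, function(x) length(x$comp), 0L))
  for (j in seq_len(max_contacts)) {       # contact j of every target cell
    for (tg in ec2_targets) {
      if (j > length(tg$comp)) next
      add(.syn_rows(NA_integer_, tg$post, tg$comp[j], tg$pw, defaults,
                    drive = "EC2", receptors = "AMPA"))
    }
  }

  # --- EC3 temporoammonic input to CA1 distal dendrites ----------------
  for (p in P1)
    add(.syn_rows(NA_integer_, p, 15, "EC3_to_CA1", defaults, drive = "EC3"))

  # --- septal theta-locked inhibition of interneurons ------------------
  for (i in c(Bdg, B3, O3, B1c, O1))
    add(.syn_rows(NA_integer_, i, 1, "septal", defaults, drive = "septum",
                  receptors = "GABA_A"))

  # --- mossy fibers: granule -> CA3 pyramidal / CA3 basket / mossy cell -
  for (k in seq_along(G)) {
    add(.syn_rows(G[k], P3[k], 4, "mossy_fiber", defaults))
    add(.syn_rows(G[k], P3[k %% 4 + 1], 4, "mossy_fiber", defaults))
    add(.syn_rows(G[k], B3[(k - 1) %% 2 + 1], 3, "mossy_fiber", defaults,
                  weight_scale = 0.18))
    add(.syn_rows(G[k], MC, 4, "mossy_fiber", defaults, weight_scale = 0.6))
  }

  # --- mossy cell feedback onto DG -------------------------------------
  for (g in G) add(.syn_rows(MC, g, 5, "mossy_cell_feedback", defaults))
  for (b in Bdg) add(.syn_rows(MC, b, 3, "mossy_cell_feedback", defaults))

  # --- Schaffer collaterals: CA3 pyramidal -> CA1 ----------------------
  for (k in seq_along(P3)) {
    add(.syn_rows(P3[k], P1[k], 5, "schaffer", defaults))
    add(.syn_rows(P3[k], P1[k %% 4 + 1], 5, "schaffer", defaults))
    add(.syn_rows(P3[k], B1c[(k - 1) %% 2 + 1], 3, "schaffer", defaults,
                  weight_scale = 0.15))
  }

  # --- local excitation of O-LM cells ----------------------------------
  for (p in P3) add(.syn_rows(p, O3, 3, "local_excitation", defaults))
  for (p in P1) add(.syn_rows(p, O1, 3, "local_excitation", defaults))

  # --- local inhibition: basket -> soma, O-LM -> distal dendrite -------
  for (b in Bdg) for (g in G)
    add(.syn_rows(b, g, 1, "local_inhibition", defaults, receptors = "GABA_A"))
  for (b in B3) for (p in P3)
    add(.syn_rows(b, p, 1, "local_inhibition", defaults, receptors = "GABA_A"))
  for (b in B1c) for (p in P1)
    add(.syn_rows(b, p, 1, "local_inhibition", defaults, receptors = "GABA_A"))
  for (p in P3)
    add(.syn_rows(O3, p, 16, "local_inhibition", defaults, receptors = "GABA_A"))
  for (p in P1)
    add(.syn_rows(O1, p, 16, "local_inhibition", defaults, receptors = "GABA_A"))

  out <- do.call(rbind, syn)
  rownames(out) <- NULL
  out
}

#' Build the default 21-cell DG-CA3-CA1 network configuration
#'
#' Constructs the full control-model configuration: 4 granule + 2 basket +
#' 1 mossy cell in DG, 4 pyramidal + 2 basket + 1 O-LM cell in each of CA3
#' and CA1, wired with perforant-path (EC2), temporoammonic (EC3), mossy
#' fiber, Schaffer, local inhibitory and septal pathways, plus
#' theta/gamma-patterned external drives and the LTP rule constants.
#'
#' @param seed Integer seed controlling every stochastic element of the
#'   simulation (drive spike trains).
#' @param duration Simulation length in ms (default from the parameter file).
#' @param parameters Parsed parameter list, see
#'   [default_network_parameters()].
#' @return An object of class `network_config`: a list with `cells`
#'   (data frame), `synapses` (data frame), `drives`, `ltp`, `dt`,
#'   `duration`, `mg`, `seed` and `schema_version`.
#' @export
#' @examples
#' cfg <- build_default_network(seed = 1)
#' nrow(cfg$cells)    # 21
#' table(cfg$synapses$pathway)
build_default_network <- function(seed = 1L, duration = NULL,
                                  parameters = default_network_parameters()) {
  cells <- .make_cells(parameters)
  synapses <- .make_synapses(cells, parameters)
  # LTP lives at excitatory synapses onto principal cells only
  synapses$plastic <- synapses$plastic &
    cells$principal[match(synapses$post, cells$id)]
  cfg <- structure(list(
    schema_version = parameters$schema_version,
    cells = cells, synapses = synapses, drives = parameters$drives,
    ltp = parameters$ltp, dt = parameters$dt,
    duration = duration %||% parameters$duration,
    mg = parameters$mg_mM, seed = as.integer(seed)
  ), class = "network_config")
  validate_network_config(cfg)
  cfg
}

#' Validate a network configuration
#'
#' Checks the structural invariants of a `network_config`: cell classes and
#' regions from the closed vocabularies, positive capacitances, a spike
#' threshold above the leak reversal, synapses referencing existing cells and
#' valid compartments, receptor kinetics with `tau_decay > tau_rise > 0`,
#' GABA-A reversal below the leak reversal, pathway tags from the closed
#' vocabulary, positive `dt`, and a duration of at least one theta period.
#'
#' @param config A `network_config`.
#' @return The config, invisibly; errors describe the first violation.
#' @export
validate_network_config <- function(config) {
  if (!inherits(config, "network_config")) stopf("not a network_config")
  cl <- config$cells
  stopifnot(all(cl$class %in% .cell_classes), all(cl$region %in% .regions),
            all(cl$cm > 0), all(cl$gl >= 0), all(cl$threshold > cl$el),
            all(cl$refractory > 0))
  sy <- config$synapses
  stopifnot(all(sy$receptor %in% .receptor_types),
            all(sy$pathway %in% .pathway_vocabulary),
            all(sy$tau_decay > sy$tau_rise), all(sy$tau_rise > 0),
            all(sy$delay >= 0), all(sy$weight >= 0), all(sy$gmax >= 0))
  if (!all(is.na(sy$pre) | sy$pre %in% cl$id))
    stopf("synapse references a non-existent presynaptic cell")
  if (!all(sy$post %in% cl$id)) stopf("synapse references a non-existent cell")
  if (!all(sy$comp %in% 1:16)) stopf("synapse targets an invalid compartment")
  gaba <- sy$receptor == "GABA_A"
  if (any(sy$reversal[gaba] >= cl$el[match(sy$post[gaba], cl$id)]))
    stopf("GABA_A reversal must lie below the leak reversal")
  assert_scalar_num(config$dt, "dt", lower = 1e-6)
  theta <- min(vapply(config$drives, function(d) d$theta_frequency, 0))
  if (config$duration < 1000 / theta)
    stopf("duration must cover at least one theta period")
  invisible(config)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %d cells, %d synapses (%d active)\n",
              nrow(x$cells), nrow(x$synapses), sum(x$synapses$active)))
  cat(sprintf("  dt = %g ms, duration = %g ms, seed = %d\n",
              x$dt, x$duration, x$seed))
  print(table(pathway = x$synapses$pathway, active = x$synapses$active))
  invisible(x)
}

#' Read / write a network configuration as structured text
#'
#' Configurations round-trip through YAML with an explicit schema version;
#' data-frame fields are stored as column lists.
#'
#' @param config A `network_config`.
#' @param path File path.
#' @return `write_network_config` returns `path` invisibly;
#'   `read_network_config` returns a validated `network_config`.
#' @export
write_network_config <- function(config, path) {
  validate_network_config(config)
  obj <- unclass(config)
  obj$cells <- as.list(config$cells)
  obj$synapses <- lapply(as.list(config$synapses), function(col) {
    if (is.numeric(col)) col else as.character(col)
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$schema_version, "1.0"))
    stopf("unsupported config schema version: %s",
          obj$schema_version %||% "<missing>")
  obj$cells <- as.data.frame(obj$cells)
  syn <- as.data.frame(obj$synapses)
  syn$pre <- suppressWarnings(as.integer(syn$pre))
  syn$active <- as.logical(syn$active)
  syn$plastic <- as.logical(syn$plastic)
  syn$drive[syn$drive == "NA"] <- NA_character_
  obj$synapses <- syn
  obj$seed <- as.integer(obj$seed)
  cfg <- structure(obj, class = "network_config")
  validate_network_config(cfg)
  cfg
}
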