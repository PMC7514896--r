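#' Canonical 16-compartment morphology
#'
#' All hippocampal cells in the model share a simplified morphology: a soma,
#' one axonal compartment, and a single apical cable of seven proximal and
#' seven distal dendritic compartments.  Perisomatic inhibition (basket
#' cells) targets the soma, feed-forward excitation the proximal cable, and
#' entorhinal / O-LM input the distal cable.
#'
#' @return A data frame with one row per compartment: `index`, `role`
#'   (`soma`, `axon`, `proximal_dendrite`, `distal_dendrite`) and `parent`
#'   (index of the parent compartment; `NA` for the soma, the tree root).
#' @export
#' @examples
#' compartment_tree()
compartment_tree <- function() {
  data.frame(
    index = 1:16,
    role = c("soma", "axon", rep("proximal_dendrite", 7),
             rep("distal_dendrite", 7)),
    parent = c(NA, 1L, 1L, 3:8, 9:15)
  )
}

# 0-based parent vector for the C++ integrator (-1 = root)
.parent_vec <- function() {
  p <- compartment_tree()$parent
  ifelse(is.na(p), -1L, as.integer(p - 1L))
}

#' Compartment parameter set for one cell class
#'
#' @param class One of `"granule"`, `"pyramidal"`, `"basket"`, `"olm"`,
#'   `"mossy"`.
#' @param defaults Parsed default parameter file (see
#'   [default_network_parameters()]).
#' @return A list with membrane capacitance `cm` (uF/cm^2), leak conductance
#'   `gl` (mS/cm^2), leak reversal `el` (mV), axial coupling `ga` (mS/cm^2),
#'   spike `threshold`, `reset` potential and `refractory` period (ms).
#' @export
cell_parameters <- function(class, defaults = default_network_parameters()) {
  class <- match.arg(class, .cell_classes)
  p <- defaults$cells[[class]]
  stopifnot(p$cm > 0, p$gl >= 0, p$threshold > p$el)
  p
}

#' Load the default quantitative network parameters
#'
#' All tunable numbers of the default microcircuit (membrane and receptor
#' constants, drive rates, pathway conductances, LTP rule constants) live in
#' a single versioned YAML file shipped with the package.
#'
#' @param file Path to a parameter file; defaults to the shipped one.
#' @return A named list mirroring the YAML structure.
#' @export
default_network_parameters <- function(file = NULL) {
  file <- file %||% system.file("extdata", "default-network.yaml",
                                package = "hippoflow")
  stopifnot(nzchar(file), file.exists(file))
  defs <- yaml::read_yaml(file)
  if (!identical(defs$schema_version, "1.0"))
    stopf("unsupported network parameter schema version: %s",
          defs$schema_version %||% "<missing>")
  defs
}
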