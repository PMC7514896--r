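test_that("default network has the study's cell inventory", {
  cfg <- build_default_network(seed = 0)
  expect_s3_class(cfg, "network_config")
  expect_equal(nrow(cfg$cells), 21)
  expect_equal(sum(cfg$cells$class == "basket"), 6)
  expect_equal(sum(cfg$cells$class == "olm"), 2)
  expect_equal(sum(cfg$cells$class == "mossy"), 1)
  # region composition: DG 4 granule + 2 basket + 1 mossy; CA3/CA1
  # 4 pyramidal + 2 basket + 1 O-LM each
  comp <- table(cfg$cells$region, cfg$cells$class)
  expect_equal(comp["DG", "granule"], 4)
  expect_equal(comp["DG", "mossy"], 1)
  expect_equal(comp["CA3", "pyramidal"], 4)
  expect_equal(comp["CA3", "olm"], 1)
  expect_equal(comp["CA1", "pyramidal"], 4)
  expect_equal(sum(cfg$cells$principal), 12)
})

test_that("EC2 pathway synapses are excitatory and target DG/CA3 only", {
  cfg <- build_default_network(seed = 0)
  sy <- cfg$synapses
  ec2 <- sy[grepl("^EC2_", sy$pathway), ]
  expect_gt(nrow(ec2), 0)
  expect_true(all(ec2$receptor %in% c("AMPA", "NMDA")))
  post_region <- cfg$cells$region[match(ec2$post, cfg$cells$id)]
  expect_true(all(post_region %in% c("DG", "CA3")))
})

test_that("wiring implements the trisynaptic topology", {
  cfg <- build_default_network(seed = 0)
  sy <- cfg$synapses
  cl <- cfg$cells
  reg <- function(ids) cl$region[match(ids, cl$id)]
  cls <- function(ids) cl$class[match(ids, cl$id)]
  mossy <- sy[sy$pathway == "mossy_fiber", ]
  expect_true(all(cls(mossy$pre) == "granule"))
  expect_true(all(reg(mossy$post) %in% c("CA3", "DG")))  # DG: mossy cell
  schaffer <- sy[sy$pathway == "schaffer", ]
  expect_true(all(cls(schaffer$pre) == "pyramidal" & reg(schaffer$pre) == "CA3"))
  expect_true(all(reg(schaffer$post) == "CA1"))
  ec3 <- sy[sy$pathway == "EC3_to_CA1", ]
  expect_true(all(reg(ec3$post) == "CA1" & cls(ec3$post) == "pyramidal"))
  expect_true(all(ec3$comp >= 10))  # distal dendrites
  septal <- sy[sy$pathway == "septal", ]
  expect_true(all(cls(septal$post) %in% c("basket", "olm")))
  expect_true(all(septal$receptor == "GABA_A"))
  # basket cells inhibit local principal somata
  inh <- sy[sy$pathway == "local_inhibition" & cls(sy$pre) == "basket", ]
  expect_true(all(inh$comp == 1))
  expect_true(all(reg(inh$pre) == reg(inh$post)))
  # O-LM cells inhibit distal dendrites and are excited by local pyramids
  olm_out <- sy[sy$pathway == "local_inhibition" & cls(sy$pre) == "olm", ]
  expect_true(all(olm_out$comp >= 10))
  olm_in <- sy[sy$pathway == "local_excitation", ]
  expect_true(all(cls(olm_in$post) == "olm"))
})

test_that("compartment morphology is a 16-compartment tree rooted at the soma", {
  tree <- compartment_tree()
  expect_equal(nrow(tree), 16)
  expect_equal(sum(tree$role == "soma"), 1)
  expect_true(is.na(tree$parent[tree$role == "soma"]))
  expect_true(all(tree$parent[-1] < tree$index[-1]))  # acyclic, parent first
  expect_setequal(unique(tree$role),
                  c("soma", "axon", "proximal_dendrite", "distal_dendrite"))
})

test_that("configuration validation catches broken invariants", {
  cfg <- build_default_network(seed = 0)
  bad <- cfg
  bad$synapses$post[1] <- 99L
  expect_error(validate_network_config(bad), "non-existent")
  bad <- cfg
  bad$synapses$tau_rise[1] <- bad$synapses$tau_decay[1] + 1
  expect_error(validate_network_config(bad))
  bad <- cfg
  bad$duration <- 10  # less than one theta period
  expect_error(validate_network_config(bad), "theta")
})

test_that("configurations round-trip through the YAML text format", {
  cfg <- build_default_network(seed = 7, duration = 1000)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_network_config(cfg, path)
  back <- read_network_config(path)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$synapses$weight, cfg$synapses$weight)
  expect_equal(back$synapses$pathway, cfg$synapses$pathway)
  expect_equal(back$cells$threshold, cfg$cells$threshold)
})
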