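test_that("deletion schedule validates its fractions and targets", {
  expect_error(deletion_schedule(fractions = c(0.2, 0.1)), "increasing")
  expect_error(deletion_schedule(fractions = c(-0.1, 0.5)), "increasing|\\[0, 1\\]")
  expect_error(deletion_schedule(target_pathways = "not_a_pathway"),
               "vocabulary")
  sch <- deletion_schedule()
  expect_equal(sch$fractions, c(0.09, 0.18, 0.26, 0.35))
  expect_true(all(grepl("^EC2_", sch$target_pathways)))
})

test_that("fraction 0 and 1 are exact boundary cases", {
  cfg <- build_default_network(seed = 1)
  same <- apply_deletion(cfg, 0)
  expect_identical(same$synapses, cfg$synapses)
  all_off <- apply_deletion(cfg, 1)
  ec2 <- grepl("^EC2_", all_off$synapses$pathway)
  expect_true(all(!all_off$synapses$active[ec2]))
  expect_true(all(all_off$synapses$active[!ec2]))
  expect_error(apply_deletion(cfg, 1.2), "fraction")
})

test_that("deletion counts follow round-half-up and nest across fractions", {
  cfg <- build_default_network(seed = 1)
  # inflate the EC2 population to exactly 100 target synapses
  ec2_rows <- cfg$synapses[grepl("^EC2_", cfg$synapses$pathway), ]
  n_extra <- 100 - nrow(ec2_rows)
  cfg$synapses <- rbind(cfg$synapses,
                        ec2_rows[rep(1, n_extra), ])
  rownames(cfg$synapses) <- NULL
  d09 <- apply_deletion(cfg, 0.09)
  d18 <- apply_deletion(cfg, 0.18)
  expect_equal(sum(!d09$synapses$active), 9)
  expect_equal(sum(!d18$synapses$active), 18)
  expect_true(all(which(!d09$synapses$active) %in%
                    which(!d18$synapses$active)))
})

test_that("the deletion series covers control plus each stage, nested", {
  cfg <- build_default_network(seed = 1)
  ser <- deletion_series(cfg)
  expect_length(ser, 5)
  expect_identical(ser[[1]]$synapses, cfg$synapses)
  deleted <- lapply(ser, function(s) which(!s$synapses$active))
  for (k in 2:5) expect_true(all(deleted[[k - 1]] %in% deleted[[k]]))
  only_ctrl <- deletion_series(cfg, deletion_schedule(fractions = numeric(0)))
  expect_length(only_ctrl, 1)
})

test_that("scheduled counts scale with the target population", {
  cfg <- build_default_network(seed = 1)
  ec2_rows <- cfg$synapses[grepl("^EC2_", cfg$synapses$pathway), ]
  cfg$synapses <- rbind(cfg$synapses, ec2_rows[rep(1, 200 - nrow(ec2_rows)), ])
  rownames(cfg$synapses) <- NULL
  ser <- deletion_series(cfg)
  counts <- vapply(ser, function(s) sum(!s$synapses$active), 0L)
  expect_equal(unname(counts), c(0L, 18L, 36L, 52L, 70L))
})

test_that("deletion never touches non-target synapses or synapse counts", {
  cfg <- build_default_network(seed = 1)
  for (f in c(0.09, 0.5, 1)) {
    del <- apply_deletion(cfg, f)
    expect_equal(nrow(del$synapses), nrow(cfg$synapses))
    non_target <- !grepl("^EC2_", cfg$synapses$pathway)
    expect_true(all(del$synapses$active[non_target]))
    changed <- which(del$synapses$active != cfg$synapses$active)
    expect_true(all(grepl("^EC2_", cfg$synapses$pathway[changed])))
  }
})

test_that("seeded random ordering is reproducible and still nested", {
  cfg <- build_default_network(seed = 1)
  sch <- deletion_schedule(order_policy = "seeded_random", seed = 42)
  a <- apply_deletion(cfg, 0.18, sch)
  b <- apply_deletion(cfg, 0.18, sch)
  expect_identical(a$synapses$active, b$synapses$active)
  small <- which(!apply_deletion(cfg, 0.09, sch)$synapses$active)
  big <- which(!a$synapses$active)
  expect_true(all(small %in% big))
})

test_that("the deletion manifest records stage of first removal", {
  cfg <- build_default_network(seed = 1)
  man <- deletion_manifest(cfg)
  n_target <- sum(grepl("^EC2_", cfg$synapses$pathway))
  expect_equal(nrow(man), round(0.35 * n_target))
  expect_true(all(man$fraction_at_which_deleted %in% c(0.09, 0.18, 0.26, 0.35)))
  expect_true(all(grepl("^EC2_", man$pathway)))
  # stages agree with apply_deletion
  d09 <- sum(man$fraction_at_which_deleted == 0.09)
  expect_equal(d09, sum(!apply_deletion(cfg, 0.09)$synapses$active))
})
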