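test_that("pool bookkeeping reproduces the planned sizes exactly", {
  solution <- remc_config(n_runs = 2, n_replicas = 16, n_sweeps = 5e6,
                          save_interval = 1000, save_policy = "all")
  expect_equal(plan_pool_size(solution), 160000)
  expect_equal(plan_n_trajectories(solution), 32)

  membrane <- remc_config(n_runs = 20, n_replicas = 8, n_sweeps = 2.5e6,
                          save_interval = 1000, save_policy = "lowest")
  expect_equal(plan_pool_size(membrane), 50000)
  expect_equal(plan_n_trajectories(membrane), 20)

  tiny <- remc_config(n_runs = 1, n_replicas = 1, t_min = 300, t_max = 301,
                      n_sweeps = 1000, save_interval = 1000)
  expect_equal(plan_pool_size(tiny), 1)

  expect_error(remc_config(t_min = 500, t_max = 300), "t_min")
  expect_error(remc_config(n_sweeps = 1500, save_interval = 1000),
               "multiple")
})

test_that("zero-amplitude moves leave the state unchanged with full acceptance", {
  tc <- make_toy_complex(seed = 2, beads_per_body = 8, linker_length = 4)
  set.seed(1)
  out <- mc_sweep(tc$conformation, tc$topology, energy_model(), 300,
                  n_sweeps = 5, amp_translation = 0, amp_rotation = 0,
                  amp_pivot = 0)
  expect_identical(out$coords, tc$conformation$coords)
  expect_equal(attr(out, "accepted"), attr(out, "attempted"))
})

test_that("acceptance approaches one in the infinite-temperature limit", {
  topo <- pair_topology()
  set.seed(2)
  out <- mc_sweep(pair_coords(10), topo, energy_model(), 1e12,
                  n_sweeps = 500, amp_translation = 0.5)
  expect_gt(attr(out, "accepted") / attr(out, "attempted"), 0.999)
})

test_that("MC sweeps preserve rigid-body internal geometry", {
  tc <- make_toy_complex(seed = 4, beads_per_body = 10, linker_length = 5)
  topo <- tc$topology
  d0 <- lapply(topo$bodies, function(ix) dist(tc$conformation$coords[ix, ]))
  set.seed(9)
  out <- mc_sweep(tc$conformation, topo, energy_model(), 400, n_sweeps = 50)
  for (b in seq_along(topo$bodies)) {
    expect_equal(as.vector(dist(out$coords[topo$bodies[[b]], ])),
                 as.vector(d0[[b]]), tolerance = 1e-6)
  }
})

test_that("a harmonic well is sampled at the Boltzmann variance", {
  k <- 1
  topo <- harmonic_bead_topology(k)
  cfg <- remc_config(n_runs = 1, n_replicas = 1, t_min = 300, t_max = 301,
                     n_sweeps = 1e5, save_interval = 10, seed = 101,
                     amp_translation = 1.5)
  pool <- run_remc(topo, harmonic_model(), cfg, membrane = TRUE,
                   temperatures = 300, init = matrix(0, 1, 3))
  z <- vapply(pool$conformations, function(x) x[1, 3], numeric(1))
  kBT <- 0.0019872041 * 300
  expect_equal(var(z), kBT / k, tolerance = 0.05)

  # enumerable 3-state partition of the same well: occupancies follow the
  # exact Boltzmann (Gaussian) bin probabilities
  sdev <- sqrt(kBT / k)
  zt <- z[seq(1, length(z), by = 5)]   # thin to reduce autocorrelation
  counts <- c(sum(zt <= -0.5), sum(zt > -0.5 & zt <= 0.5), sum(zt > 0.5))
  p <- c(pnorm(-0.5, 0, sdev), pnorm(0.5, 0, sdev) - pnorm(-0.5, 0, sdev),
         pnorm(0.5, 0, sdev, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(counts, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("replica swaps between equal temperatures are always accepted", {
  tc <- make_toy_complex(seed = 5, beads_per_body = 6, linker_length = 3)
  cfg <- remc_config(n_runs = 1, n_replicas = 2, t_min = 300, t_max = 400,
                     n_sweeps = 200, save_interval = 100, seed = 7)
  pool <- run_remc(tc$topology, energy_model(), cfg,
                   temperatures = c(350, 350))
  acc <- pool$acceptance
  expect_equal(sum(acc$swaps_accepted), sum(acc$swaps_attempted))
  expect_gt(sum(acc$swaps_attempted), 0)
})

test_that("swapping replicas preserves the target marginal distribution", {
  # single harmonic bead under 2-temperature replica exchange: the
  # lowest-temperature marginal must still have variance kBT/k
  topo <- harmonic_bead_topology(1)
  cfg <- remc_config(n_runs = 1, n_replicas = 2, t_min = 300, t_max = 600,
                     n_sweeps = 6e4, save_interval = 10, seed = 33,
                     save_policy = "lowest", amp_translation = 1.5)
  pool <- run_remc(topo, harmonic_model(), cfg, membrane = TRUE,
                   init = matrix(0, 1, 3))
  z <- vapply(pool$conformations, function(x) x[1, 3], numeric(1))
  expect_equal(var(z), 0.0019872041 * 300, tolerance = 0.05)
})

test_that("runs are bit-reproducible from the seed and sized as planned", {
  tc <- make_toy_complex(seed = 6, beads_per_body = 6, linker_length = 3)
  cfg <- remc_config(n_runs = 2, n_replicas = 3, t_min = 300, t_max = 500,
                     n_sweeps = 300, save_interval = 100, seed = 42)
  p1 <- run_remc(tc$topology, energy_model(), cfg)
  p2 <- run_remc(tc$topology, energy_model(), cfg)
  expect_identical(p1$conformations, p2$conformations)
  expect_identical(p1$info$energy, p2$info$energy)
  expect_equal(length(p1$conformations), plan_pool_size(cfg))

  cfg_low <- remc_config(n_runs = 1, n_replicas = 3, t_min = 300,
                         t_max = 500, n_sweeps = 300, save_interval = 100,
                         seed = 42, save_policy = "lowest")
  p3 <- run_remc(tc$topology, energy_model(), cfg_low)
  expect_equal(length(p3$conformations), plan_pool_size(cfg_low))
  expect_true(all(p3$info$replica == 1))
})
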