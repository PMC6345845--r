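# Metropolis Monte Carlo with rigid-body and linker moves, wrapped in
# temperature replica exchange. One sweep attempts one move per mobile
# degree of freedom: each rigid body gets a random translation or rotation
# about its centroid, each linker bead a local displacement or a pivot of
# the free tail of its chain. Swaps between adjacent temperatures are
# attempted every `swap_period` sweeps with the standard parallel-tempering
# acceptance min(1, exp((beta_i - beta_j)(E_i - E_j))).

#' Replica-exchange Monte Carlo configuration
#'
#' @param n_runs number of independent REMC runs, each started from a
#'   different randomized conformation and RNG stream.
#' @param n_replicas replicas per run.
#' @param t_min,t_max temperature ladder endpoints (K); the ladder is
#'   geometric between them.
#' @param n_sweeps MC sweeps per run (must be a multiple of
#'   `save_interval`).
#' @param save_interval record conformations every this many sweeps.
#' @param save_policy `"all"` records every replica at each save event;
#'   `"lowest"` records the lowest-temperature replica only (the membrane
#'   default).
#' @param seed master seed; spawns per-run streams.
#' @param amp_translation rigid-body translation / linker-bead displacement
#'   amplitude (A).
#' @param amp_rotation rigid-body rotation amplitude (rad).
#' @param amp_pivot linker pivot amplitude (rad).
#' @param swap_period sweeps between replica-swap attempts.
#' @return An object of class `remc_config`.
#' @export
remc_config <- function(n_runs = 2, n_replicas = 16, t_min = 300, t_max = 500,
                        n_sweeps = 5e6, save_interval = 1000,
                        save_policy = c("all", "lowest"), seed = 1,
                        amp_translation = 1, amp_rotation = 0.15,
                        amp_pivot = 0.3, swap_period = 10) {
  save_policy <- match.arg(save_policy)
  if (t_min >= t_max) abort("t_min must be < t_max")
  if (n_sweeps %% save_interval != 0) {
    abort("n_sweeps must be a multiple of save_interval")
  }
  structure(list(n_runs = n_runs, n_replicas = n_replicas,
                 t_min = t_min, t_max = t_max, n_sweeps = n_sweeps,
                 save_interval = save_interval, save_policy = save_policy,
                 seed = seed, amp_translation = amp_translation,
                 amp_rotation = amp_rotation, amp_pivot = amp_pivot,
                 swap_period = swap_period),
            class = "remc_config")
}

#' Geometric temperature ladder of a configuration
#'
#' @param config an [remc_config].
#' @return Temperatures in K, length `n_replicas`, geometric from `t_min`
#'   to `t_max`.
#' @export
temperature_ladder <- function(config) {
  if (config$n_replicas == 1) return(config$t_min)
  exp(seq(log(config$t_min), log(config$t_max),
          length.out = config$n_replicas))
}

#' Planned pool size of a configuration
#'
#' Exact number of conformations a run of this configuration records:
#' `n_runs * replicas_saved * n_sweeps / save_interval`.
#'
#' @param config an [remc_config].
#' @return Integer count.
#' @export
plan_pool_size <- function(config) {
  saved <- if (config$save_policy == "all") config$n_replicas else 1
  config$n_runs * saved * config$n_sweeps / config$save_interval
}

#' Number of trajectories a configuration produces
#'
#' @param config an [remc_config].
#' @return `n_runs * replicas_saved`.
#' @export
plan_n_trajectories <- function(config) {
  saved <- if (config$save_policy == "all") config$n_replicas else 1
  config$n_runs * saved
}

#' One (or a few) Metropolis sweeps at a fixed temperature
#'
#' @param x starting conformation (or coordinate matrix).
#' @param topology,model topology and energy model.
#' @param temperature K.
#' @param n_sweeps number of sweeps to run.
#' @param membrane include membrane terms?
#' @param amp_translation,amp_rotation,amp_pivot move amplitudes.
#' @return The updated `cg_conformation` with its energy, and attributes
#'   `attempted` / `accepted` move counts.
#' @export
mc_sweep <- function(x, topology, model = energy_model(), temperature = 300,
                     n_sweeps = 1, membrane = FALSE,
                     amp_translation = 1, amp_rotation = 0.15,
                     amp_pivot = 0.3) {
  res <- cpp_run_mc(as_coords(x), topo_cpp(topology), unclass(model),
                    membrane, temperature, as.integer(n_sweeps), 0L,
                    amp_translation, amp_rotation, amp_pivot)
  out <- conformation(res$final, topology, energy = res$final_energy,
                      temperature = temperature)
  attr(out, "attempted") <- res$attempted
  attr(out, "accepted") <- res$accepted
  out
}

# randomized starting conformation: new random pose for every rigid body
# (rotation about its centroid plus a bounded translation), linkers rebuilt
# near their anchors
randomize_conformation <- function(topology, translation_sd = 8) {
  x <- topology$init_coords
  for (b in seq_along(topology$bodies)) {
    ctr <- colMeans(x[topology$bodies[[b]], , drop = FALSE])
    shift <- ctr + rnorm(3, 0, translation_sd)
    x <- set_body_pose(x, topology, b, random_unit_quaternion(), shift)
  }
  # re-seat each linker between its (possibly moved) anchors
  for (l in seq_along(topology$linkers)) {
    idx <- topology$linkers[[l]]
    x[idx, ] <- extend_linker(x, topology$bodies, topology$body_id,
                              topology$anchor_start[l],
                              topology$anchor_end[l],
                              length(idx), topology$bond_length, l)
    x[idx, ] <- x[idx, ] + matrix(rnorm(3 * length(idx), 0, 0.3),
                                  length(idx), 3)
  }
  x
}

#' Run replica-exchange Monte Carlo
#'
#' Performs `n_runs` independent REMC simulations of the topology under the
#' energy model. Each run starts from a different randomized conformation
#' (all rigid-body poses re-drawn from the run's RNG stream) and uses its
#' own RNG stream spawned from the master seed, so the full pool is
#' reproducible bit-for-bit from `config$seed`.
#'
#' @param topology a [cg_topology].
#' @param model a [cg_energy_model][energy_model].
#' @param config an [remc_config].
#' @param membrane run with the implicit-membrane terms?
#' @param temperatures optional explicit temperature ladder overriding the
#'   geometric one (useful for calibration runs).
#' @param init optional starting coordinate matrix used (after
#'   randomization is skipped) for every replica of every run.
#' @return A `cg_pool`: list with `conformations` (coordinate matrices),
#'   `info` (tibble: id, run, replica slot, temperature, sweep, energy,
#'   rg, dmax), `acceptance` (per run/replica move and swap statistics),
#'   the `topology` and the echoed `config`.
#' @export
run_remc <- function(topology, model = energy_model(), config = remc_config(),
                     membrane = FALSE, temperatures = NULL, init = NULL) {
  temps <- if (is.null(temperatures)) temperature_ladder(config)
           else as.numeric(temperatures)
  if (length(temps) != config$n_replicas) {
    abort("temperature ladder length must equal n_replicas")
  }
  tc <- topo_cpp(topology)
  mc <- unclass(model)
  set.seed(config$seed)
  run_seeds <- sample.int(2147483646L, config$n_runs)

  conformations <- list()
  info <- list()
  acc <- list()
  for (r in seq_len(config$n_runs)) {
    set.seed(run_seeds[r])
    inits <- lapply(seq_len(config$n_replicas), function(i) {
      if (is.null(init)) randomize_conformation(topology) else as_coords(init)
    })
    res <- cpp_run_remc(inits, tc, mc, membrane, temps,
                        as.integer(config$n_sweeps),
                        as.integer(config$save_interval),
                        as.integer(config$swap_period),
                        config$amp_translation, config$amp_rotation,
                        config$amp_pivot,
                        config$save_policy == "all")
    conformations <- c(conformations, res$frames)
    info[[r]] <- tibble(
      run = r, replica = res$slot, temperature = temps[res$slot],
      sweep = res$sweep, energy = res$energy,
      rg = vapply(res$frames, radius_of_gyration, numeric(1)),
      dmax = vapply(res$frames, dmax_quiet, numeric(1))
    )
    acc[[r]] <- tibble(
      run = r, replica = seq_len(config$n_replicas), temperature = temps,
      moves_attempted = res$move_attempted, moves_accepted = res$move_accepted,
      swaps_attempted = res$swap_attempted / max(1, config$n_replicas - 1),
      swaps_accepted = res$swap_accepted / max(1, config$n_replicas - 1)
    )
  }
  info <- bind_rows(info)
  info$id <- seq_len(nrow(info))
  info <- info[, c("id", "run", "replica", "temperature", "sweep",
                   "energy", "rg", "dmax")]
  structure(list(conformations = conformations, info = info,
                 acceptance = bind_rows(acc), topology = topology,
                 config = config, membrane = membrane,
                 run_seeds = run_seeds),
            class = "cg_pool")
}

#' Construct a pool from a list of conformations
#'
#' @param conformations list of coordinate matrices (or `cg_conformation`s).
#' @param topology the common topology.
#' @param info optional metadata tibble (one row per conformation).
#' @return A `cg_pool`.
#' @export
cg_pool <- function(conformations, topology, info = NULL) {
  conformations <- lapply(conformations, as_coords)
  if (is.null(info)) {
    info <- tibble(
      id = seq_along(conformations),
      rg = vapply(conformations, radius_of_gyration, numeric(1)),
      dmax = vapply(conformations, dmax_quiet, numeric(1))
    )
  }
  structure(list(conformations = conformations, info = info,
                 topology = topology),
            class = "cg_pool")
}

#' @export
print.cg_pool <- function(x, ...) {
  cat("Conformation pool:", length(x$conformations), "structures,",
      x$topology$n, "beads each\n")
  if (!is.null(x$info$rg)) {
    cat(sprintf("  Rg %.1f-%.1f A, Dmax %.1f-%.1f A\n",
                min(x$info$rg), max(x$info$rg),
                min(x$info$dmax), max(x$info$dmax)))
  }
  invisible(x)
}

#' @export
tidy.cg_pool <- function(x, ...) x$info

# Dmax without the single-bead warning (used for pool bookkeeping)
dmax_quiet <- function(x) if (nrow(x) < 2) 0 else max(dist(x))
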