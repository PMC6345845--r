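# Pipeline orchestration: simulate -> profiles -> rank/select -> cluster
# (solution mode), or simulate -> membrane-analyze (membrane mode), with a
# JSON run manifest recording configuration, seed, versions, stage timings
# and output digests.

#' Run the full analysis pipeline
#'
#' Solution mode executes: REMC sampling, per-structure Debye profiles,
#' chi-square ranking against the target profile, top-N selection, optional
#' minimum-ensemble search, QT/DRMS clustering of the selected structures,
#' and writes ranked TSVs, Kratky-plot data, selected structures as a
#' multi-MODEL PDB, and a manifest. Membrane mode executes: restrained REMC
#' sampling, per-residue contact probabilities at the requested thresholds,
#' and Dmax/Rg statistics.
#'
#' @param config list (or YAML path) with elements:
#'   `mode` ("solution"/"membrane"), `topology` (spec for
#'   [build_topology()], or a ready `cg_topology`), `energy`
#'   ([build_energy_model()] spec, optional), `remc` ([remc_config()]
#'   arguments), `target` (SAXS .dat path or a [saxs_profile]; solution
#'   mode), `q` (profile grid when target has none), `top_n` (default
#'   100), `min_ensemble` (max size, 0 to skip), `chi2_accept`,
#'   `cluster_cutoff` (A, default 5), `z0` (membrane thresholds, A),
#'   `pool` (a ready `cg_pool`; skips the sampling stage), `init`
#'   (starting coordinates for every replica instead of randomized poses).
#' @param out_dir output directory (created).
#' @param seed overrides `config$remc$seed` when given.
#' @return List with the pool, ranking, selection, ensemble, clusters or
#'   membrane summaries, and the manifest (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- match.arg(config$mode, c("solution", "membrane"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()
  timings <- list()
  step <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(force(expr), error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  topology <- step("topology", {
    if (inherits(config$topology, "cg_topology")) config$topology
    else build_topology(config$topology)
  })
  model <- step("energy", {
    if (inherits(config$energy, "cg_energy_model")) config$energy
    else build_energy_model(if (is.null(config$energy)) list() else config$energy)
  })
  remc_args <- if (is.null(config$remc)) list() else config$remc
  if (!is.null(seed)) remc_args$seed <- seed
  rc <- do.call(remc_config, remc_args)

  pool <- step("simulate", {
    if (inherits(config$pool, "cg_pool")) config$pool  # pre-computed pool
    else run_remc(topology, model, rc, membrane = (mode == "membrane"),
                  init = config$init)
  })
  write_tsv(pool$info, file.path(out_dir, "pool.tsv"))
  write_tsv(pool$acceptance, file.path(out_dir, "acceptance.tsv"))

  result <- list(pool = pool, topology = topology, model = model, config = rc)

  if (mode == "solution") {
    target <- step("target", {
      if (inherits(config$target, "saxs_profile")) config$target
      else read_saxs(config$target)
    })
    profiles <- step("profile", pool_intensities(pool, target$q))
    ranked <- step("rank", rank_structures(profiles, target))
    write_tsv(ranked, file.path(out_dir, "ranked_chi2.tsv"))
    top_n <- min(if (is.null(config$top_n)) 100 else config$top_n,
                 nrow(ranked))
    top_ids <- select_top_n(ranked, top_n)
    write_pdb(pool$conformations[top_ids],
              file.path(out_dir, "top_structures.pdb"), topology)
    best <- top_ids[1]
    kr <- kratky(saxs_profile(target$q, profiles[best, ]))
    write_tsv(kr, file.path(out_dir, "kratky_best.tsv"))

    ensemble <- NULL
    if (!is.null(config$min_ensemble) && config$min_ensemble > 0) {
      ensemble <- step("min_ensemble", {
        minimum_ensemble(profiles, target,
                         max_size = config$min_ensemble,
                         chi2_accept = if (is.null(config$chi2_accept)) 1.5
                                       else config$chi2_accept)
      })
      write_tsv(cbind(tidy(ensemble), glance(ensemble)),
                file.path(out_dir, "ensemble.tsv"))
    }

    cutoff <- if (is.null(config$cluster_cutoff)) 5 else config$cluster_cutoff
    clusters <- step("cluster", {
      dm <- drms_matrix(pool$conformations[top_ids],
                        inter_body_pairs(topology))
      qt_cluster(dm, cutoff, ids = top_ids)
    })
    write_tsv(tidy(clusters), file.path(out_dir, "clusters.tsv"))
    result <- c(result, list(target = target, ranked = ranked,
                             top_ids = top_ids, ensemble = ensemble,
                             clusters = clusters))
  } else {
    z0 <- if (is.null(config$z0)) c(20, 22.5, 25) else config$z0
    contacts <- step("membrane_analyze", contact_probability(pool, z0))
    ext <- extension_stats(pool)
    write_tsv(contacts, file.path(out_dir, "contacts.tsv"))
    write_tsv(ext$summary, file.path(out_dir, "extension_summary.tsv"))
    write_tsv(ext$histogram, file.path(out_dir, "extension_hist.tsv"))
    result <- c(result, list(contacts = contacts, extension = ext))
  }

  manifest <- list(
    mode = mode,
    seed = rc$seed,
    version = as.character(packageVersion("flexsaxs")),
    created = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    remc = unclass(rc),
    pool_size = length(pool$conformations),
    planned_pool_size = plan_pool_size(rc),
    stage_timings_s = timings,
    outputs = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}
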