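# Analysis of membrane-mode pools: per-residue membrane contact
# probabilities at a z threshold, and extension (Dmax, Rg) statistics.
# Thresholds are in Angstrom internally (the membrane surface sits at
# z = 20 A, i.e. 2 nm); outputs annotate both units.

#' Per-bead membrane contact probabilities
#'
#' For each bead, the fraction of pool conformations whose bead
#' z-coordinate lies below the threshold `z0`. Contacts are counted over
#' the saved (room-temperature) structures of a membrane run.
#'
#' @param pool a `cg_pool` (or list of coordinate matrices).
#' @param z0 contact threshold(s) in Angstrom; the conventional window is
#'   20-25 A (2-2.5 nm) and values outside it trigger a warning.
#' @return A tibble of class `contact_profile`: `bead`, `residue` (when the
#'   pool carries a topology), `z0`, `z0_nm`, `probability`.
#' @export
contact_probability <- function(pool, z0 = 25) {
  confs <- if (inherits(pool, "cg_pool")) pool$conformations else pool
  if (length(confs) == 0) abort("empty pool")
  if (any(z0 < 20 | z0 > 25)) {
    warn("z0 outside the conventional 20-25 A (2-2.5 nm) window")
  }
  zmat <- vapply(confs, function(xx) xx[, 3], numeric(nrow(confs[[1]])))
  # zmat: beads x conformations
  res <- bind_rows(lapply(z0, function(th) {
    tibble(bead = seq_len(nrow(zmat)),
           z0 = th, z0_nm = th / 10,
           probability = rowMeans(zmat < th))
  }))
  if (inherits(pool, "cg_pool") && !is.null(pool$topology)) {
    res$residue <- pool$topology$beads$residue[res$bead]
    res$unit <- pool$topology$beads$unit[res$bead]
    res <- res[, c("bead", "residue", "unit", "z0", "z0_nm", "probability")]
  }
  class(res) <- c("contact_profile", class(res))
  res
}

#' Extension statistics of a pool
#'
#' Exact order statistics, mean and histogram of the per-conformation
#' maximum extension (Dmax) and radius of gyration (Rg).
#'
#' @param pool a `cg_pool` or list of coordinate matrices.
#' @param bins histogram bin count (default 30).
#' @return List of class `extension_stats` with `summary` (tibble: metric,
#'   n, min, max, mean, sd) and `histogram` (tibble: metric, mid, count).
#' @export
extension_stats <- function(pool, bins = 30) {
  confs <- if (inherits(pool, "cg_pool")) pool$conformations else pool
  if (length(confs) == 0) abort("empty pool")
  dmax <- vapply(confs, function(xx) {
    if (nrow(xx) < 2) 0 else max(dist(xx))
  }, numeric(1))
  rg <- vapply(confs, radius_of_gyration, numeric(1))
  summ <- bind_rows(
    tibble(metric = "dmax", n = length(dmax), min = min(dmax),
           max = max(dmax), mean = mean(dmax), sd = sd(dmax)),
    tibble(metric = "rg", n = length(rg), min = min(rg),
           max = max(rg), mean = mean(rg), sd = sd(rg))
  )
  histo <- bind_rows(lapply(list(dmax = dmax, rg = rg), function(v) {
    h <- graphics::hist(v, breaks = bins, plot = FALSE)
    tibble(mid = h$mids, count = h$counts)
  }), .id = "metric")
  structure(list(summary = summ, histogram = histo, dmax = dmax, rg = rg),
            class = "extension_stats")
}

#' @export
print.extension_stats <- function(x, ...) {
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("%4s: min %.1f  mean %.1f  max %.1f  sd %.1f A  (n = %d)\n",
                toupper(s$metric[k]), s$min[k], s$mean[k], s$max[k],
                s$sd[k], s$n[k]))
  }
  invisible(x)
}

#' @export
glance.extension_stats <- function(x, ...) x$summary
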