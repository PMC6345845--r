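# Quality-threshold clustering of accepted structures under a DRMS
# (distance root-mean-square) metric computed over inter-body bead pairs.
# DRMS depends only on internal distances, so it is invariant to global
# rotation and translation and measures similarity of the relative
# placement of the rigid bodies.

#' DRMS between two conformations
#'
#' `sqrt(mean over the pair set of (d_ij^a - d_ij^b)^2)`, where `d_ij` is
#' the distance between beads i and j within each conformation.
#'
#' @param a,b conformations or coordinate matrices from the same topology.
#' @param pairs two-column matrix of bead index pairs (see
#'   [inter_body_pairs()]).
#' @return DRMS in Angstrom.
#' @export
drms <- function(a, b, pairs) {
  xa <- as_coords(a); xb <- as_coords(b)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) abort("empty pair set")
  da <- sqrt(rowSums((xa[pairs[, 1], , drop = FALSE] -
                        xa[pairs[, 2], , drop = FALSE])^2))
  db <- sqrt(rowSums((xb[pairs[, 1], , drop = FALSE] -
                        xb[pairs[, 2], , drop = FALSE])^2))
  sqrt(mean((da - db)^2))
}

#' Inter-body bead pairs of a topology
#'
#' All bead pairs whose two members belong to different rigid bodies (the
#' default DRMS pair set: it captures the relative placement of the bodies
#' and ignores linker motion). When the full set exceeds `max_pairs` it is
#' subsampled with the given seed for tractable distance matrices.
#'
#' @param topology a [cg_topology].
#' @param max_pairs subsampling ceiling (default 5000); `Inf` for the full
#'   set.
#' @param seed subsampling seed.
#' @return Two-column integer matrix of bead indices.
#' @export
inter_body_pairs <- function(topology, max_pairs = 5000, seed = 1) {
  bid <- topology$body_id
  in_body <- which(bid > 0)
  pr <- t(combn(in_body, 2))
  pr <- pr[bid[pr[, 1]] != bid[pr[, 2]], , drop = FALSE]
  if (nrow(pr) > max_pairs) {
    pr <- pr[sort(sample_with_seed(nrow(pr), max_pairs, seed)), ,
             drop = FALSE]
  }
  pr
}

# seeded sample.int that leaves the caller's RNG state untouched
sample_with_seed <- function(n, k, seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  sample.int(n, k)
}

#' Pairwise DRMS matrix of a pool
#'
#' @param pool a `cg_pool` or list of coordinate matrices.
#' @param pairs pair set (default: [inter_body_pairs()] of the pool
#'   topology).
#' @return Symmetric matrix of DRMS values (Angstrom), zero diagonal.
#' @export
drms_matrix <- function(pool, pairs = NULL) {
  confs <- if (inherits(pool, "cg_pool")) pool$conformations else pool
  if (is.null(pairs)) {
    if (!inherits(pool, "cg_pool")) abort("pairs required for a bare list")
    pairs <- inter_body_pairs(pool$topology)
  }
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) abort("empty pair set")
  dvec <- t(vapply(confs, function(xx) {
    sqrt(rowSums((xx[pairs[, 1], , drop = FALSE] -
                    xx[pairs[, 2], , drop = FALSE])^2))
  }, numeric(nrow(pairs))))
  as.matrix(dist(dvec)) / sqrt(nrow(pairs))
}

#' Quality-threshold clustering of a DRMS matrix
#'
#' Classic QT procedure with cluster diameter (maximum intra-cluster DRMS)
#' as the quality measure: from every remaining point a candidate cluster
#' is grown greedily, always adding the point that increases the diameter
#' least while keeping it within the cutoff; the largest candidate is
#' committed, its members removed, and the procedure repeats. Singleton
#' clusters are allowed. Ties in diameter growth are broken by lowest id,
#' ties in candidate size by lowest seed id, so the output is
#' deterministic.
#'
#' @param dmat symmetric distance matrix with zero diagonal (e.g. from
#'   [drms_matrix()]).
#' @param cutoff diameter cutoff in the metric's units (Angstrom for DRMS).
#' @param ids optional point identifiers (default 1..n).
#' @return An object of class `cluster_set`: `clusters` (list of member id
#'   vectors, descending size), `cutoff`, `metric`.
#' @export
qt_cluster <- function(dmat, cutoff, ids = NULL) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  if (n == 0) abort("empty distance matrix")
  if (max(abs(dmat - t(dmat))) > 1e-9 || any(diag(dmat) != 0)) {
    abort("distance matrix must be symmetric with a zero diagonal")
  }
  if (is.null(ids)) ids <- seq_len(n)
  remaining <- seq_len(n)
  clusters <- list()
  while (length(remaining) > 0) {
    best <- NULL
    for (seed_pt in remaining) {
      members <- seed_pt
      avail <- setdiff(remaining, seed_pt)
      maxd <- rep(0, n)                  # max distance to current members
      maxd[avail] <- dmat[avail, seed_pt]
      repeat {
        ok <- avail[maxd[avail] <= cutoff]
        if (length(ok) == 0) break
        add <- ok[which.min(maxd[ok])]   # ties: lowest index (= lowest id)
        members <- c(members, add)
        avail <- setdiff(avail, add)
        if (length(avail) == 0) break
        maxd[avail] <- pmax(maxd[avail], dmat[avail, add])
      }
      if (is.null(best) || length(members) > length(best)) best <- members
      # ties in size: first seed (lowest) wins, so strict > above
    }
    clusters[[length(clusters) + 1]] <- sort(best)
    remaining <- setdiff(remaining, best)
  }
  ord <- order(-lengths(clusters), vapply(clusters, min, numeric(1)))
  structure(list(clusters = lapply(clusters[ord], function(ix) ids[ix]),
                 cutoff = cutoff, metric = "DRMS",
                 diameters = vapply(clusters[ord], function(ix) {
                   if (length(ix) == 1) 0
                   else max(dmat[ix, ix])
                 }, numeric(1))),
            class = "cluster_set")
}

#' Medoid of each cluster
#'
#' The member minimizing the sum of distances to the other members (ties:
#' lowest id).
#'
#' @param cs a `cluster_set` from [qt_cluster()].
#' @param dmat the distance matrix the clustering was computed from, with
#'   rows/columns in id order.
#' @param ids ids labelling `dmat` rows (default 1..n).
#' @return Integer vector, one medoid id per cluster.
#' @export
cluster_medoids <- function(cs, dmat, ids = NULL) {
  dmat <- as.matrix(dmat)
  if (is.null(ids)) ids <- seq_len(nrow(dmat))
  vapply(cs$clusters, function(mem) {
    ix <- match(mem, ids)
    mem[which.min(rowSums(dmat[ix, ix, drop = FALSE]))]
  }, numeric(1))
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("QT clustering (%s, cutoff %.3g A): %d clusters; sizes %s\n",
              x$metric, x$cutoff, length(x$clusters),
              paste(lengths(x$clusters), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.cluster_set <- function(x, ...) {
  bind_rows(lapply(seq_along(x$clusters), function(k) {
    tibble(id = x$clusters[[k]], cluster = k)
  }))
}

#' @export
glance.cluster_set <- function(x, ...) {
  tibble(n_clusters = length(x$clusters),
         largest = max(lengths(x$clusters)),
         n_singletons = sum(lengths(x$clusters) == 1),
         cutoff = x$cutoff)
}
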