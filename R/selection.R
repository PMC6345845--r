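# Selection against a target SAXS curve: chi-square ranking, top-N
# selection, and the minimum-ensemble search (smallest equal-weight set of
# structures whose mixed profile fits the target).

#' Compute profiles for every structure in a pool
#'
#' @param pool a `cg_pool` (or list of coordinate matrices).
#' @param q momentum-transfer grid.
#' @param form_factors per-bead form factors (see [debye_intensity()]).
#' @return Matrix, one row per structure, one column per q point, with the
#'   grid in `attr(, "q")`.
#' @export
pool_intensities <- function(pool, q, form_factors = 1) {
  confs <- if (inherits(pool, "cg_pool")) pool$conformations else pool
  m <- t(vapply(confs,
                function(xx) debye_intensity(xx, q, form_factors)$intensity,
                numeric(length(q))))
  attr(m, "q") <- q
  m
}

pool_matrix <- function(profiles, target) {
  if (is.matrix(profiles)) {
    qm <- attr(profiles, "q")
    if (!is.null(qm) && !isTRUE(all.equal(qm, target$q))) {
      abort("profile matrix q grid must equal the target grid")
    }
    return(profiles)
  }
  t(vapply(profiles, function(p) {
    if (isTRUE(all.equal(p$q, target$q))) p$intensity
    else interpolate_intensity(p, target$q)
  }, numeric(length(target$q))))
}

#' Rank pool structures by chi-square against a target profile
#'
#' Each structure is fitted individually with its own analytic intensity
#' scale; the result is sorted by ascending reduced chi-square, ties broken
#' by pool id.
#'
#' @param profiles matrix from [pool_intensities()] (rows on the target
#'   grid), or a list of [saxs_profile]s.
#' @param target a [saxs_profile] with `sigma`.
#' @return Tibble `(id, chi2, a)` in rank order.
#' @export
rank_structures <- function(profiles, target) {
  im <- pool_matrix(profiles, target)
  if (nrow(im) == 0) abort("empty pool")
  if (all(is.na(target$sigma))) abort("target profile must carry sigma")
  w <- 1 / target$sigma^2
  ie <- target$intensity
  t0 <- sum(w * ie^2)
  u <- as.vector(im %*% (w * ie))
  v <- as.vector((im^2) %*% w)
  a <- u / v
  chi2 <- (t0 - u^2 / v) / length(ie)
  out <- tibble(id = seq_len(nrow(im)), chi2 = chi2, a = a)
  out[order(out$chi2, out$id), ]
}

#' Select the top-N structures from a ranking
#'
#' @param ranked tibble from [rank_structures()].
#' @param n how many to keep (must be in 1..pool size).
#' @return Integer vector of the first `n` pool ids.
#' @export
select_top_n <- function(ranked, n) {
  if (n <= 0) abort("n must be positive")
  if (n > nrow(ranked)) abort("n exceeds pool size")
  ranked$id[seq_len(n)]
}

#' Minimum-ensemble search against a target profile
#'
#' Finds the smallest set of pool structures whose equal-weight mixed
#' profile, jointly rescaled by the closed-form scale factor, fits the
#' target within `chi2_accept` (reduced). Sizes s = 1, 2, ..., `max_size`
#' are searched in order by exhaustive enumeration over a candidate pool
#' pruned to the `prune` best single structures; the first size whose best
#' chi-square reaches the threshold wins. If no size reaches it, the
#' overall best combination is returned with `reached = FALSE`.
#'
#' With `mode = "nnls"` the weights of each candidate subset are instead
#' fitted by non-negative least squares (the scale is absorbed into the
#' weights); this is an extension beyond the default equal-weight search.
#'
#' @param profiles matrix from [pool_intensities()] or list of profiles.
#' @param target a [saxs_profile] with `sigma`.
#' @param max_size largest ensemble size to try (default 2, at most 4).
#' @param chi2_accept acceptance threshold on the reduced chi-square
#'   (default 1.5).
#' @param prune candidate-pool size: the best `prune` single structures
#'   enter the exhaustive search (default 200). For sizes whose
#'   combination count would exceed ~5e6 the candidate pool is narrowed
#'   further.
#' @param mode `"equal"` (equal statistical weights, the default) or
#'   `"nnls"`.
#' @return An object of class `cg_ensemble`: `members` (pool ids),
#'   `weights`, `a`, `chi2` (reduced), `chi2_raw`, `size`, `reached`.
#' @export
minimum_ensemble <- function(profiles, target, max_size = 2,
                             chi2_accept = 1.5, prune = 200,
                             mode = c("equal", "nnls")) {
  mode <- match.arg(mode)
  if (max_size < 1) abort("max_size must be >= 1")
  im <- pool_matrix(profiles, target)
  if (nrow(im) == 0) abort("empty pool")
  w <- 1 / target$sigma^2
  ie <- target$intensity
  nq <- length(ie)
  t0 <- sum(w * ie^2)
  u_all <- as.vector(im %*% (w * ie))
  v_all <- as.vector((im^2) %*% w)
  singles <- order(t0 - u_all^2 / v_all, seq_len(nrow(im)))
  cand <- singles[seq_len(min(prune, length(singles)))]

  best <- NULL
  for (s in seq_len(max_size)) {
    m_s <- length(cand)
    while (m_s > s && choose(m_s, s) > 5e6) m_s <- m_s - 1
    cc <- sort(cand[seq_len(m_s)])   # ascending id => deterministic tie-break
    if (length(cc) < s) break
    res <- if (mode == "equal") {
      best_equal_subset(im, cc, s, ie, w, t0, u_all)
    } else {
      best_nnls_subset(im, cc, s, ie, w)
    }
    res$size <- s
    if (is.null(best) || res$chi2_raw < best$chi2_raw) best <- res
    if (res$chi2_raw / nq <= chi2_accept) {
      best <- res
      best$reached <- TRUE
      break
    }
  }
  if (is.null(best$reached)) best$reached <- FALSE
  structure(list(members = best$members, weights = best$weights,
                 a = best$a, chi2 = best$chi2_raw / nq,
                 chi2_raw = best$chi2_raw, size = best$size,
                 reached = best$reached),
            class = "cg_ensemble")
}

# exhaustive equal-weight search at size s over candidate ids via the
# weighted Gram matrix: chi2_raw(S) = t0 - U^2 / V with U = sum_k u_k,
# V = sum_kl v_kl over the subset
best_equal_subset <- function(im, cand, s, ie, w, t0, u_all) {
  iw <- im[cand, , drop = FALSE] * matrix(sqrt(w), length(cand), ncol(im),
                                          byrow = TRUE)
  v <- tcrossprod(iw)                    # v_kl = sum w I_k I_l
  u <- u_all[cand]
  if (s == 1) {
    chi2 <- t0 - u^2 / diag(v)
    k <- which.min(chi2)                 # ties: first index = lowest id order
    U <- u[k]; V <- diag(v)[k]
    members <- cand[k]
  } else {
    combos <- combn(length(cand), s)
    U <- colSums(matrix(u[combos], nrow = s))
    V <- numeric(ncol(combos))
    for (a_ in seq_len(s)) {
      for (b_ in seq_len(s)) {
        V <- V + v[cbind(combos[a_, ], combos[b_, ])]
      }
    }
    chi2 <- t0 - U^2 / V
    k <- which.min(chi2)
    U <- U[k]; V <- V[k]
    members <- cand[combos[, k]]
  }
  a <- s * U / V                         # scale for the mean profile
  list(members = sort(members), weights = rep(1 / s, s), a = a,
       chi2_raw = t0 - U^2 / V)
}

# per-subset non-negative least squares on c_k >= 0 with I_exp ~ sum c_k I_k;
# weights = c / sum(c), a = sum(c). Tiny active-set (Lawson-Hanson) solver.
best_nnls_subset <- function(im, cand, s, ie, w) {
  combos <- if (s == 1) matrix(seq_along(cand), 1) else combn(length(cand), s)
  sw <- sqrt(w)
  y <- ie * sw
  best <- NULL
  for (k in seq_len(ncol(combos))) {
    ids <- cand[combos[, k]]
    A <- t(im[ids, , drop = FALSE] * matrix(sw, length(ids), ncol(im),
                                            byrow = TRUE))
    cfit <- nnls_small(A, y)
    r <- y - A %*% cfit
    raw <- sum(r^2)
    if (is.null(best) || raw < best$chi2_raw) {
      tot <- sum(cfit)
      best <- list(members = ids,
                   weights = if (tot > 0) cfit / tot else rep(1 / length(ids),
                                                              length(ids)),
                   a = tot, chi2_raw = raw)
    }
  }
  best
}

nnls_small <- function(A, y, tol = 1e-10) {
  p <- ncol(A)
  passive <- rep(FALSE, p)
  x <- rep(0, p)
  for (iter in 1:(10 * p + 10)) {
    grad <- crossprod(A, y - A %*% x)
    cand <- which(!passive & grad > tol)
    if (length(cand) == 0) break
    passive[cand[which.max(grad[cand])]] <- TRUE
    repeat {
      xs <- rep(0, p)
      xs[passive] <- qr.solve(A[, passive, drop = FALSE], y)
      if (all(xs[passive] > tol)) {
        x <- xs
        break
      }
      neg <- passive & xs <= tol
      ratio <- x[neg] / (x[neg] - xs[neg])
      alpha <- min(ratio[is.finite(ratio)], 1)
      x <- x + alpha * (xs - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
    }
  }
  pmax(x, 0)
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat(sprintf("Minimum ensemble: size %d, reduced chi2 = %.4g%s\n",
              x$size, x$chi2,
              if (x$reached) "" else " (acceptance threshold not reached)"))
  cat("  members:", paste(x$members, collapse = ", "),
      " weights:", paste(signif(x$weights, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.cg_ensemble <- function(x, ...) {
  tibble(id = x$members, weight = x$weights)
}

#' @export
glance.cg_ensemble <- function(x, ...) {
  tibble(size = x$size, chi2 = x$chi2, chi2_raw = x$chi2_raw, a = x$a,
         reached = x$reached)
}
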