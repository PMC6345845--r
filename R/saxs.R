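# SAXS: Debye-formula profiles from bead models, Guinier analysis, and
# chi-square fitting of model profiles against a target curve with the
# analytic intensity scale.

#' SAXS profile container
#'
#' A tibble of `(q, intensity, sigma)` triplets; `sigma` is absent (NA) for
#' theoretical profiles.
#'
#' @param q momentum transfer grid, 1/Angstrom, strictly increasing, >= 0.
#' @param intensity scattering intensity, arbitrary units.
#' @param sigma optional per-point statistical error (> 0).
#' @return A tibble of class `saxs_profile`.
#' @export
saxs_profile <- function(q, intensity, sigma = NULL) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity)) abort("q and intensity lengths differ")
  if (any(q < 0)) abort("q must be >= 0")
  if (is.unsorted(q, strictly = TRUE)) abort("q must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) abort("sigma length differs from q")
    if (any(!is.finite(sigma)) || any(sigma <= 0)) abort("sigma must be > 0")
  } else {
    sigma <- rep(NA_real_, length(q))
  }
  structure(tibble(q = q, intensity = intensity, sigma = sigma),
            class = c("saxs_profile", "tbl_df", "tbl", "data.frame"))
}

#' Theoretical scattering intensity by the Debye formula
#'
#' Orientation-averaged intensity of a bead model:
#' `I(q) = sum_ij f_i(q) f_j(q) sin(q r_ij) / (q r_ij)`, with the `i = j`
#' and `q = 0` limits taken as 1.
#'
#' @param x conformation or n x 3 coordinate matrix.
#' @param q momentum-transfer grid (1/Angstrom).
#' @param form_factors per-bead form factors: a scalar (same for all
#'   beads), a length-n vector (constant in q), or an n x length(q) matrix
#'   (q-dependent table).
#' @return A [saxs_profile] (no sigma).
#' @export
debye_intensity <- function(x, q, form_factors = 1) {
  xyz <- as_coords(x)
  n <- nrow(xyz)
  if (n < 1) abort("empty conformation")
  q <- as.numeric(q)
  nq <- length(q)
  f <- form_factors
  if (is.matrix(f)) {
    if (nrow(f) != n || ncol(f) != nq) abort("form-factor table must be n x length(q)")
  } else {
    if (length(f) == 1) f <- rep(f, n)
    if (length(f) != n) abort("form_factors must be length 1, n, or n x nq")
    f <- matrix(f, n, nq)
  }
  self <- colSums(f^2)
  if (n == 1) return(saxs_profile(q, self))
  d <- as.vector(dist(xyz))              # n(n-1)/2 pair distances
  # dist() orders pairs (2,1),(3,1),...,(n,1),(3,2),...: lower triangle
  # by column; matching index vectors:
  ii <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  jj <- rep(seq_len(n - 1), times = (n - 1):1)
  inten <- numeric(nq)
  chunk <- max(1L, floor(5e6 / length(d)))
  for (start in seq(1, nq, by = chunk)) {
    cols <- start:min(nq, start + chunk - 1)
    qd <- outer(d, q[cols])
    s <- sin(qd) / qd
    s[qd == 0] <- 1
    fp <- f[ii, cols, drop = FALSE] * f[jj, cols, drop = FALSE]
    inten[cols] <- self[cols] + 2 * colSums(fp * s)
  }
  saxs_profile(q, inten)
}

#' Pointwise weighted mean of ensemble member profiles
#'
#' @param profiles list of [saxs_profile]s on a common q grid.
#' @param weights non-negative weights summing to 1 (within 1e-8).
#' @return A [saxs_profile].
#' @export
ensemble_intensity <- function(profiles, weights) {
  if (length(profiles) != length(weights)) {
    abort("weights length must match number of profiles")
  }
  if (any(weights < 0)) abort("weights must be >= 0")
  if (abs(sum(weights) - 1) > 1e-8) abort("weights must sum to 1")
  q <- profiles[[1]]$q
  for (p in profiles) {
    if (length(p$q) != length(q) || any(p$q != q)) {
      abort("profiles must share a common q grid")
    }
  }
  inten <- Reduce(`+`, Map(function(p, w) w * p$intensity, profiles, weights))
  saxs_profile(q, inten)
}

#' Interpolate a model profile onto a target q grid
#'
#' Linear interpolation in q; extrapolation outside the model's q range is
#' an error.
#'
#' @param model a [saxs_profile].
#' @param q target grid.
#' @return Intensity vector on `q`.
#' @export
interpolate_intensity <- function(model, q) {
  if (min(q) < min(model$q) - 1e-12 || max(q) > max(model$q) + 1e-12) {
    abort("target q grid extends beyond the model profile (extrapolation forbidden)")
  }
  approx(model$q, model$intensity, xout = q, rule = 1)$y
}

#' Fit a model profile to a target profile (scale + chi-square)
#'
#' The intensity scale `a` is the unique solution of `d chi2 / d a = 0`:
#' `a = sum(I_exp I_mod / sigma^2) / sum(I_mod^2 / sigma^2)`. The
#' chi-square is the error-weighted sum of squared residuals
#' `sum((I_exp - a I_mod)^2 / sigma^2)`; the headline value reported is the
#' reduced statistic (divided by the number of points), with the raw sum
#' kept alongside.
#'
#' @param target a [saxs_profile] with `sigma` present.
#' @param model a [saxs_profile] (interpolated onto the target grid if its
#'   grid differs).
#' @return An object of class `saxs_fit`: list with `a`, `chi2` (reduced),
#'   `chi2_raw`, `n`.
#' @export
chi2_fit <- function(target, model) {
  if (all(is.na(target$sigma))) abort("target profile must carry sigma")
  im <- if (length(model$q) == length(target$q) &&
            isTRUE(all.equal(model$q, target$q))) {
    model$intensity
  } else {
    interpolate_intensity(model, target$q)
  }
  fit_scaled(target$intensity, im, target$sigma)
}

fit_scaled <- function(ie, im, sigma) {
  if (all(im == 0)) abort("all-zero model profile")
  w <- 1 / sigma^2
  a <- sum(w * ie * im) / sum(w * im^2)
  raw <- sum(w * (ie - a * im)^2)
  nq <- length(ie)
  structure(list(a = a, chi2 = raw / nq, chi2_raw = raw, n = nq),
            class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("SAXS fit: reduced chi2 = %.4g (raw %.4g, N = %d), scale a = %.4g\n",
              x$chi2, x$chi2_raw, x$n, x$a))
  invisible(x)
}

#' @export
tidy.saxs_fit <- function(x, ...) {
  tibble(term = "a", estimate = x$a)
}

#' @export
glance.saxs_fit <- function(x, ...) {
  tibble(chi2 = x$chi2, chi2_raw = x$chi2_raw, n = x$n, a = x$a)
}

#' Guinier analysis of a low-q SAXS profile
#'
#' Iteratively fits `ln I = ln I0 - q^2 Rg^2 / 3` by (weighted) linear
#' regression on `q^2`, shrinking the fit window until
#' `q_max * Rg <= qrg_limit` (the validity region of the Guinier
#' approximation for globular particles) reaches a fixed point.
#'
#' @param profile a [saxs_profile]; points with non-positive intensity are
#'   dropped with a warning.
#' @param qrg_limit validity limit on `q * Rg` (default 1.3).
#' @param min_points minimum usable points in the window (default 5).
#' @return An object of class `guinier_result`: `rg`, `i0`, `window`
#'   (index range used), `qmax_rg`, `n`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 5) {
  keep <- is.finite(profile$intensity) & profile$intensity > 0 & profile$q > 0
  if (any(!keep)) {
    warn(sprintf("dropping %d non-positive/zero-q points from Guinier fit",
                 sum(!keep)))
  }
  q <- profile$q[keep]
  i <- profile$intensity[keep]
  s <- profile$sigma[keep]
  if (length(q) < min_points) abort("too few usable low-q points")
  w <- if (all(is.na(s))) rep(1, length(q)) else (i / s)^2  # ln-space weights
  upper <- length(q)
  rg <- NA_real_
  for (iter in 1:100) {
    idx <- seq_len(upper)
    if (length(idx) < min_points) {
      abort("no stable Guinier window: fewer than min_points inside qRg limit")
    }
    fit <- lm(log(i[idx]) ~ I(q[idx]^2), weights = w[idx])
    slope <- coef(fit)[2]
    if (!is.finite(slope) || slope >= 0) {
      abort("no stable Guinier window: non-decreasing low-q intensity")
    }
    rg <- sqrt(-3 * slope)
    if (q[1] * rg > qrg_limit) {
      abort("no valid Guinier window: q_min * Rg already exceeds the limit")
    }
    new_upper <- max(which(q * rg <= qrg_limit))
    if (new_upper == upper) break
    upper <- new_upper
  }
  i0 <- exp(coef(fit)[1])
  structure(list(rg = unname(rg), i0 = unname(i0),
                 window = c(1L, upper), qmax_rg = q[upper] * rg,
                 n = upper),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier fit: Rg = %.2f A, I0 = %.4g (%d points, qmax*Rg = %.2f)\n",
              x$rg, x$i0, x$n, x$qmax_rg))
  invisible(x)
}

#' @export
tidy.guinier_result <- function(x, ...) {
  tibble(term = c("rg", "i0"), estimate = c(x$rg, x$i0))
}

#' @export
glance.guinier_result <- function(x, ...) {
  tibble(rg = x$rg, i0 = x$i0, n = x$n, qmax_rg = x$qmax_rg)
}

#' Kratky transform of a profile
#'
#' @param profile a [saxs_profile].
#' @return Tibble with `q` and `q2I = q^2 * I(q)` (the Kratky ordinate).
#' @export
kratky <- function(profile) {
  tibble(q = profile$q, q2I = profile$q^2 * profile$intensity)
}
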