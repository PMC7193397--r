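#' Linear calendar spline for seasonality and long-term trend
#'
#' Degree-1 B-spline basis on the day index with equally spaced interior
#' knots, giving `df_per_year * n_years` columns (intercept excluded).
#' Together with an intercept it reproduces exactly any continuous
#' piecewise-linear function with breaks at the knots.
#'
#' @param day_index numeric vector of day indices (1, 2, ...) covering the
#'   study period.
#' @param df_per_year integer, degrees of freedom per year (default 5).
#' @param n_years number of years spanned; defaults to the index range
#'   divided by 365.25.
#' @return design matrix with `round(df_per_year * n_years)` columns and
#'   attributes `knots` and `boundary`.
#' @export
calendar_spline <- function(day_index, df_per_year = 5L, n_years = NULL) {
  if (df_per_year < 1) stop("'df_per_year' must be >= 1")
  rng <- range(day_index)
  if (is.null(n_years)) n_years <- (rng[2L] - rng[1L] + 1) / 365.25
  total_df <- max(1L, as.integer(round(df_per_year * n_years)))
  if (total_df >= length(unique(day_index))) {
    stop("requested df (", total_df, ") too large for ",
         length(unique(day_index)), " distinct days")
  }
  interior <- if (total_df > 1L) {
    seq(rng[1L], rng[2L], length.out = total_df + 1L)[-c(1L, total_df + 1L)]
  } else numeric(0)
  B <- splines::bs(day_index, degree = 1L, knots = interior,
                   Boundary.knots = rng, intercept = FALSE)
  out <- unclass(B)[, , drop = FALSE]
  colnames(out) <- paste0("season", seq_len(ncol(out)))
  attr(out, "knots") <- interior
  attr(out, "boundary") <- rng
  out
}

#' Cubic regression spline with knots at quantiles
#'
#' Cubic B-spline basis with `df` columns (intercept excluded) and `df - 3`
#' interior knots at equally spaced quantiles of `x` — the standard basis an
#' analyst obtains from `splines::bs(x, df = df)`.  Together with an
#' intercept it reproduces any cubic polynomial exactly.
#'
#' @param x numeric vector.
#' @param df degrees of freedom, `>= 4`.
#' @return design matrix with `df` columns and attributes `knots` and
#'   `boundary`.
#' @export
cubic_quantile_spline <- function(x, df = 5L) {
  if (df < 4) stop("'df' must be >= 4 for a cubic basis")
  if (diff(range(x)) == 0) stop("'x' is constant; spline basis degenerate")
  n_int <- df - 3L
  probs <- seq(0, 1, length.out = n_int + 2L)[-c(1L, n_int + 2L)]
  interior <- as.numeric(stats::quantile(x, probs, names = FALSE, type = 7))
  B <- splines::bs(x, degree = 3L, knots = interior,
                   Boundary.knots = range(x), intercept = FALSE)
  out <- unclass(B)[, , drop = FALSE]
  attr(out, "knots") <- interior
  attr(out, "boundary") <- range(x)
  out
}

# thin-plate kernel in two dimensions; phi(0) = 0 by continuity
tps_phi <- function(d) {
  out <- d
  out[] <- 0
  pos <- d > 0
  out[pos] <- d[pos]^2 * log(d[pos])
  out
}

# deterministic greedy max-min space-filling design: start at the candidate
# nearest the centroid, then repeatedly add the candidate farthest (in
# min-distance) from the current set; ties break to the lowest index.
maxmin_knots <- function(pts, K) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  d_ctr <- (pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2
  chosen <- integer(K)
  chosen[1L] <- which.min(d_ctr)
  mind <- (pts[, 1L] - pts[chosen[1L], 1L])^2 +
    (pts[, 2L] - pts[chosen[1L], 2L])^2
  if (K > 1L) for (k in 2L:K) {
    nxt <- which.max(mind)
    chosen[k] <- nxt
    dd <- (pts[, 1L] - pts[nxt, 1L])^2 + (pts[, 2L] - pts[nxt, 2L])^2
    mind <- pmin(mind, dd)
  }
  chosen
}

#' Penalized bivariate thin-plate radial basis
#'
#' Constructs the low-rank bivariate smoother design used by the outcome
#' model.  Both inputs are min-max standardized to `[0, 1]`; `K` knots are
#' placed among the observed (standardized) pairs by a deterministic greedy
#' max-min design; radial columns use the 2-D thin-plate kernel
#' `phi(d) = d^2 log d`; and the radial block is linearly transformed
#' (whitened by the inverse symmetric square root of the knot kernel
#' matrix's absolute value) so that the roughness penalty is the identity on
#' the radial coefficients and zero on the unpenalized block `[1, z, r]`.
#'
#' @param z,r numeric vectors of equal length (exposure and GPS at the
#'   training days).
#' @param K number of radial knots, `4 <= K <` number of distinct pairs.
#' @return an object of class `penalized_basis`: list with elements `X`
#'   (n x (3+K) design), `penalty` (diagonal of the penalty matrix),
#'   `knots` (K x 2, standardized), `ranges`, and `whiten` (K x K).
#' @export
radial_penalized_basis <- function(z, r, K = 50L) {
  n <- length(z)
  if (length(r) != n) stop("'z' and 'r' must have equal length")
  if (K < 4L) stop("'K' must be at least 4")
  ranges <- list(z = range(z), r = range(r))
  zs <- rescale01(z, ranges$z)
  rs <- rescale01(r, ranges$r)
  pts <- cbind(zs, rs)
  distinct <- !duplicated(pts)
  if (K >= sum(distinct)) {
    stop("'K' (", K, ") must be smaller than the number of distinct (z, r) ",
         "pairs (", sum(distinct), ")")
  }
  cand <- pts[distinct, , drop = FALSE]
  knots <- cand[maxmin_knots(cand, K), , drop = FALSE]

  Phi <- tps_phi(pair_dist(pts, knots))             # n x K raw radial block
  Omega <- tps_phi(pair_dist(knots, knots))         # K x K knot kernel
  Omega <- (Omega + t(Omega)) / 2
  eo <- eigen(Omega, symmetric = TRUE)
  # the 2-D thin-plate kernel is conditionally positive definite, so Omega
  # is indefinite; whiten by the matrix absolute value (eigenvalue
  # magnitudes, floored relative to the largest for numerical safety)
  ev <- pmax(abs(eo$values), 1e-8 * max(abs(eo$values), 1e-8))
  whiten <- eo$vectors %*% (t(eo$vectors) / sqrt(ev))  # |Omega|^{-1/2}
  Xr <- Phi %*% whiten

  X <- cbind(1, zs, rs, Xr)
  colnames(X) <- c("(Intercept)", "z", "r", paste0("tps", seq_len(K)))
  structure(list(X = X,
                 penalty = c(rep(0, 3L), rep(1, K)),
                 knots = knots,
                 ranges = ranges,
                 whiten = whiten),
            class = "penalized_basis")
}

rescale01 <- function(x, rng) {
  if (diff(rng) == 0) stop("degenerate range in standardization")
  (x - rng[1L]) / (rng[2L] - rng[1L])
}

pair_dist <- function(a, b) {
  # Euclidean distances between rows of a (n x 2) and rows of b (m x 2)
  da <- outer(a[, 1L], b[, 1L], "-")
  db <- outer(a[, 2L], b[, 2L], "-")
  sqrt(da * da + db * db)
}

#' Evaluate a penalized radial basis at new points
#'
#' Standardizes `(z, r)` by the training ranges, clamps each coordinate into
#' `[0, 1]` (counterfactual GPS values can fall outside the training cloud),
#' and returns the design matrix aligned with the training coefficients.
#'
#' @param basis a `penalized_basis`.
#' @param z,r numeric vectors of equal length.
#' @return design matrix with attribute `n_clamped`, the number of points
#'   with at least one clamped coordinate.
#' @export
eval_penalized_basis <- function(basis, z, r) {
  zs <- rescale01(z, basis$ranges$z)
  rs <- rescale01(r, basis$ranges$r)
  clamped <- (zs < 0) | (zs > 1) | (rs < 0) | (rs > 1)
  zs <- pmin(pmax(zs, 0), 1)
  rs <- pmin(pmax(rs, 0), 1)
  Xr <- tps_phi(pair_dist(cbind(zs, rs), basis$knots)) %*% basis$whiten
  X <- cbind(1, zs, rs, Xr)
  colnames(X) <- colnames(basis$X)
  attr(X, "n_clamped") <- sum(clamped)
  X
}

#' Generalized cross-validation score
#'
#' `n * deviance / (n - edf)^2`, the criterion minimized over the smoothing
#' parameter of the outcome model.
#'
#' @param deviance model deviance.
#' @param n number of observations.
#' @param edf effective degrees of freedom (trace of the influence matrix),
#'   must satisfy `0 <= edf < n`.
#' @return the GCV score.
#' @export
gcv_score <- function(deviance, n, edf) {
  if (edf >= n) stop("GCV undefined: edf (", edf, ") >= n (", n, ")")
  n * deviance / (n - edf)^2
}
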