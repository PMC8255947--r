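## Difference-data assembly, noise scaling, regularized LSQR solution of the
## augmented system, and the region/contrast evaluation metrics.

#' Assemble noise-scaled difference data
#'
#' Forms b = y - y_ref and the diagonal row scaling S = diag(1/sigma) of
#' the objective. Zero or negative sigmas are floored at `sigma_min`
#' (default: the smallest positive sigma) with a warning.
#'
#' @param y windowed data vector (pair-major, windows contiguous)
#' @param y_ref homogeneous reference, same shape
#' @param sigma per-entry standard deviation of the difference
#' @param sigma_min floor for degenerate sigmas
#' @return list with `b` (raw difference), `S` (vector of 1/sigma) and
#'   `b_scaled` = S * b
#' @export
differenceData <- function(y, y_ref, sigma, sigma_min = NULL) {
  stopifnot(length(y) == length(y_ref), length(sigma) == length(y))
  bad <- !is.finite(sigma) | sigma <= 0
  if (any(bad)) {
    if (is.null(sigma_min)) {
      pos <- sigma[!bad]
      sigma_min <- if (length(pos)) min(pos) else 1
    }
    warning(sprintf("differenceData: %d sigmas floored at %g", sum(bad), sigma_min))
    sigma[bad] <- sigma_min
  }
  b <- y - y_ref
  s <- 1 / sigma
  list(b = b, S = s, b_scaled = s * b)
}

#' LSQR solver for sparse/operator least squares
#'
#' Paige-Saunders LSQR for min ||A x - b||_2 with `A` given as a pair of
#' matrix-vector product closures. Deterministic: starts from x = 0, so a
#' zero right-hand side returns exactly zero.
#'
#' @param aprod function(x) returning A x
#' @param atprod function(y) returning A' y
#' @param b right-hand side
#' @param n number of unknowns
#' @param max_iter iteration cap
#' @param atol relative-residual stopping tolerance
#' @return list with `x`, `iterations`, `relres` (||Ax - b|| / ||b||)
#' @export
lsqrSolve <- function(aprod, atprod, b, n, max_iter = 100, atol = 1e-8) {
  x <- numeric(n)
  beta0 <- sqrt(sum(b^2))
  if (beta0 == 0) return(list(x = x, iterations = 0L, relres = 0))
  u <- b / beta0
  v <- atprod(u)
  alpha <- sqrt(sum(v^2))
  if (alpha == 0) return(list(x = x, iterations = 0L, relres = 1))
  v <- v / alpha
  w <- v
  phibar <- beta0; rhobar <- alpha
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    u <- aprod(v) - alpha * u
    beta <- sqrt(sum(u^2))
    if (beta > 0) u <- u / beta
    v <- atprod(u) - beta * v
    alpha <- sqrt(sum(v^2))
    if (alpha > 0) v <- v / alpha
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho; sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    if (any(!is.finite(x))) stop("lsqrSolve: divergence (non-finite iterate)")
    if (phibar / beta0 < atol) break
  }
  list(x = x, iterations = iter, relres = phibar / beta0)
}

#' Solve the regularized Born inversion
#'
#' LSQR solution of the stacked system
#' \deqn{\left\| \binom{S J}{\alpha^{1/2} L} \binom{\delta\mu_a}{\delta\kappa}
#'   - \binom{S b}{0} \right\|^2 \to \min.}
#' With `L = NULL` and `alpha = 0` this is unregularized least squares;
#' with `L = NULL` and a nonzero alpha the zeroth-order Tikhonov operator
#' (identity) is substituted. A first-order operator from
#' [buildRegularizer()] (N columns) is applied to each coefficient block.
#' The automatic `alpha` scales the user factor by the ratio of the
#' squared Frobenius norms of S J and L.
#'
#' @param system a [SystemMatrix-class]
#' @param S row scaling vector (1/sigma), or NULL for unweighted
#' @param b raw difference-data vector (unscaled)
#' @param L regularization operator (N or 2N columns), or NULL
#' @param alpha regularization weight, or "auto"
#' @param alpha_factor multiplier for the automatic weight (default 10,
#'   set by the discrepancy principle on synthetic phantom data)
#' @param max_iter LSQR iteration cap
#' @param atol LSQR relative-residual tolerance
#' @return a [ReconstructionResult-class]
#' @export
solveSystem <- function(system, S, b, L = NULL, alpha = "auto",
                        alpha_factor = 10, max_iter = 100, atol = 1e-8) {
  J <- system@J
  n <- nVoxels(system@grid)
  if (is.null(S)) S <- rep(1, nrow(J))
  stopifnot(length(S) == nrow(J), length(b) == nrow(J))
  unreg <- is.null(L) && identical(alpha, 0)
  if (!unreg) {
    if (is.null(L)) L <- Matrix::Diagonal(2 * n)
    if (ncol(L) == n) L <- Matrix::bdiag(L, L)
    stopifnot(ncol(L) == 2 * n)
  }
  if (identical(alpha, "auto")) {
    if (unreg) alpha <- 0
    else {
      nJ2 <- sum((S^2) %*% (J^2))
      nL2 <- sum(L^2)
      alpha <- alpha_factor * nJ2 / nL2
    }
  }
  stopifnot(is.numeric(alpha), alpha >= 0)
  sa <- sqrt(alpha)
  m <- nrow(J)
  if (unreg || alpha == 0) {
    aprod <- function(x) S * as.numeric(J %*% x)
    atprod <- function(y) as.numeric(crossprod(J, S * y))
    rhs <- S * b
  } else {
    aprod <- function(x) c(S * as.numeric(J %*% x), sa * as.numeric(L %*% x))
    atprod <- function(y) as.numeric(crossprod(J, S * y[seq_len(m)])) +
      sa * as.numeric(Matrix::crossprod(L, y[-seq_len(m)]))
    rhs <- c(S * b, numeric(nrow(L)))
  }
  sol <- lsqrSolve(aprod, atprod, rhs, 2 * n, max_iter = max_iter, atol = atol)
  d <- gridDims(system@grid)
  new("ReconstructionResult",
      delta_mu_a = array(sol$x[seq_len(n)], d),
      delta_kappa = array(sol$x[n + seq_len(n)], d),
      grid = system@grid, alpha = as.numeric(alpha),
      iterations = as.numeric(sol$iterations), residual = sol$relres)
}

#' Localize the reconstructed inclusion region
#'
#' The region omega of voxels whose standardized deviation from the
#' median exceeds `threshold` (default 4):
#' |field - median(field)| / std(field) > threshold. A constant field
#' yields an empty region.
#'
#' @param field 3D voxel field (e.g. [deltaMuA()] of a result)
#' @param threshold z-score threshold (default 4)
#' @param robust use the median absolute deviation instead of the standard
#'   deviation?
#' @return logical array, TRUE inside omega
#' @export
localizeRegion <- function(field, threshold = 4, robust = FALSE) {
  med <- stats::median(field)
  s <- if (robust) stats::mad(field) else stats::sd(field)
  if (!is.finite(s) || s == 0) return(array(FALSE, dim(field)))
  abs(field - med) / s > threshold
}

#' Region metrics of a reconstruction
#'
#' Summary statistics of a reconstructed absorption-perturbation field over
#' a localized region omega: mean and integral of the field in omega, the
#' intensity-weighted centroid and its displacement from the true
#' inclusion centroid, the bounding-box elongations of omega, and the
#' nominal and reconstructed absorption contrasts
#' NC = mu_a,in_true / mu_a,bulk_true,
#' RC = mu_a,in_recon / mu_a,bulk_recon (means inside omega and over its
#' complement, each offset by the bulk reference absorption).
#'
#' @param field 3D array of reconstructed delta mu_a, mm^-1
#' @param omega logical array (from [localizeRegion()])
#' @param grid the [VoxelGrid-class]
#' @param mu_a_bulk bulk (reference) absorption, mm^-1
#' @param truth optional list with `centroid` (mm), `mu_a_in`, `mu_a_bulk`
#' @return one-row data.frame of metrics (NA-filled if omega is empty)
#' @export
regionMetrics <- function(field, omega, grid, mu_a_bulk, truth = NULL) {
  out <- data.frame(n_omega = sum(omega), mean_in = NA_real_,
                    integral_in = NA_real_, x = NA_real_, y = NA_real_,
                    z = NA_real_, d = NA_real_, dx = NA_real_, dy = NA_real_,
                    dz = NA_real_, rc = NA_real_, nc = NA_real_)
  if (!is.null(truth) && !is.null(truth$mu_a_in))
    out$nc <- truth$mu_a_in / (if (is.null(truth$mu_a_bulk)) mu_a_bulk else truth$mu_a_bulk)
  if (!any(omega)) return(out)
  vol <- voxelVolume(grid)
  vals <- field[omega]
  out$mean_in <- mean(vals)
  out$integral_in <- sum(vals) * vol
  centers <- voxelCenters(grid)
  widx <- which(as.vector(omega))
  wts <- abs(vals)
  if (sum(wts) == 0) wts <- rep(1, length(vals))
  cen <- colSums(centers[widx, , drop = FALSE] * wts) / sum(wts)
  out$x <- cen[1]; out$y <- cen[2]; out$z <- cen[3]
  if (!is.null(truth) && !is.null(truth$centroid))
    out$d <- sqrt(sum((cen - truth$centroid)^2))
  ext <- apply(centers[widx, , drop = FALSE], 2, function(v) diff(range(v)) + grid@voxel)
  out$dx <- ext[1]; out$dy <- ext[2]; out$dz <- ext[3]
  mu_in <- mu_a_bulk + out$mean_in
  mu_out <- mu_a_bulk + mean(field[!omega])
  out$rc <- mu_in / mu_out
  out
}
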