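#' Singular value thresholding
#'
#' Proximal operator of the nuclear norm: computes the SVD `x = U S V'` and
#' shrinks every singular value towards zero by `tau`, dropping those at or
#' below the threshold. The result has rank no larger than `x` and smaller
#' nuclear norm.
#'
#' @param x numeric matrix with finite entries.
#' @param tau non-negative shrinkage.
#' @return Matrix of the same shape as `x`.
#' @export
svt <- function(x, tau) {
  if (!is.matrix(x) || !is.numeric(x) || any(!is.finite(x)))
    stop("`x` must be a finite numeric matrix")
  if (tau < 0) stop("`tau` must be non-negative")
  if (tau == 0) return(x)
  m <- nrow(x); n <- ncol(x)
  # exact SVD via the symmetric eigendecomposition of the short-side Gram
  # matrix: much cheaper than a full rectangular SVD and only the components
  # surviving the threshold are reconstructed
  flip <- m > n
  g <- if (flip) crossprod(x) else tcrossprod(x)
  ev <- eigen(g, symmetric = TRUE)
  d <- sqrt(pmax(ev$values, 0))
  if (tau < 1e-6 * d[1]) {
    # Gram route loses accuracy for singular values far below sigma_1;
    # with a tiny threshold those survive, so use the rectangular SVD
    sv <- svd(x)
    dd <- pmax(sv$d - tau, 0)
    keep <- dd > 0
    if (!any(keep)) return(matrix(0, m, n))
    return(sv$u[, keep, drop = FALSE] %*%
             (dd[keep] * t(sv$v[, keep, drop = FALSE])))
  }
  keep <- d > tau
  if (!any(keep)) return(matrix(0, m, n))
  U <- ev$vectors[, keep, drop = FALSE]
  shrink <- (d[keep] - tau) / d[keep]
  if (flip) {
    (x %*% U) %*% (shrink * t(U))        # x V diag((d-tau)/d) V'
  } else {
    U %*% (shrink * crossprod(U, x))     # U diag((d-tau)/d) U' x
  }
}

#' Entrywise soft thresholding
#'
#' Proximal operator of the l1 norm: `sign(x) * max(|x| - tau, 0)` applied to
#' every entry (with `sign(0) = 0`).
#'
#' @param x numeric matrix or vector.
#' @param tau non-negative shrinkage.
#' @return Object of the same shape as `x`.
#' @export
soft_threshold <- function(x, tau) {
  if (tau < 0) stop("`tau` must be non-negative")
  sign(x) * pmax(abs(x) - tau, 0)
}

# Gram matrix of the shorter side (for spectral-scale probes).
tcrossprod_small <- function(x) {
  if (nrow(x) <= ncol(x)) tcrossprod(x) else crossprod(x)
}

#' Sparsity weight of Candes-style principal component pursuit
#'
#' The common default for the l1 weight in robust PCA is `1 / sqrt(max(m, n))`
#' for an `m x n` matrix, which carries exact-recovery guarantees for
#' incoherent low-rank matrices under random sparse corruption. It is offered
#' as an alternative preset to the fixed default `lam = 0.01`.
#'
#' @param d numeric matrix, or an [voltage_matrix()] object.
#' @return The scalar weight.
#' @export
candes_lambda <- function(d) {
  if (inherits(d, "eit_voltage")) d <- d$data
  1 / sqrt(max(dim(d)))
}

#' Robust principal component analysis
#'
#' Decomposes an observed matrix `D` into a low-rank component `L` (the
#' structured signal; for EIT, the respiratory voltages) plus a sparse
#' component `S` (outliers; spike-like noise) by solving
#' \deqn{\min_{L,S} \|L\|_* + \lambda \|S\|_1 \quad \mathrm{s.t.}\quad D = L + S}
#' with an augmented-Lagrangian ADMM. Each iteration performs, in order,
#' \itemize{
#'   \item `L <- svt(D - S + mu/rho, 1/rho)` (singular value thresholding),
#'   \item `S <- soft_threshold(D - L + mu/rho, lam/rho)`,
#'   \item `mu <- mu + rho * (D - L - S)` (multiplier ascent),
#' }
#' starting from `S = 0`, `mu = 0`, and stops when the relative constraint
#' residual `||D - L - S||_F / max(1, ||D||_F)` drops to `eps` (the exact
#' constraint `D = L + S` holds at the optimum, so the residual measures
#' remaining suboptimality; the normalisation makes the rule indifferent to
#' the arbitrary voltage scale of a recording).
#'
#' @param d numeric matrix, at least 2 x 2, all entries finite.
#' @param lam sparsity weight \eqn{\lambda > 0}. Default 0.01; see
#'   [candes_lambda()] for the size-adaptive alternative.
#' @param rho augmented-Lagrangian penalty \eqn{\lambda_0 > 0} (default 10).
#'   Both proximal shrinkages derive from it: `1/rho` for the singular values,
#'   `lam/rho` for the entries of `S`.
#' @param eps relative stopping tolerance (default 1e-8).
#' @param max_iter iteration cap (default 1000). Hitting the cap returns the
#'   current iterate with `converged = FALSE` and a warning, not an error:
#'   partial decompositions are diagnostically useful when the penalty needs
#'   re-tuning for an unusual dataset.
#' @param method `"fixed"` (default) runs the augmented-Lagrangian iteration
#'   with the penalty held at `rho` throughout. `"continuation"` runs the
#'   standard inexact-ALM schedule instead: the penalty starts at
#'   `1.25 / sigma_1(d)` and grows by `rho_growth` each iteration (capped at
#'   `1e9 / sigma_1(d)`), so the singular-value threshold starts at the data's
#'   spectral scale and tightens geometrically. Both methods solve the same
#'   convex program and agree at convergence; the fixed penalty converges
#'   slowly when the corruption carries large spectral mass (each iteration
#'   shaves only `1/rho` off a singular value, so spike energy sitting in `L`
#'   takes about `rho * sigma_spike` iterations to migrate into `S`), while
#'   continuation reaches the optimum in a few dozen iterations.
#' @param rho_growth per-iteration penalty growth factor for
#'   `method = "continuation"` (default 1.2; ignored for `"fixed"`). Growing
#'   the penalty too aggressively can freeze the iteration at a feasible but
#'   suboptimal split, so the default is deliberately conservative.
#'
#' @return An object of class `rpca`: list with `L`, `S`, `mu` (matrices of
#'   the shape of `d`), `n_iter`, `residual_trace` (Frobenius norm of
#'   `D - L - S` after each iteration, unnormalised), `converged`, and the
#'   configuration used. Methods: [print.rpca()], [summary.rpca()],
#'   [fitted.rpca()] (returns `L`), [residuals.rpca()] (returns `D - L - S`),
#'   [plot.rpca()] (residual trace).
#' @examples
#' # a rank-1 signal with one corrupted entry; at this generic (small) size
#' # the size-adaptive sparsity weight is the right preset
#' d <- outer(sin(1:40 / 3), cos(1:60 / 5))
#' d[5, 7] <- 25 * d[5, 7]
#' fit <- rpca(d, lam = candes_lambda(d), method = "continuation")
#' which(abs(fit$S) > 1, arr.ind = TRUE)   # the corrupted entry
#' @export
rpca <- function(d, lam = 0.01, rho = 10, eps = 1e-8, max_iter = 1000L,
                 method = c("fixed", "continuation"), rho_growth = 1.2) {
  if (!is.matrix(d) || !is.numeric(d) || any(!is.finite(d)))
    stop("`d` must be a finite numeric matrix")
  if (nrow(d) < 2L || ncol(d) < 2L) stop("`d` must be at least 2 x 2")
  if (lam <= 0 || rho <= 0 || eps <= 0) stop("lam, rho and eps must be positive")
  method <- match.arg(method)
  if (rho_growth < 1) stop("`rho_growth` must be >= 1")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")

  scale <- max(1, sqrt(sum(d^2)))
  s1 <- if (sum(d^2) > 0) sqrt(eigen(tcrossprod_small(d), symmetric = TRUE,
                                     only.values = TRUE)$values[1]) else 0
  rho_k <- if (method == "continuation" && s1 > 0) 1.25 / s1 else rho
  rho_cap <- if (s1 > 0) 1e9 / s1 else Inf
  S <- matrix(0, nrow(d), ncol(d))
  mu <- S
  L <- S
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    L <- svt(d - S + mu / rho_k, 1 / rho_k)
    S <- soft_threshold(d - L + mu / rho_k, lam / rho_k)
    R <- d - L - S
    mu <- mu + rho_k * R
    res <- sqrt(sum(R^2))
    trace[it] <- res
    if (res / scale <= eps) { converged <- TRUE; break }
    if (method == "continuation")
      rho_k <- min(rho_k * rho_growth, rho_cap)
  }
  if (!converged)
    warning(sprintf("rpca did not reach tolerance %g in %d iterations (relative residual %.3g)",
                    eps, max_iter, trace[it] / scale))
  structure(list(L = L, S = S, mu = mu, residual = R, n_iter = it,
                 residual_trace = trace, converged = converged,
                 lam = lam, rho = rho, eps = eps, max_iter = max_iter,
                 method = method),
            class = "rpca")
}

#' @export
print.rpca <- function(x, ...) {
  cat(sprintf("Robust PCA decomposition (%d x %d)\n", nrow(x$L), ncol(x$L)))
  cat(sprintf("  lambda = %g, rho = %g; %d iterations, %s\n",
              x$lam, x$rho, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  thr <- 1e-6 * max(abs(x$S), 1e-300)
  cat(sprintf("  rank(L) ~ %d, spike support: %d entries (%.2f%%, above 1e-6 of peak)\n",
              sum(svd(x$L, nu = 0, nv = 0)$d > 1e-9 * max(1, max(abs(x$L)))),
              sum(abs(x$S) > thr), 100 * mean(abs(x$S) > thr)))
  invisible(x)
}

#' @describeIn rpca residual trace, component norms and the achieved objective.
#' @param object,x an `rpca` fit.
#' @param ... unused.
#' @export
summary.rpca <- function(object, ...) {
  sv <- svd(object$L, nu = 0, nv = 0)$d
  out <- list(
    n_iter = object$n_iter, converged = object$converged,
    final_residual = utils::tail(object$residual_trace, 1),
    rank_L = sum(sv > 1e-9 * max(1, sv[1])),
    nuclear_norm_L = sum(sv),
    l1_norm_S = sum(abs(object$S)),
    objective = sum(sv) + object$lam * sum(abs(object$S)),
    # support at a numerically meaningful level (entries above 1e-6 of the
    # largest spike), so residual dust does not masquerade as support
    sparsity_S = mean(abs(object$S) > 1e-6 * max(abs(object$S), 1e-300)))
  class(out) <- "summary.rpca"
  out
}

#' @export
print.summary.rpca <- function(x, ...) {
  cat(sprintf(paste0(
    "RPCA summary: %d iterations (%s)\n",
    "  ||D-L-S||_F = %.3g; rank(L) = %d; ||L||_* = %.4g\n",
    "  ||S||_1 = %.4g (%.2f%% entries above 1e-6 of peak); objective = %.4g\n"),
    x$n_iter, if (x$converged) "converged" else "not converged",
    x$final_residual, x$rank_L, x$nuclear_norm_L,
    x$l1_norm_S, 100 * x$sparsity_S, x$objective))
  invisible(x)
}

#' @describeIn rpca the low-rank estimate `L`.
#' @export
fitted.rpca <- function(object, ...) object$L

#' @describeIn rpca the constraint residual `D - L - S` at the final iterate.
#' @export
residuals.rpca <- function(object, ...) object$residual

#' @describeIn rpca residual-trace convergence plot (log scale).
#' @export
plot.rpca <- function(x, ...) {
  graphics::plot(seq_along(x$residual_trace), x$residual_trace, type = "b",
                 log = "y", xlab = "iteration", ylab = "||D - L - S||_F",
                 main = "RPCA convergence", ...)
  invisible(x)
}

#' Denoise an EIT recording with robust PCA
#'
#' Applies [rpca()] to the full channels-by-frames matrix of a recording and
#' returns the clean (low-rank) and spike (sparse) parts as voltage matrices
#' carrying the original acquisition metadata.
#'
#' @param v an [voltage_matrix()] object.
#' @inheritParams rpca
#' @return A list with elements `clean` and `spikes` (both `eit_voltage`) and
#'   `fit` (the underlying `rpca` object).
#' @export
rpca_denoise <- function(v, lam = 0.01, rho = 10, eps = 1e-8,
                         max_iter = 1000L,
                         method = c("fixed", "continuation"),
                         rho_growth = 1.2) {
  stopifnot_voltage(v)
  fit <- rpca(v$data, lam = lam, rho = rho, eps = eps, max_iter = max_iter,
              method = method, rho_growth = rho_growth)
  list(
    clean = voltage_matrix(fit$L, v$frame_rate, v$n_electrodes, v$protocol_id),
    spikes = voltage_matrix(fit$S, v$frame_rate, v$n_electrodes, v$protocol_id),
    fit = fit)
}
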