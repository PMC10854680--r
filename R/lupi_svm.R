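#' Kernel configuration
#'
#' @param scale Positive kernel scale `s`; the Gaussian kernel is
#'   `exp(-||x - x'||^2 / s^2)`.
#' @param kernel `"gaussian"` or `"linear"` (`x . x'`; mainly for
#'   algebraic cross-checks of the privileged correction).
#' @param augmented When `TRUE`, 1 is added to every kernel value. This
#'   is the kernel of the augmented feature map `z <- [z, 1]`, which
#'   absorbs the bias term into the weight vector.
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(scale = 1, kernel = c("gaussian", "linear"),
                          augmented = TRUE) {
  kernel <- match.arg(kernel)
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("kernel scale must be a positive scalar", call. = FALSE)
  }
  structure(list(scale = scale, kernel = kernel, augmented = augmented),
            class = "kernel_config")
}

#' Kernel matrix between two sets of feature vectors
#'
#' @param A,B Numeric matrices with one row per observation and matching
#'   feature dimension (`B` defaults to `A`).
#' @param cfg A [kernel_config].
#' @return The `nrow(A) x nrow(B)` kernel matrix.
#' @export
gaussian_kernel_matrix <- function(A, B = A, cfg = kernel_config()) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (ncol(A) != ncol(B)) {
    stop("feature dimensions of A and B differ", call. = FALSE)
  }
  K <- if (cfg$kernel == "linear") {
    A %*% t(B)
  } else {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    exp(-d2 / cfg$scale^2)
  }
  if (cfg$augmented) K <- K + 1
  K
}

#' SVM+ hyperparameters
#'
#' @param C Positive penalty weighting the privileged slack model.
#' @param gamma Positive regulariser of the privileged weight vector;
#'   large `gamma` shrinks the privileged correction towards zero.
#' @param nu Level of the one-class dual constraint `sum(alpha) = nu * n`,
#'   in (0, 1].
#' @param regular_scale,privileged_scale Gaussian kernel scales of the
#'   regular and privileged space (`NULL` = `sqrt(d)` of the respective
#'   feature matrix at fit time).
#' @return An object of class `svmplus_hyperparams`.
#' @export
svmplus_hyperparams <- function(C = 1, gamma = 1, nu = 0.5,
                                regular_scale = NULL,
                                privileged_scale = NULL) {
  stopifnot(C > 0, gamma > 0, nu > 0, nu <= 1)
  structure(list(C = C, gamma = gamma, nu = nu,
                 regular_scale = regular_scale,
                 privileged_scale = privileged_scale),
            class = "svmplus_hyperparams")
}

#' Privileged correction matrix G
#'
#' The SVM+ dual adds to the regular-kernel matrix the correction
#' `G = P' (gamma I + C P P')^{-1} P`, where the columns of `P` are the
#' privileged feature vectors. The push-through identity turns this into
#' the kernelised form `G = K* (gamma I + C K*)^{-1}` with
#' `K* = P'P`, which is what is computed here, so any positive
#' semi-definite privileged kernel is supported.
#'
#' @param Kstar Privileged kernel matrix (`n x n`), or `NULL` to build it
#'   from `Pstar`.
#' @param Pstar Optional explicit privileged feature matrix (one row per
#'   observation) used with a linear kernel when `Kstar` is `NULL`.
#' @param gamma,C Positive SVM+ hyperparameters.
#' @return The symmetric positive semi-definite `n x n` matrix `G`.
#' @export
build_correction_matrix <- function(Kstar = NULL, Pstar = NULL,
                                    gamma = 1, C = 1) {
  stopifnot(gamma > 0, C > 0)
  if (is.null(Kstar)) {
    if (is.null(Pstar)) stop("supply Kstar or Pstar", call. = FALSE)
    Pstar <- as.matrix(Pstar)
    Kstar <- Pstar %*% t(Pstar)
  }
  Kstar <- as.matrix(Kstar)
  n <- nrow(Kstar)
  G <- Kstar %*% solve(gamma * diag(n) + C * Kstar)
  (G + t(G)) / 2
}

#' Solve the SVM+ dual by pairwise coordinate (SMO-style) updates
#'
#' Minimises `0.5 * t(alpha) %*% Q %*% alpha` subject to
#' `sum(alpha) = nu * n` and `0 <= alpha <= 1`, the dual of one-class
#' SVM with `Q = H + G`. The working pair is always the first maximal
#' violator (smallest gradient among coordinates that can grow, largest
#' among those that can shrink), which makes the solver deterministic.
#'
#' @param Q Symmetric positive semi-definite matrix.
#' @param nu Level parameter in (0, 1].
#' @param tol Stopping threshold on the KKT violation.
#' @param max_updates Cap on pairwise updates.
#' @return List with `alpha`, the attained `objective`, the final KKT
#'   `violation` and the number of `updates`.
#' @export
solve_svmplus_dual <- function(Q, nu = 0.5, tol = 1e-8,
                               max_updates = 200000L) {
  Q <- as.matrix(Q)
  n <- nrow(Q)
  if (!isTRUE(all.equal(Q, t(Q), tolerance = 1e-7))) {
    stop("Q must be symmetric", call. = FALSE)
  }
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]", call. = FALSE)
  alpha <- rep(nu, n)
  grad <- as.numeric(Q %*% alpha)
  eps <- 1e-12
  updates <- 0L
  repeat {
    up <- alpha < 1 - eps   # can grow
    dn <- alpha > eps       # can shrink
    if (!any(up) || !any(dn)) break
    i <- which(up)[which.min(grad[up])]
    j <- which(dn)[which.max(grad[dn])]
    viol <- grad[j] - grad[i]
    if (viol <= tol || updates >= max_updates) break
    curv <- Q[i, i] + Q[j, j] - 2 * Q[i, j]
    step <- if (curv > 1e-12) viol / curv else Inf
    step <- min(step, 1 - alpha[i], alpha[j])
    alpha[i] <- alpha[i] + step
    alpha[j] <- alpha[j] - step
    grad <- grad + step * (Q[, i] - Q[, j])
    updates <- updates + 1L
  }
  up <- alpha < 1 - eps; dn <- alpha > eps
  viol <- if (any(up) && any(dn)) max(grad[dn]) - min(grad[up]) else 0
  list(alpha = alpha,
       objective = 0.5 * sum(alpha * (Q %*% alpha)),
       violation = max(0, viol),
       updates = updates)
}

#' Fit an SVM+ (LUPI) classifier
#'
#' Builds `H` from the augmented Gaussian kernel of the regular features
#' (`H = (K + 1) * y y'`), the privileged correction `G` from the
#' privileged kernel, and solves the one-class dual of `Q = H + G` for
#' the coefficients `alpha`. Privileged features are used only here, at
#' training time; prediction needs the regular features alone.
#'
#' @param X Regular-space feature matrix (`n x d`).
#' @param Xstar Privileged feature matrix (`n x d*`), row-aligned with
#'   `X`.
#' @param y Labels in `{-1, +1}`; both classes must be present.
#' @param hp An [svmplus_hyperparams].
#' @param privileged_kernel `"gaussian"` (default) or `"linear"`.
#' @return An object of class `svmplus_model`.
#' @export
fit_svmplus <- function(X, Xstar, y, hp = svmplus_hyperparams(),
                        privileged_kernel = c("gaussian", "linear")) {
  privileged_kernel <- match.arg(privileged_kernel)
  X <- as.matrix(X); Xstar <- as.matrix(Xstar)
  y <- as.numeric(y)
  if (nrow(X) != nrow(Xstar) || nrow(X) != length(y)) {
    stop("X, Xstar and y must be row-aligned", call. = FALSE)
  }
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2) {
    stop("y must contain both classes coded as -1/+1", call. = FALSE)
  }
  rscale <- hp$regular_scale %||% sqrt(ncol(X))
  pscale <- hp$privileged_scale %||% sqrt(max(1, ncol(Xstar)))
  rcfg <- kernel_config(rscale, "gaussian", augmented = TRUE)
  K <- gaussian_kernel_matrix(X, X, rcfg)
  H <- K * tcrossprod(y)
  pcfg <- kernel_config(pscale, privileged_kernel,
                        augmented = privileged_kernel == "gaussian")
  Kstar <- gaussian_kernel_matrix(Xstar, Xstar, pcfg)
  G <- build_correction_matrix(Kstar = Kstar, gamma = hp$gamma, C = hp$C)
  sol <- solve_svmplus_dual(H + G, hp$nu)
  structure(list(alpha = sol$alpha, y = y, X = X, hp = hp,
                 regular_cfg = rcfg, dual = sol),
            class = "svmplus_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decision scores of a fitted model
#'
#' For SVM+ the decision function is `f(x) = sum_i alpha_i y_i
#' (K(x_i, x) + 1)` with the bias absorbed in the augmented kernel; for
#' the baseline SVM it is `f(x) = sum_i alpha_i y_i K(x_i, x) + b`.
#' Raw scores are returned; the class prediction is `+1` when the score
#' is strictly positive.
#'
#' @param model An `svmplus_model` or `svm_baseline_model`.
#' @param Xtest Feature matrix of test points (one per row).
#' @return Numeric vector of raw decision scores.
#' @export
decision_scores <- function(model, Xtest) {
  UseMethod("decision_scores")
}

#' @export
decision_scores.svmplus_model <- function(model, Xtest) {
  K <- gaussian_kernel_matrix(model$X, as.matrix(Xtest), model$regular_cfg)
  as.numeric(crossprod(K, model$alpha * model$y))
}

#' @export
decision_scores.svm_baseline_model <- function(model, Xtest) {
  K <- gaussian_kernel_matrix(model$X, as.matrix(Xtest), model$cfg)
  as.numeric(crossprod(K, model$alpha * model$y)) + model$b
}

#' Fit the soft-margin Gaussian-kernel SVM baseline
#'
#' Standard hinge-loss SVM: the dual
#' `min 0.5 t(a) (K * yy') a - sum(a)` subject to `0 <= a <= C` and
#' `sum(a * y) = 0` is solved by a deterministic maximal-violating-pair
#' SMO; the bias is recovered from the free support vectors.
#'
#' @param X Feature matrix (`n x d`).
#' @param y Labels in `{-1, +1}`, both classes present.
#' @param C Positive box constraint.
#' @param scale Gaussian kernel scale (`NULL` = `sqrt(d)`).
#' @param tol KKT stopping threshold.
#' @param max_updates Cap on pairwise updates.
#' @return An object of class `svm_baseline_model`.
#' @export
fit_svm_baseline <- function(X, y, C = 1, scale = NULL, tol = 1e-8,
                             max_updates = 200000L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1)) || length(unique(y)) < 2) {
    stop("y must contain both classes coded as -1/+1", call. = FALSE)
  }
  stopifnot(C > 0)
  n <- nrow(X)
  cfg <- kernel_config(scale %||% sqrt(ncol(X)), "gaussian",
                       augmented = FALSE)
  K <- gaussian_kernel_matrix(X, X, cfg)
  Q <- K * tcrossprod(y)
  alpha <- rep(0, n)
  grad <- rep(-1, n) # Q %*% alpha - 1
  eps <- 1e-12 * max(1, C)
  updates <- 0L
  repeat {
    gy <- -y * grad
    i_up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    i_lo <- (y < 0 & alpha < C - eps) | (y > 0 & alpha > eps)
    if (!any(i_up) || !any(i_lo)) break
    m_up <- max(gy[i_up]); m_lo <- min(gy[i_lo])
    if (m_up - m_lo <= tol || updates >= max_updates) break
    i <- which(i_up)[which.max(gy[i_up])]
    j <- which(i_lo)[which.min(gy[i_lo])]
    curv <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_opt <- if (curv > 1e-12) (m_up - m_lo) / curv else Inf
    # alpha_i moves by +y_i t, alpha_j by -y_j t within [0, C]
    t_max_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    t_max_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    t_step <- min(t_opt, t_max_i, t_max_j)
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    grad <- grad + t_step * (y[i] * Q[, i] - y[j] * Q[, j])
    updates <- updates + 1L
  }
  gy <- -y * grad
  free <- alpha > eps & alpha < C - eps
  b <- if (any(free)) {
    mean(gy[free])
  } else {
    i_up <- (y > 0 & alpha < C - eps) | (y < 0 & alpha > eps)
    i_lo <- (y < 0 & alpha < C - eps) | (y > 0 & alpha > eps)
    (max(gy[i_up]) + min(gy[i_lo])) / 2
  }
  structure(list(alpha = alpha, y = y, X = X, b = b, C = C, cfg = cfg,
                 objective = 0.5 * sum(alpha * (Q %*% alpha)) - sum(alpha),
                 updates = updates),
            class = "svm_baseline_model")
}
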