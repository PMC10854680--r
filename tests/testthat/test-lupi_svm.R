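test_that("Gaussian kernel has unit diagonal, decays, and is PSD", {
  set.seed(81)
  X <- matrix(rnorm(10), 5, 2)
  cfg <- kernel_config(scale = 1.5, augmented = FALSE)
  K <- gaussian_kernel_matrix(X, X, cfg)
  expect_equal(diag(K), rep(1, 5))
  expect_true(all(K > 0 & K <= 1))
  expect_equal(K, t(K))
  Ka <- gaussian_kernel_matrix(X, X, kernel_config(1.5))
  expect_equal(diag(Ka), rep(2, 5)) # augmentation adds 1
  far <- gaussian_kernel_matrix(matrix(0, 1, 2), matrix(1e6, 1, 2), cfg)
  expect_lt(far[1, 1], 1e-12)
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-10)
  expect_error(gaussian_kernel_matrix(X, matrix(0, 2, 3), cfg),
               "dimensions")
})

test_that("correction matrix satisfies the push-through identity", {
  set.seed(82)
  P <- matrix(rnorm(18), 6, 3) # rows are privileged vectors z*_i
  gamma <- 1; C <- 2
  Pd <- t(P) # columns are z*_i, the explicit-P orientation
  G_explicit <- t(Pd) %*% solve(gamma * diag(3) + C * Pd %*% t(Pd)) %*% Pd
  G_kern <- build_correction_matrix(Pstar = P, gamma = gamma, C = C)
  expect_lt(max(abs(G_explicit - G_kern)), 1e-10)

  expect_equal(build_correction_matrix(Kstar = diag(5), gamma = 1, C = 1),
               diag(5) / 2)

  G_far <- build_correction_matrix(Pstar = P, gamma = 1e12, C = 1)
  expect_lt(norm(G_far, "F"), 1e-6)

  ev <- eigen(G_kern, symmetric = TRUE)$values
  expect_gte(min(ev), -1e-8)
})

test_that("one-class dual solver handles the symmetric and saturated cases", {
  s <- solve_svmplus_dual(diag(4), nu = 0.5)
  expect_equal(s$alpha, rep(0.5, 4))
  s1 <- solve_svmplus_dual(diag(4), nu = 1)
  expect_equal(s1$alpha, rep(1, 4))
  expect_error(solve_svmplus_dual(diag(3), nu = 1.5), "nu")
  expect_error(solve_svmplus_dual(matrix(c(1, 2, 0, 1), 2), 0.5),
               "symmetric")
})

test_that("one-class dual matches the generic QP oracle on random problems", {
  set.seed(83)
  for (k in 1:8) {
    n <- sample(6:20, 1)
    Q <- rand_psd(n)
    nu <- sample(c(0.3, 0.5, 0.8), 1)
    sol <- solve_svmplus_dual(Q, nu)
    expect_lte(abs(sum(sol$alpha) - nu * n), 1e-6)
    expect_true(all(sol$alpha >= -1e-9 & sol$alpha <= 1 + 1e-9))
    oracle <- oneclass_qp_oracle(Q, nu)
    expect_lte(abs(sol$objective - oracle$objective),
               1e-6 * max(1, oracle$objective))
  }
})

test_that("SVM+ fits separable data and reduces to H-only without PI", {
  X <- rbind(c(0, 0), c(0, 1), c(3, 3), c(3, 4))
  y <- c(-1, -1, 1, 1)
  hp <- svmplus_hyperparams(C = 100, gamma = 1, nu = 0.5,
                            regular_scale = 1)
  m <- fit_svmplus(X, X, y, hp)
  expect_equal(sign(decision_scores(m, X)), y)

  # all-zero privileged features with a linear kernel: G = 0 exactly
  set.seed(84)
  Xr <- matrix(rnorm(40), 20)
  yr <- rep(c(-1, 1), 10)
  hp2 <- svmplus_hyperparams(C = 2, regular_scale = 2)
  mz <- fit_svmplus(Xr, matrix(0, 20, 3), yr, hp2,
                    privileged_kernel = "linear")
  K <- gaussian_kernel_matrix(Xr, Xr, kernel_config(2))
  s0 <- solve_svmplus_dual(K * tcrossprod(yr), 0.5)
  expect_equal(mz$alpha, s0$alpha)

  expect_error(fit_svmplus(Xr, Xr, rep(1, 20), hp2), "both classes")
})

test_that("SVM+ dual objective matches the QP oracle on a synthetic task", {
  set.seed(85)
  n <- 20
  X <- matrix(rnorm(n * 4), n)
  Xstar <- matrix(rnorm(n * 3), n)
  y <- rep(c(-1, 1), n / 2)
  hp <- svmplus_hyperparams(C = 3, gamma = 0.7, nu = 0.5,
                            regular_scale = 2, privileged_scale = 1.5)
  m <- fit_svmplus(X, Xstar, y, hp)
  K <- gaussian_kernel_matrix(X, X, kernel_config(2))
  Kstar <- gaussian_kernel_matrix(Xstar, Xstar, kernel_config(1.5))
  Q <- K * tcrossprod(y) +
    build_correction_matrix(Kstar = Kstar, gamma = 0.7, C = 3)
  oracle <- oneclass_qp_oracle(Q, 0.5)
  expect_lte(abs(m$dual$objective - oracle$objective),
             1e-6 * max(1, oracle$objective))
})

test_that("decision scores equal naive double-loop evaluation", {
  set.seed(86)
  n <- 20
  X <- matrix(rnorm(n * 3), n)
  y <- rep(c(-1, 1), n / 2)
  m <- fit_svmplus(X, X + rnorm(n * 3, sd = 0.1), y,
                   svmplus_hyperparams(regular_scale = 1.7))
  Xtest <- matrix(rnorm(15), 5, 3)
  naive <- vapply(seq_len(5), function(j) {
    s <- 0
    for (i in seq_len(n)) {
      k <- exp(-sum((X[i, ] - Xtest[j, ])^2) / 1.7^2) + 1
      s <- s + m$alpha[i] * y[i] * k
    }
    s
  }, numeric(1))
  expect_equal(decision_scores(m, Xtest), naive, tolerance = 1e-10)

  # positive rescaling of alpha preserves the score ranking
  m2 <- m
  m2$alpha <- m$alpha * 7
  expect_equal(order(decision_scores(m2, Xtest)),
               order(decision_scores(m, Xtest)))
})

test_that("baseline SVM solves the hinge dual to oracle accuracy", {
  X <- rbind(c(0, 0), c(1, 0), c(4, 4), c(5, 4))
  y <- c(-1, -1, 1, 1)
  m <- fit_svm_baseline(X, y, C = 100, scale = 2)
  expect_equal(sign(decision_scores(m, X)), y)

  set.seed(87)
  for (k in 1:6) {
    n <- 15
    Xr <- matrix(rnorm(n * 3), n)
    yr <- c(rep(-1, 7), rep(1, 8))
    C <- sample(c(0.5, 2, 20), 1)
    mr <- fit_svm_baseline(Xr, yr, C = C, scale = 1.5)
    K <- gaussian_kernel_matrix(Xr, Xr,
                                kernel_config(1.5, augmented = FALSE))
    oracle <- csvm_qp_oracle(K, yr, C)
    expect_lte(abs(mr$objective - oracle$objective),
               1e-6 * max(1, abs(oracle$objective)))
    expect_lte(abs(sum(mr$alpha * yr)), 1e-9)
    expect_true(all(mr$alpha >= -1e-9 & mr$alpha <= C + 1e-9))
  }

  # C -> 0+ saturates every dual at the box bound on balanced data
  yb <- rep(c(-1, 1), 8)
  Xb <- matrix(rnorm(32), 16)
  m0 <- fit_svm_baseline(Xb, yb, C = 1e-6, scale = 1)
  expect_equal(m0$alpha, rep(1e-6, 16), tolerance = 1e-3)
})

test_that("baseline predictions track an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(88)
  n <- 60
  X <- matrix(rnorm(n * 2), n)
  y <- ifelse(X[, 1] + X[, 2] + rnorm(n, sd = 0.5) > 0, 1, -1)
  if (length(unique(y)) < 2) skip("degenerate draw")
  m <- fit_svm_baseline(X, y, C = 1, scale = sqrt(2))
  ref <- e1071::svm(X, factor(y), kernel = "radial", gamma = 1 / 2,
                    cost = 1, scale = FALSE)
  Xt <- matrix(rnorm(40), 20)
  agree <- mean(sign(decision_scores(m, Xt)) ==
                  as.numeric(as.character(predict(ref, Xt))))
  expect_gte(agree, 0.9)
})

test_that("the privileged correction vanishes as gamma grows", {
  set.seed(89)
  n <- 24
  X <- matrix(rnorm(n * 3), n)
  Xstar <- matrix(rnorm(n * 2), n)
  y <- rep(c(-1, 1), n / 2)
  Xt <- matrix(rnorm(30), 10, 3)
  hp_inf <- svmplus_hyperparams(C = 2, gamma = 1e12, regular_scale = 2)
  m_inf <- fit_svmplus(X, Xstar, y, hp_inf)
  K <- gaussian_kernel_matrix(X, X, kernel_config(2))
  s0 <- solve_svmplus_dual(K * tcrossprod(y), 0.5)
  m0 <- m_inf
  m0$alpha <- s0$alpha
  rho <- cor(decision_scores(m_inf, Xt), decision_scores(m0, Xt),
             method = "spearman")
  expect_gte(rho, 0.999)
})

test_that("privileged denoised labels do not hurt test AUROC on average", {
  # directional sanity of LUPI: privileged features are a clean copy of
  # the label signal, regular features a noisy one
  set.seed(90)
  deltas <- replicate(30, {
    n <- 40
    truth <- rep(c(-1, 1), n / 2)
    X <- matrix(rnorm(n * 6, sd = 1.2), n) + truth %o% rep(0.5, 6)
    Xstar <- cbind(truth, truth) + matrix(rnorm(n * 2, sd = 0.05), n)
    Xt <- matrix(rnorm(n * 6, sd = 1.2), n) + truth %o% rep(0.5, 6)
    hp <- svmplus_hyperparams(C = 1, gamma = 1, regular_scale = sqrt(6))
    mp <- fit_svmplus(X, Xstar, truth, hp)
    mb <- solve_svmplus_dual(
      gaussian_kernel_matrix(X, X, kernel_config(sqrt(6))) *
        tcrossprod(truth), 0.5)
    m0 <- mp
    m0$alpha <- mb$alpha
    a_plus <- compute_metrics(decision_scores(mp, Xt), truth)["auroc"]
    a_base <- compute_metrics(decision_scores(m0, Xt), truth)["auroc"]
    a_plus - a_base
  })
  expect_gte(mean(deltas), -0.01)
})
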