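# Independent brute-force oracles used to verify the fast implementations.

# Projected SOR on the box QP: min sum (g[i+1]-g[i])^2 s.t. |g - f| <= eps.
# Deliberately a different algorithm (iterative QP) from the geometric
# funnel solver it checks.
qp_taut_oracle <- function(f, eps, omega = 1.85, tol = 5e-14,
                           maxit = 60000) {
  n <- length(f)
  lo <- f - eps
  hi <- f + eps
  g <- pmin(pmax(rep(mean(f), n), lo), hi)
  for (it in seq_len(maxit)) {
    gold <- g
    for (i in seq_len(n)) {
      t <- if (i == 1) g[2] else if (i == n) g[n - 1] else (g[i - 1] + g[i + 1]) / 2
      g[i] <- min(max(g[i] + omega * (t - g[i]), lo[i]), hi[i])
    }
    if (max(abs(g - gold)) < tol) break
  }
  g
}

ts_objective <- function(g) sum(diff(g)^2)

# generic QP oracle for the one-class dual:
# min 0.5 a'Qa  s.t. sum(a) = nu*n, 0 <= a <= 1
oneclass_qp_oracle <- function(Q, nu) {
  n <- nrow(Q)
  ip <- kernlab::ipop(c = rep(0, n), H = Q, A = matrix(1, 1, n),
                      b = nu * n, r = 0, l = rep(0, n), u = rep(1, n),
                      sigf = 12, maxiter = 300)
  a <- kernlab::primal(ip)
  list(alpha = a, objective = 0.5 * sum(a * (Q %*% a)))
}

# generic QP oracle for the C-SVM dual:
# min 0.5 a'(K*yy')a - sum(a)  s.t. y'a = 0, 0 <= a <= C
csvm_qp_oracle <- function(K, y, C) {
  n <- nrow(K)
  Q <- K * tcrossprod(y)
  ip <- kernlab::ipop(c = rep(-1, n), H = Q, A = matrix(y, 1, n),
                      b = 0, r = 0, l = rep(0, n), u = rep(C, n),
                      sigf = 12, maxiter = 300)
  a <- kernlab::primal(ip)
  list(alpha = a, objective = 0.5 * sum(a * (Q %*% a)) - sum(a))
}

rand_psd <- function(n, jitter = 0.01) {
  M <- matrix(rnorm(n * n), n)
  crossprod(M) / n + diag(n) * jitter
}

random_test_signal <- function(n) {
  switch(sample(1:3, 1),
         cumsum(rnorm(n, sd = 0.3)),
         rnorm(n),
         sin(seq(0, sample(1:6, 1) * pi, length.out = n)) +
           rnorm(n, sd = 0.2))
}
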