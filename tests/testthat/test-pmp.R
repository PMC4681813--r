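test_that("normalized Gaussian bases form a partition of unity with the block layout", {
  basis <- pmp_basis(20L)
  bm <- basis_matrix(50L, basis)
  expect_equal(rowSums(bm$Phi), rep(1, 50))
  expect_identical(dim(bm$Psi), c(100L, 40L))
  # block structure: y block zero in x rows and vice versa
  expect_true(all(bm$Psi[1:50, 21:40] == 0))
  expect_true(all(bm$Psi[51:100, 1:20] == 0))

  # narrow bases: the feature at a centre dominates
  nb <- pmp_basis(5L, h = (1 / 4) / 10)
  Phi <- basis_matrix(5L, nb)$Phi   # phases coincide with the 5 centres
  expect_true(all(diag(Phi) > 0.99))
  expect_error(pmp_basis(5L, h = 0), "domain error")
})

test_that("weight fitting recovers exact and constant trajectories and matches the pseudoinverse oracle", {
  basis <- pmp_basis(8L)
  T <- 40L
  bm <- basis_matrix(T, basis)
  set.seed(3)
  w_true <- rnorm(16)
  tau <- drop(bm$Psi %*% w_true)
  traj <- trajectory(seq_len(T), tau[1:T], tau[T + 1:T])
  expect_equal(fit_weights(traj, basis), w_true, tolerance = 1e-5)

  # partition of unity reproduces constants exactly
  const <- trajectory(seq_len(T), rep(2.5, T), rep(2.5, T))
  w_c <- fit_weights(const, basis)
  recon <- drop(bm$Psi %*% w_c)
  expect_equal(recon, rep(2.5, 2 * T), tolerance = 1e-6)

  # noisy data: residual no worse than the normal-equations pseudoinverse
  noisy <- trajectory(seq_len(T), tau[1:T] + rnorm(T, 0, 0.3),
                      tau[T + 1:T] + rnorm(T, 0, 0.3))
  w_n <- fit_weights(noisy, basis)
  res_pkg <- sum((drop(bm$Psi %*% w_n) - c(noisy$x, noisy$y))^2)
  w_or <- c(drop(MASS::ginv(bm$Phi) %*% noisy$x),
            drop(MASS::ginv(bm$Phi) %*% noisy$y))
  res_or <- sum((drop(bm$Psi %*% w_or) - c(noisy$x, noisy$y))^2)
  expect_lte(res_pkg, res_or + 1e-8)
})

test_that("Normal-inverse-Wishart updates match the closed-form formulas", {
  prior <- niw_prior(c(0, 0), kappa0 = 0.1, nu0 = 10, Psi0 = diag(2))

  # empty update returns the prior unchanged
  expect_identical(niw_posterior(NULL, prior), prior)
  expect_identical(niw_posterior(matrix(numeric(0), 0, 2), prior), prior)

  # three observations in d = 2, verified against a hand evaluation
  W <- rbind(c(1, 2), c(3, 0), c(2, 4))
  post <- niw_posterior(W, prior)
  xbar <- c(2, 2)
  expect_equal(post$mu, (0.1 * c(0, 0) + 3 * xbar) / 3.1)
  expect_equal(post$kappa, 3.1)
  expect_equal(post$nu, 13)
  scatter <- rbind(c(2, -2), c(-2, 8))   # sum of centred outer products
  psi_hand <- diag(2) + scatter + (0.1 * 3 / 3.1) * (xbar %o% xbar)
  expect_equal(post$Psi, psi_hand)

  # kappa0 -> 0: the location update washes out the prior mean
  tiny <- niw_prior(c(100, 100), kappa0 = 1e-12, nu0 = 10, Psi0 = diag(2))
  expect_equal(niw_posterior(W, tiny)$mu, xbar, tolerance = 1e-9)

  expect_error(niw_posterior(cbind(1:3), prior), "dimension")
})

test_that("MAP estimate is Psi/nu, symmetric, and shrinks with repeated identical data", {
  prior <- niw_prior(rep(0, 3), 0.1, 10, 10 * diag(3))
  st <- prior; st$Psi <- st$nu * diag(3)
  est <- map_estimate(st)
  expect_equal(est$Sigma_omega, diag(3))

  W <- matrix(rep(c(1, 2, 3), 6), nrow = 6, byrow = TRUE)  # identical rows
  post <- niw_posterior(W, prior)
  est2 <- map_estimate(post)
  expect_equal(est2$Sigma_omega, t(est2$Sigma_omega))
  # zero scatter: Sigma dominated by the prior scale plus the mean-shift
  # term, shrinking as 1/nu
  dev <- c(1, 2, 3)
  expected <- (10 * diag(3) + (0.1 * 6 / 6.1) * (dev %o% dev)) / 16
  expect_equal(est2$Sigma_omega, expected, tolerance = 1e-12)
})

test_that("lemma-based predictive entropy matches the dense-matrix oracle", {
  for (cfg in list(c(T = 5L, n = 2L), c(T = 12L, n = 3L), c(T = 20L, n = 4L))) {
    T <- cfg[["T"]]; n <- cfg[["n"]]
    set.seed(T + n)
    basis <- pmp_basis(n, h = 1 / (n - 1))
    A <- matrix(rnorm((2 * n)^2), 2 * n)
    Sigma <- crossprod(A) / (2 * n) + 0.05 * diag(2 * n)
    Psi <- basis_matrix(T, basis)$Psi
    dense <- function(s) {
      S <- Psi %*% Sigma %*% t(Psi) + diag(s, 2 * T)
      ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
      0.5 * (2 * T * log(2 * pi * exp(1)) + ld)
    }
    model <- list(basis = basis, T = T, sigma_tau = 1e-4,
                  mu_omega = rnorm(2 * n), Sigma_omega = Sigma)
    # well-conditioned noise floor: dense LU and the lemma agree to 1e-8
    expect_equal(pmp_complexity(model, T), dense(1e-4), tolerance = 1e-8)
    # the default near-singular floor: agreement to the precision the dense
    # factorization itself can deliver
    model$sigma_tau <- 1e-10
    expect_equal(pmp_complexity(model, T), dense(1e-10), tolerance = 1e-6)
  }
})

test_that("predictive entropy is near the noise floor for a collapsed weight distribution and increases with scale", {
  T <- 10L
  basis <- pmp_basis(4L)
  model <- list(basis = basis, T = T, sigma_tau = 1e-10,
                mu_omega = rep(0, 8), Sigma_omega = diag(1e-16, 8))
  floor_ent <- 0.5 * 2 * T * log(2 * pi * exp(1) * 1e-10)
  expect_equal(pmp_complexity(model, T), floor_ent, tolerance = 1e-3)

  model2 <- model; model2$Sigma_omega <- diag(0.5, 8)
  model3 <- model; model3$Sigma_omega <- diag(1.5, 8)
  expect_gt(pmp_complexity(model3, T), pmp_complexity(model2, T))
})

test_that("sampling is reproducible, respects a collapsed distribution, and has the right mean", {
  p <- make_ellipse_pattern(n_rep = 5L, T = 30L, seed = 8L)
  fit <- fit_pmp(p, pmp_basis(8L), T = 30L)

  s1 <- simulate(fit, nsim = 3, seed = 42)
  s2 <- simulate(fit, nsim = 3, seed = 42)
  expect_identical(s1, s2)

  collapsed <- fit
  collapsed$Sigma_omega <- diag(1e-18, length(fit$mu_omega))
  mean_tau <- fitted(fit)
  draws <- simulate(collapsed, nsim = 4, seed = 1)
  for (d in draws) {
    expect_equal(d$x, mean_tau$x, tolerance = 1e-4)
  }

  big <- simulate(fit, nsim = 2000, seed = 5)
  emp_x <- rowMeans(vapply(big, `[[`, numeric(30), "x"))
  mc_sd <- max(sqrt(diag(fit$Sigma_omega))) # loose Monte-Carlo scale
  expect_lt(max(abs(emp_x - mean_tau$x)), 4 * mc_sd / sqrt(2000) * 10 + 0.05)
})

test_that("MAP entropy error shrinks as more repetitions are observed", {
  basis <- pmp_basis(6L)
  d <- 12L
  T <- 30L
  set.seed(100)
  A <- matrix(rnorm(d * d), d)
  Sigma_true <- crossprod(A) / d + 0.1 * diag(d)
  mu_true <- rnorm(d, 0, 2)
  gen <- list(basis = basis, T = T, sigma_tau = 1e-10,
              mu_omega = mu_true, Sigma_omega = Sigma_true)
  true_ent <- pmp_complexity(gen, T)
  prior <- niw_prior(rep(0, d), 0.1, 10, 10 * diag(d))
  err_for_N <- function(N, seed) {
    set.seed(seed)
    W <- t(mu_true + t(chol(Sigma_true)) %*% matrix(rnorm(d * N), d))
    est <- map_estimate(niw_posterior(W, prior))
    mod <- gen; mod$mu_omega <- est$mu_omega; mod$Sigma_omega <- est$Sigma_omega
    abs(pmp_complexity(mod, T) - true_ent)
  }
  meds <- vapply(c(5L, 10L, 50L), function(N) {
    stats::median(vapply(1:20, function(s) err_for_N(N, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meds) < 0))
})
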