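#' Normalized Gaussian basis configuration
#'
#' Defines the feature space of the probabilistic movement primitive: `n`
#' Gaussian bumps of width `h` on the phase interval `[0, 1]`, normalized so
#' that the features sum to one at every phase. The phase map is linear in
#' time, `z(1) = 0`, `z(T) = 1`.
#'
#' @param n Number of basis functions per dimension (default 20, so the
#'   stacked weight vector has 2n = 40 components).
#' @param h Basis width in phase units; default `1/(n - 1)`, giving adjacent
#'   bases an overlap of about `exp(-1/2)`.
#' @param centers Basis centres in `[0, 1]`, strictly increasing; default
#'   equally spaced.
#' @return An object of class `pmp_basis`.
#' @export
pmp_basis <- function(n = 20L, h = 1 / (n - 1),
                      centers = seq(0, 1, length.out = n)) {
  n <- as.integer(n)
  if (n < 2L) stop("invalid input: need at least 2 basis functions", call. = FALSE)
  if (h <= 0) stop("domain error: basis width h must be > 0", call. = FALSE)
  if (length(centers) != n || any(diff(centers) <= 0)) {
    stop("invalid input: centers must be n strictly increasing values", call. = FALSE)
  }
  structure(list(n = n, h = h, centers = centers), class = "pmp_basis")
}

#' Basis feature matrices
#'
#' Evaluates the normalized features at `T` equidistant phases: `Phi` is
#' `T x n` with rows summing to one, and `Psi` the `2T x 2n` block-diagonal
#' layout (x block, then y block) used for full 2-D trajectories.
#'
#' @param T Number of time samples.
#' @param basis A [pmp_basis()].
#' @return List with matrices `Phi` (`T x n`) and `Psi` (`2T x 2n`).
#' @export
basis_matrix <- function(T, basis = pmp_basis()) {
  stopifnot(inherits(basis, "pmp_basis"))
  z <- seq(0, 1, length.out = T)
  B <- exp(-outer(z, basis$centers, "-")^2 / (2 * basis$h^2))
  Phi <- B / rowSums(B)
  n <- basis$n
  Psi <- matrix(0, 2 * T, 2 * n)
  Psi[seq_len(T), seq_len(n)] <- Phi
  Psi[T + seq_len(T), n + seq_len(n)] <- Phi
  list(Phi = Phi, Psi = Psi)
}

#' Per-trajectory weight vector
#'
#' Ridge-regularized least squares of the trajectory on the normalized basis,
#' each dimension solved independently; the tiny penalty (1e-8) only guards
#' rank deficiency, so noiseless basis-generated trajectories are recovered
#' essentially exactly.
#'
#' @param traj A [trajectory()] resampled to the model's `T`.
#' @param basis A [pmp_basis()].
#' @param ridge Ridge penalty (default 1e-8).
#' @return Numeric weight vector of length `2n`, x weights first.
#' @export
fit_weights <- function(traj, basis = pmp_basis(), ridge = 1e-8) {
  stopifnot(inherits(traj, "trajectory"))
  T <- length(traj$t)
  Phi <- basis_matrix(T, basis)$Phi
  G <- crossprod(Phi) + diag(ridge, basis$n)
  R <- chol_jitter(G)
  solve1 <- function(v) backsolve(R, backsolve(R, crossprod(Phi, v),
                                               transpose = TRUE))
  c(solve1(traj$x), solve1(traj$y))
}

#' Normal-inverse-Wishart prior and posterior
#'
#' `niw_prior()` constructs a prior state; `niw_posterior()` applies the
#' conjugate update for `N` observed weight vectors:
#' \deqn{\mu = \frac{\kappa_0 \mu_0 + N \bar x}{\kappa_0 + N},\quad
#'   \kappa = \kappa_0 + N,\quad \nu = \nu_0 + N,}
#' \deqn{\Psi = \Psi_0 + \bar\Psi +
#'   \frac{\kappa_0 N}{\kappa_0 + N}(\bar x - \mu_0)(\bar x - \mu_0)^\top,}
#' where \eqn{\bar x} is the sample mean and \eqn{\bar\Psi} the sum of outer
#' products of the centred weight vectors.
#'
#' @param mu0 Prior location vector (length d).
#' @param kappa0 Prior strength (> 0; default 0.1).
#' @param nu0 Prior degrees of freedom (> 0; default 10).
#' @param Psi0 Prior scale matrix (d x d, symmetric positive definite).
#' @return An object of class `niw_state`.
#' @export
niw_prior <- function(mu0, kappa0 = 0.1, nu0 = 10.0, Psi0) {
  d <- length(mu0)
  if (kappa0 <= 0 || nu0 <= 0) {
    stop("invalid input: kappa0 and nu0 must be positive", call. = FALSE)
  }
  Psi0 <- as.matrix(Psi0)
  if (!all(dim(Psi0) == d)) {
    stop("invalid input: Psi0 dimension does not match mu0", call. = FALSE)
  }
  structure(list(mu = as.numeric(mu0), kappa = kappa0, nu = nu0,
                 Psi = (Psi0 + t(Psi0)) / 2,
                 xbar = NULL, scatter = NULL, N = 0L),
            class = "niw_state")
}

#' @rdname niw_prior
#' @param weights Matrix of observed weight vectors (rows = observations), a
#'   list of vectors, or `NULL`/zero rows for the empty update.
#' @param prior An `niw_state` as returned by [niw_prior()].
#' @export
niw_posterior <- function(weights, prior) {
  stopifnot(inherits(prior, "niw_state"))
  if (is.list(weights)) weights <- do.call(rbind, weights)
  if (is.null(weights) || NROW(weights) == 0L) return(prior)
  W <- as.matrix(weights)
  d <- length(prior$mu)
  if (ncol(W) != d) {
    stop(sprintf("invalid input: weight dimension %d does not match prior dimension %d",
                 ncol(W), d), call. = FALSE)
  }
  N <- nrow(W)
  xbar <- colMeans(W)
  C <- sweep(W, 2L, xbar)
  scatter <- crossprod(C)             # sum of outer products of centred rows
  k0 <- prior$kappa; n0 <- prior$nu
  dev <- xbar - prior$mu
  Psi <- prior$Psi + scatter + (k0 * N / (k0 + N)) * tcrossprod(dev)
  structure(list(mu = (k0 * prior$mu + N * xbar) / (k0 + N),
                 kappa = k0 + N, nu = n0 + N,
                 Psi = (Psi + t(Psi)) / 2,
                 xbar = xbar, scatter = scatter, N = N),
            class = "niw_state")
}

#' @export
print.niw_state <- function(x, ...) {
  cat(sprintf("<niw_state> d = %d, kappa = %.3g, nu = %.3g, N observed = %d\n",
              length(x$mu), x$kappa, x$nu, x$N))
  invisible(x)
}

#' Maximum-a-posteriori weight distribution
#'
#' The MAP estimate of the Gaussian over weights under a Normal-inverse-
#' Wishart state: `mu_omega = mu`, `Sigma_omega = Psi / nu`.
#'
#' @param state An `niw_state`.
#' @return List with `mu_omega` (length d) and `Sigma_omega` (d x d).
#' @export
map_estimate <- function(state) {
  stopifnot(inherits(state, "niw_state"))
  Sigma <- state$Psi / state$nu
  Sigma <- (Sigma + t(Sigma)) / 2
  # positive definiteness check via Cholesky (errors with diagnostics)
  chol_jitter(Sigma)
  list(mu_omega = state$mu, Sigma_omega = Sigma)
}

#' Empirical-Bayes prior from a collection of patterns
#'
#' Pools the fitted weight vectors of every repetition of every pattern in
#' the collection. The prior location `mu0` is their grand mean; the prior
#' scale is `Psi0 = nu0` times the pooled *within-pattern* maximum-likelihood
#' covariance (each pattern's weights centred on its own mean before
#' pooling, lightly regularized). The inverse-Wishart component of the prior
#' governs the within-pattern weight covariance, so its empirical-Bayes
#' scale is the pooled within-pattern covariance; between-pattern mean
#' spread is carried by the Normal component (`mu0`, `kappa0`). The prior is
#' shared across all patterns being compared.
#'
#' @param patterns List of [motion_pattern()] objects.
#' @param basis A [pmp_basis()].
#' @param T Resampling length.
#' @param kappa0,nu0 Prior strength and degrees of freedom (defaults 0.1, 10).
#' @param reg Relative diagonal regularization of the pooled covariance
#'   (default 1e-6), keeping the scale matrix positive definite when few
#'   patterns are pooled.
#' @return An `niw_state` prior.
#' @export
pmp_prior <- function(patterns, basis = pmp_basis(), T = 150L,
                      kappa0 = 0.1, nu0 = 10.0, reg = 1e-6) {
  if (inherits(patterns, "motion_pattern")) patterns <- list(patterns)
  Ws <- lapply(patterns, function(p) {
    reps <- lapply(p$repetitions, resample_trajectory, T = T)
    t(vapply(reps, fit_weights, numeric(2 * basis$n), basis = basis))
  })
  W <- do.call(rbind, Ws)
  mu0 <- colMeans(W)
  # pooled within-pattern ML covariance: centre each pattern on its own mean
  S <- Reduce(`+`, lapply(Ws, function(w) {
    crossprod(sweep(w, 2L, colMeans(w)))
  })) / nrow(W)
  S <- S + diag(reg * mean(diag(S)) + 1e-12, ncol(W))
  niw_prior(mu0, kappa0, nu0, nu0 * S)
}

#' Fit a probabilistic movement primitive to a motion pattern
#'
#' Each repetition is resampled, projected onto the normalized Gaussian basis
#' ([fit_weights()]), and the weight vectors are combined with a
#' Normal-inverse-Wishart prior; the MAP mean and covariance of the weight
#' distribution define the primitive's Gaussian trajectory distribution
#' \eqn{N(\Psi \mu_\omega, \Psi \Sigma_\omega \Psi^\top + \Sigma_\tau)} with
#' trajectory noise \eqn{\Sigma_\tau = \sigma_\tau I} (default 1e-10,
#' negligible observation noise).
#'
#' @param pattern A [motion_pattern()].
#' @param basis A [pmp_basis()].
#' @param prior An `niw_state` prior, typically from [pmp_prior()] over the
#'   whole pattern collection; `NULL` builds a prior from this pattern alone.
#' @param T Resampling length (default 150).
#' @param sigma_tau Trajectory noise variance (default 1e-10).
#' @return An object of class `pmp_fit` with `mu_omega`, `Sigma_omega`, the
#'   posterior `niw_state`, and entropy-based `complexity`. Methods:
#'   `print()`, `summary()`, `coef()`, `fitted()`, `residuals()`,
#'   `simulate()`.
#' @export
#' @examples
#' p <- generate_pattern("ellipse_low_var", seed = 1, T = 60)
#' fit <- fit_pmp(p, T = 60)
#' fit$complexity
fit_pmp <- function(pattern, basis = pmp_basis(), prior = NULL, T = 150L,
                    sigma_tau = 1e-10) {
  stopifnot(inherits(pattern, "motion_pattern"))
  if (is.null(prior)) prior <- pmp_prior(pattern, basis, T)
  reps <- lapply(pattern$repetitions, resample_trajectory, T = T)
  W <- t(vapply(reps, fit_weights, numeric(2 * basis$n), basis = basis))
  post <- niw_posterior(W, prior)
  est <- map_estimate(post)
  obj <- structure(list(
    subject = pattern$subject, trial = pattern$trial,
    basis = basis, T = as.integer(T), sigma_tau = sigma_tau,
    mu_omega = est$mu_omega, Sigma_omega = est$Sigma_omega,
    posterior = post, weights = W), class = "pmp_fit")
  obj$complexity <- pmp_complexity(obj)
  obj
}

#' Entropy of the primitive's predictive trajectory distribution
#'
#' Differential entropy (nats) of
#' \eqn{N(\Psi \mu_\omega, \Psi \Sigma_\omega \Psi^\top + \sigma_\tau I)},
#' computed with the matrix determinant lemma so that only a `2n x 2n`
#' determinant is formed:
#' \deqn{\log\det(\sigma_\tau I + \Psi \Sigma_\omega \Psi^\top) =
#'   2T \log \sigma_\tau + \log\det(I + L^\top \Psi^\top \Psi L / \sigma_\tau)}
#' with `L` a Cholesky factor of `Sigma_omega`.
#'
#' @param model A `pmp_fit`, or a list with elements `basis`, `mu_omega`,
#'   `Sigma_omega`, `sigma_tau`.
#' @param T Number of time samples of the predictive (default the model's).
#' @return Differential entropy in nats.
#' @export
pmp_complexity <- function(model, T = model$T) {
  Psi <- basis_matrix(T, model$basis)$Psi
  s <- model$sigma_tau
  d <- ncol(Psi)
  R <- chol_jitter(model$Sigma_omega)      # Sigma = R^T R, R upper
  Mt <- Psi %*% t(R)                       # 2T x d
  inner <- diag(d) + crossprod(Mt) / s
  logdet <- 2 * T * log(s) + 2 * sum(log(diag(chol_jitter(inner))))
  0.5 * (2 * T * log(2 * pi * exp(1)) + logdet)
}

#' @export
print.pmp_fit <- function(x, ...) {
  cat(sprintf("<pmp_fit> subject %s, trial %d: %d bases/dim, T = %d, N = %d repetitions\n",
              x$subject, x$trial, x$basis$n, x$T, nrow(x$weights)))
  cat(sprintf("  predictive entropy (complexity): %.2f nats\n", x$complexity))
  invisible(x)
}

#' @export
summary.pmp_fit <- function(object, ...) {
  ev <- eigen(object$Sigma_omega, symmetric = TRUE, only.values = TRUE)$values
  structure(list(n = object$basis$n, T = object$T,
                 N = nrow(object$weights),
                 complexity = object$complexity,
                 eig_range = range(ev),
                 posterior = object$posterior), class = "summary.pmp_fit")
}

#' @export
print.summary.pmp_fit <- function(x, ...) {
  cat(sprintf("PMP fit: %d bases/dim (weight dim %d), T = %d, N = %d\n",
              x$n, 2 * x$n, x$T, x$N))
  cat(sprintf("weight covariance eigenvalues in [%.3g, %.3g]\n",
              x$eig_range[1], x$eig_range[2]))
  cat(sprintf("predictive entropy: %.3f nats\n", x$complexity))
  invisible(x)
}

#' @export
coef.pmp_fit <- function(object, ...) object$mu_omega

#' @export
fitted.pmp_fit <- function(object, ...) {
  T <- object$T
  tau <- basis_matrix(T, object$basis)$Psi %*% object$mu_omega
  trajectory(seq_len(T), tau[seq_len(T)], tau[T + seq_len(T)])
}

#' @export
residuals.pmp_fit <- function(object, ...) {
  T <- object$T
  Psi <- basis_matrix(T, object$basis)$Psi
  recon <- Psi %*% t(object$weights)      # 2T x N reconstructions
  mean_tau <- as.vector(Psi %*% object$mu_omega)
  recon - mean_tau
}

#' Sample trajectories from a fitted primitive
#'
#' Draws weight vectors from `N(mu_omega, Sigma_omega)` and emits
#' `tau = Psi omega + eps` with `eps ~ N(0, sigma_tau I)`. Reproducible under
#' a fixed `seed`.
#'
#' @param object A `pmp_fit`.
#' @param nsim Number of trajectories (default 1).
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return List of [trajectory()] objects of length `nsim`.
#' @export
simulate.pmp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  T <- object$T
  Psi <- basis_matrix(T, object$basis)$Psi
  d <- length(object$mu_omega)
  R <- chol_jitter(object$Sigma_omega)
  Z <- matrix(stats::rnorm(d * nsim), d, nsim)
  W <- object$mu_omega + t(R) %*% Z
  Tau <- Psi %*% W +
    sqrt(object$sigma_tau) * matrix(stats::rnorm(2 * T * nsim), 2 * T, nsim)
  lapply(seq_len(nsim), function(j) {
    trajectory(seq_len(T), Tau[seq_len(T), j], Tau[T + seq_len(T), j])
  })
}

#' @rdname simulate.pmp_fit
#' @param model A `pmp_fit`.
#' @param m Number of trajectories.
#' @export
sample_trajectories <- function(model, m = 1, seed = NULL) {
  simulate.pmp_fit(model, nsim = m, seed = seed)
}
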