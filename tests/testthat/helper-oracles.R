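# Independent oracles used across the suite. These deliberately share no
# code with the package internals.

# LZ-76 parsing straight from the definition: a block grows while it can be
# reproduced from the preceding history (self-overlap allowed), then takes
# one innovative symbol; the final block counts whether or not it is novel.
r_lz76 <- function(s) {
  n <- nchar(s)
  if (n == 0L) return(0L)
  count <- 0L
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n &&
           grepl(substr(s, i, j), substr(s, 1L, j - 1L), fixed = TRUE)) {
      j <- j + 1L
    }
    count <- count + 1L
    i <- j + 1L
  }
  count
}

# Rasterization oracle: walk each segment in many tiny steps and emit a
# symbol whenever the occupied cell changes (x move emitted before y move
# when a micro-step changes both).
r_symbolize <- function(x, y, cell = 1, nx = 10L, ny = 10L, steps = 2000L) {
  cellix <- function(v, ncell) pmin(pmax(floor(v / cell), 0L), ncell - 1L)
  out <- character(0)
  for (i in seq_len(length(x) - 1L)) {
    tt <- seq(0, 1, length.out = steps)
    px <- x[i] + tt * (x[i + 1L] - x[i])
    py <- y[i] + tt * (y[i + 1L] - y[i])
    cx <- cellix(px, nx); cy <- cellix(py, ny)
    for (k in seq_len(steps - 1L)) {
      dx <- cx[k + 1L] - cx[k]; dy <- cy[k + 1L] - cy[k]
      if (dx > 0) out <- c(out, "r") else if (dx < 0) out <- c(out, "l")
      if (dy > 0) out <- c(out, "u") else if (dy < 0) out <- c(out, "d")
    }
  }
  paste(out, collapse = "")
}

# Dense zero-mean multivariate normal log-density, via determinant() and
# solve() rather than Cholesky backsolves.
r_mvn_logpdf <- function(y, Sigma) {
  M <- length(y)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (M * log(2 * pi) + ld + drop(t(y) %*% solve(Sigma, y)))
}

# A small deterministic test pattern: noisy ellipse repetitions.
make_ellipse_pattern <- function(n_rep = 4L, T = 40L, noise = 0.05,
                                 seed = 1L, subject = "s1", trial = 1L) {
  set.seed(seed)
  th <- seq(0, 2 * pi, length.out = T)
  reps <- lapply(seq_len(n_rep), function(i) {
    trajectory(seq_len(T),
               5 + 3 * cos(th) + rnorm(T, 0, noise),
               5 + 2 * sin(th) + rnorm(T, 0, noise))
  })
  motion_pattern(reps, subject, trial)
}
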