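# circular Gaussian smoothing of a vector, kernel sd in samples
smooth_circular <- function(v, sd_samples) {
  T <- length(v)
  if (sd_samples <= 0) return(v)
  half <- min(T %/% 2, ceiling(3 * sd_samples))
  k <- stats::dnorm(-half:half, sd = sd_samples)
  k <- k / sum(k)
  idx <- outer(seq_len(T), -half:half, function(i, j) ((i + j - 1) %% T) + 1)
  as.vector(matrix(v[idx], T) %*% k)
}

# smooth periodic noise with unit marginal sd
smooth_noise <- function(T, sd_samples) {
  z <- smooth_circular(stats::rnorm(T), sd_samples)
  s <- stats::sd(z)
  if (s == 0) return(z)
  z / s
}

# affine-scale a closed base curve (two columns x, y) into the box
# [margin, width - margin] x [margin, height - margin]
scale_to_box <- function(xy, ws, margin) {
  for (j in 1:2) {
    lim <- if (j == 1) ws$width else ws$height
    r <- range(xy[, j])
    span <- max(r[2] - r[1], 1e-12)
    xy[, j] <- margin + (xy[, j] - r[1]) / span * (lim - 2 * margin)
  }
  xy
}

#' Generate a synthetic motion pattern
#'
#' Produces a pattern of `n_rep` repeated trajectories with controllable
#' spatial complexity and across-repetition variability, emulating four
#' qualitative classes of drawing behaviour:
#' * `ellipse_low_var`, `ellipse_high_var`: a simple parametric ellipse base
#'   curve with small / large smooth repetition-to-repetition perturbations;
#' * `complex_low_var`: a closed curve with rich harmonic content (several
#'   random Fourier components) drawn very repeatably;
#' * `random_high_var`: no repeatable base curve at all; every repetition is
#'   an independent heavily low-pass-filtered Gaussian walk (closed by
#'   detrending) carrying rough white positional jitter of sd `jitter_sd`,
#'   so the movement has no repeatable or smooth fine structure;
#' * `graded`: an ellipse plus harmonics whose amplitude grows with
#'   `complexity_grade` (grade 0 = pure ellipse), for dose-response
#'   experiments.
#'
#' Repetition variability mimics imperfect memory of the intended movement
#' rather than sensor noise: each repetition re-draws the base curve at a
#' smoothly phase-jittered timing and adds a smooth spatial drift field, the
#' two calibrated to contribute `sigma_rep / sqrt(2)` cm of positional
#' standard deviation each (total approximately `sigma_rep`). Phase jitter
#' matters: for spatially complex curves a small timing error produces a
#' disproportionate excursion in feature space while leaving the positional
#' variance small. All generated points are clamped to the workspace.
#'
#' @param class One of `"random_high_var"`, `"complex_low_var"`,
#'   `"ellipse_high_var"`, `"ellipse_low_var"`, `"graded"`.
#' @param complexity_grade Non-negative real; harmonic amplitude for the
#'   `graded` class (ignored otherwise).
#' @param sigma_rep Repetition variability (cm); defaults: 0.08
#'   (`ellipse_low_var`), 0.12 (`complex_low_var`; intricate shapes are a
#'   little harder to repeat), 0.6 (`ellipse_high_var`), 0.3 (`graded`).
#'   The `random_high_var` class owes its variability to the independent
#'   walks themselves.
#' @param jitter_sd White positional jitter of the `random_high_var` class
#'   (cm, default 1).
#' @param drift_frac Correlation length of the smooth memory-drift field as a
#'   fraction of the repetition length (default 0.25, i.e. the drift varies
#'   over about a quarter of the pattern).
#' @param n_rep Number of repetitions (default 10).
#' @param T Samples per repetition (default 150).
#' @param seed Optional integer seed (reproducible patterns).
#' @param ws A [workspace()] (default 10 x 10 cm).
#' @param subject,trial Identifiers stored in the pattern.
#' @return A [motion_pattern()].
#' @export
#' @examples
#' p <- generate_pattern("complex_low_var", seed = 1)
#' pattern_variance(p)
generate_pattern <- function(class = c("ellipse_low_var", "ellipse_high_var",
                                       "complex_low_var", "random_high_var",
                                       "graded"),
                             complexity_grade = 1, sigma_rep = NULL,
                             jitter_sd = 1, drift_frac = 0.25,
                             n_rep = 10L, T = 150L,
                             seed = NULL, ws = workspace(),
                             subject = "sim", trial = 1L) {
  class <- match.arg(class)
  if (complexity_grade < 0) {
    stop("invalid input: complexity_grade must be >= 0", call. = FALSE)
  }
  if (n_rep < 2L) stop("invalid input: n_rep must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sigma_rep)) {
    sigma_rep <- switch(class,
                        ellipse_low_var = 0.08, complex_low_var = 0.12,
                        ellipse_high_var = 0.6, random_high_var = 0.6,
                        graded = 0.3)
  }
  if (sigma_rep < 0) stop("invalid input: sigma_rep must be >= 0", call. = FALSE)
  theta <- seq(0, 2 * pi, length.out = T)
  margin <- min(1.5, 0.5 + 2 * sigma_rep)
  perturb_sd_samples <- drift_frac * T

  harmonic_curve <- function(K, amp_decay = 0.7) {
    co <- function() {
      a <- stats::rnorm(K) / (seq_len(K)^amp_decay)
      b <- stats::rnorm(K) / (seq_len(K)^amp_decay)
      rowSums(sapply(seq_len(K), function(k) {
        a[k] * cos(k * theta) + b[k] * sin(k * theta)
      }))
    }
    cbind(co(), co())
  }

  base <- switch(class,
    ellipse_low_var = ,
    ellipse_high_var = cbind(3.5 * cos(theta), 2.2 * sin(theta)),
    complex_low_var = {
      # rich spatial frequency content: harmonics 1..8, no amplitude decay
      harmonic_curve(8, amp_decay = 0)
    },
    graded = {
      g <- complexity_grade
      h <- if (g > 0) harmonic_curve(6, amp_decay = 0.7) else 0
      cbind(cos(theta), sin(theta)) + g * 0.5 * h
    },
    random_high_var = NULL)

  reps <- vector("list", n_rep)
  if (class == "random_high_var") {
    for (r in seq_len(n_rep)) {
      walk <- function() {
        w <- cumsum(stats::rnorm(T))
        w <- w - seq(w[1], w[length(w)], length.out = T)  # close the curve
        smooth_circular(w, T / 15)       # only the large-scale drift survives
      }
      xy <- scale_to_box(cbind(walk(), walk()), ws, margin)
      x <- pmin(pmax(xy[, 1] + stats::rnorm(T, 0, jitter_sd), 0), ws$width)
      y <- pmin(pmax(xy[, 2] + stats::rnorm(T, 0, jitter_sd), 0), ws$height)
      reps[[r]] <- trajectory(seq_len(T), x, y)
    }
  } else {
    xy0 <- scale_to_box(base, ws, margin)
    # periodic interpolation of the closed base curve at jittered phases
    eval_base <- function(th) {
      th <- th %% (2 * pi)
      cbind(stats::approx(theta, xy0[, 1], xout = th)$y,
            stats::approx(theta, xy0[, 2], xout = th)$y)
    }
    # rms positional speed w.r.t. phase, for calibrating the timing jitter
    speed <- sqrt(mean(rowSums((xy0[-1, ] - xy0[-T, ])^2)) /
                    mean(diff(theta))^2)
    # timing jitter and spatial drift each carry half the variance budget:
    # sd(speed * dphase) = sigma_rep/sqrt(2); drift sd sigma_rep/2 per axis
    for (r in seq_len(n_rep)) {
      dphase <- (sigma_rep / sqrt(2) / max(speed, 1e-9)) *
        smooth_noise(T, perturb_sd_samples)
      xy <- eval_base(theta + dphase)
      px <- (sigma_rep / 2) * smooth_noise(T, perturb_sd_samples)
      py <- (sigma_rep / 2) * smooth_noise(T, perturb_sd_samples)
      x <- pmin(pmax(xy[, 1] + px, 0), ws$width)
      y <- pmin(pmax(xy[, 2] + py, 0), ws$height)
      reps[[r]] <- trajectory(seq_len(T), x, y)
    }
  }
  motion_pattern(reps, subject, trial)
}

#' Generate a whole synthetic experiment with known complexity grades
#'
#' Emits `n_subjects x n_trials` graded patterns; subject `s` draws every
#' trial at complexity grade `grade_assignment[s]`, so the ground truth for
#' recovery tests is returned alongside the data.
#'
#' @param n_subjects Number of simulated subjects (>= 2).
#' @param n_trials Trials per subject (default 55).
#' @param grade_assignment Numeric vector of per-subject complexity grades
#'   (recycled/defaulted to equally spaced grades in `[0, 2]`).
#' @param sigma_rep Repetition variability (cm, default 0.3).
#' @param T,n_rep Pattern dimensions (defaults 150, 10).
#' @param seed Optional integer seed.
#' @return List with `patterns` (list of [motion_pattern()], subjects
#'   `"s1"..."sK"`) and `grades` (named per-subject vector).
#' @export
generate_experiment <- function(n_subjects, n_trials = 55L,
                                grade_assignment = NULL, sigma_rep = 0.3,
                                T = 150L, n_rep = 10L, seed = NULL) {
  if (n_subjects < 2L) stop("invalid input: need at least 2 subjects", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grade_assignment)) {
    grade_assignment <- seq(0, 2, length.out = n_subjects)
  }
  grade_assignment <- rep_len(grade_assignment, n_subjects)
  names(grade_assignment) <- paste0("s", seq_len(n_subjects))
  patterns <- list()
  for (s in seq_len(n_subjects)) {
    for (tr in seq_len(n_trials)) {
      patterns[[length(patterns) + 1L]] <-
        generate_pattern("graded", complexity_grade = grade_assignment[s],
                         sigma_rep = sigma_rep, n_rep = n_rep, T = T,
                         subject = paste0("s", s), trial = tr)
    }
  }
  list(patterns = patterns, grades = grade_assignment)
}

#' Simulate a jury ranking patterns by noisy scores
#'
#' Within each trial every juror ranks the compared patterns by
#' `true_score + N(0, noise_sd)`; ranks run 1..m with m = patterns per trial
#' and m = most creative. Ties in the noisy scores break deterministically
#' toward the lower subject index (which receives the lower rank).
#'
#' @param true_scores Data frame with columns `trial`, `subject`, `score`;
#'   every trial must compare the same subjects (2..10 of them).
#' @param n_jurors Number of jurors (default 10).
#' @param noise_sd Standard deviation of juror noise, in score units
#'   (default 0 = noiseless).
#' @param seed Optional integer seed.
#' @return Data frame with columns `trial`, `subject`, `juror`, `rank`;
#'   aggregate with [average_ranks()].
#' @export
simulate_jury <- function(true_scores, n_jurors = 10L, noise_sd = 0,
                          seed = NULL) {
  need <- c("trial", "subject", "score")
  if (!all(need %in% names(true_scores))) {
    stop("invalid input: true_scores needs columns trial, subject, score",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  trials <- unique(true_scores$trial)
  m <- table(true_scores$trial)
  if (any(m < 2L)) {
    stop("invalid input: every trial must compare at least 2 patterns",
         call. = FALSE)
  }
  if (length(unique(m)) != 1L) {
    stop("invalid input: every trial must compare the same number of patterns",
         call. = FALSE)
  }
  if (m[1] > 10L) {
    stop("invalid input: jurors compare no more than 10 items per trial",
         call. = FALSE)
  }
  out <- vector("list", length(trials) * n_jurors)
  i <- 0L
  for (tr in trials) {
    d <- true_scores[true_scores$trial == tr, , drop = FALSE]
    d <- d[order(d$subject), , drop = FALSE]
    for (j in seq_len(n_jurors)) {
      noisy <- d$score + if (noise_sd > 0) stats::rnorm(nrow(d), 0, noise_sd) else 0
      # rank m = most creative; ties -> lower subject index gets lower rank
      rk <- rank(noisy, ties.method = "first")
      i <- i + 1L
      out[[i]] <- data.frame(trial = tr, subject = d$subject, juror = j,
                             rank = rk, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Average per-juror ranks into a rank table
#'
#' @param ranks Data frame with columns `trial`, `subject`, `rank` (and
#'   optionally `juror`); per-juror rows are averaged.
#' @return Data frame `trial`, `subject`, `avg_rank`.
#' @export
average_ranks <- function(ranks) {
  agg <- stats::aggregate(rank ~ trial + subject, data = ranks, FUN = mean)
  names(agg)[names(agg) == "rank"] <- "avg_rank"
  agg[order(agg$trial, agg$subject), , drop = FALSE]
}
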