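#' Construct a 2-D trajectory
#'
#' A trajectory is a time-ordered sequence of 2-D positions in centimetres.
#' Times must be strictly increasing; the units of time are arbitrary (after
#' [resample_trajectory()] they are equidistant indices).
#'
#' @param t Numeric vector of sample times, strictly increasing.
#' @param x,y Numeric vectors of horizontal / vertical positions (cm), same
#'   length as `t`.
#' @return An object of class `trajectory`: a list with elements `t`, `x`, `y`.
#' @export
#' @examples
#' tr <- trajectory(1:4, c(0, 1, 2, 3), c(0, 0, 1, 1))
#' length(tr$t)
trajectory <- function(t, x, y) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y)) {
    stop("invalid input: t, x, y must have equal length", call. = FALSE)
  }
  if (anyNA(t) || anyNA(x) || anyNA(y) || !all(is.finite(c(t, x, y)))) {
    stop("invalid input: non-finite values in trajectory", call. = FALSE)
  }
  if (length(t) >= 2L && any(diff(t) <= 0)) {
    stop("invalid input: times must be strictly increasing", call. = FALSE)
  }
  structure(list(t = t, x = x, y = y), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples, t in [%g, %g], x in [%.3g, %.3g] cm, y in [%.3g, %.3g] cm\n",
              length(x$t), min(x$t), max(x$t),
              min(x$x), max(x$x), min(x$y), max(x$y)))
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$t)

#' Construct a motion pattern
#'
#' A motion pattern is one trial's set of N repeated trajectories of a
#' self-chosen closed-form movement, together with subject and trial
#' identifiers. Repetitions need not share a common length until resampled.
#'
#' @param repetitions List of [trajectory()] objects, N >= 2.
#' @param subject Subject identifier (coerced to character).
#' @param trial Trial number (integer).
#' @return An object of class `motion_pattern`.
#' @export
motion_pattern <- function(repetitions, subject = "s1", trial = 1L) {
  if (!is.list(repetitions) || length(repetitions) < 2L) {
    stop("invalid input: a motion pattern needs at least 2 repetitions",
         call. = FALSE)
  }
  ok <- vapply(repetitions, inherits, logical(1), "trajectory")
  if (!all(ok)) stop("invalid input: repetitions must be trajectory objects",
                     call. = FALSE)
  structure(list(repetitions = repetitions,
                 subject = as.character(subject),
                 trial = as.integer(trial)),
            class = "motion_pattern")
}

#' @export
print.motion_pattern <- function(x, ...) {
  lens <- vapply(x$repetitions, function(r) length(r$t), integer(1))
  cat(sprintf("<motion_pattern> subject %s, trial %d, %d repetitions (%s samples each)\n",
              x$subject, x$trial, length(x$repetitions),
              if (length(unique(lens)) == 1L) as.character(lens[1]) else "varying"))
  invisible(x)
}

#' Define the drawing workspace
#'
#' The experimental workspace is a rectangle tessellated into square grid
#' cells for symbolic analysis. Width and height must be integer multiples of
#' the cell size.
#'
#' @param width,height Workspace extent in cm (default 10 x 10).
#' @param cell_size Grid cell edge in cm (default 1).
#' @return An object of class `workspace`.
#' @export
workspace <- function(width = 10, height = 10, cell_size = 1) {
  if (width <= 0 || height <= 0 || cell_size <= 0) {
    stop("invalid input: workspace dimensions must be positive", call. = FALSE)
  }
  nx <- width / cell_size; ny <- height / cell_size
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop("invalid input: width and height must be integer multiples of cell_size",
         call. = FALSE)
  }
  structure(list(width = width, height = height, cell_size = cell_size,
                 nx = as.integer(round(nx)), ny = as.integer(round(ny))),
            class = "workspace")
}

#' Resample a trajectory to equidistant time points
#'
#' Linear interpolation at `T` equidistant times spanning the original time
#' interval. Endpoints are preserved exactly; resampling is idempotent.
#'
#' @param traj A [trajectory()].
#' @param T Target number of samples (default 150).
#' @return A `trajectory` with exactly `T` equidistant samples.
#' @export
resample_trajectory <- function(traj, T = 150L) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$t) < 2L) {
    stop("invalid input: need at least 2 samples to resample", call. = FALSE)
  }
  if (T < 2L) stop("invalid input: T must be >= 2", call. = FALSE)
  tt <- seq(traj$t[1], traj$t[length(traj$t)], length.out = T)
  # guard the endpoints against seq() rounding so idempotence is exact
  tt[1] <- traj$t[1]; tt[T] <- traj$t[length(traj$t)]
  x <- stats::approx(traj$t, traj$x, xout = tt, rule = 2)$y
  y <- stats::approx(traj$t, traj$y, xout = tt, rule = 2)$y
  trajectory(tt, x, y)
}

#' Resample every repetition of a pattern
#'
#' Each repetition is independently resampled to `T` points over its own
#' duration (no time warping), so repetitions can be compared index-by-index.
#'
#' @param pattern A [motion_pattern()].
#' @param T Target number of samples per repetition.
#' @return A `motion_pattern` with all repetitions of length `T`.
#' @export
resample_pattern <- function(pattern, T = 150L) {
  stopifnot(inherits(pattern, "motion_pattern"))
  reps <- lapply(pattern$repetitions, resample_trajectory, T = T)
  motion_pattern(reps, pattern$subject, pattern$trial)
}

#' Across-repetition variance of a motion pattern
#'
#' At each time index the unbiased sample variance over the N repetitions is
#' computed for x and for y; the two are summed and the result averaged over
#' time indices. The measure is translation invariant and scales as c^2 under
#' uniform spatial scaling; units are cm^2.
#'
#' @param pattern A [motion_pattern()] whose repetitions share a common length
#'   (resample first if needed).
#' @return Non-negative scalar variance (cm^2).
#' @export
pattern_variance <- function(pattern) {
  stopifnot(inherits(pattern, "motion_pattern"))
  reps <- pattern$repetitions
  n <- length(reps)
  if (n < 2L) stop("invalid input: need at least 2 repetitions", call. = FALSE)
  lens <- vapply(reps, function(r) length(r$t), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("invalid input: repetitions must share a common length; resample first",
         call. = FALSE)
  }
  X <- vapply(reps, `[[`, numeric(lens[1]), "x")  # T x N
  Y <- vapply(reps, `[[`, numeric(lens[1]), "y")
  vx <- apply(X, 1L, stats::var)
  vy <- apply(Y, 1L, stats::var)
  mean(vx + vy)
}

#' Read motion patterns from a delimited text file
#'
#' The file format is comma-separated with header
#' `subject,trial,repetition,t,x,y`; one file may hold many patterns. Rows are
#' grouped by (subject, trial, repetition) and sorted by time, so shuffled
#' input is canonicalized.
#'
#' @param path Path to a CSV file.
#' @return A list of [motion_pattern()] objects, ordered by subject then trial.
#' @export
read_patterns <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "trial", "repetition", "t", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("format error: missing column(s) %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  for (col in c("t", "x", "y")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("format error: non-numeric value in column '%s' at data row %d",
                   col, bad[1]), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("format error: missing value in column '%s' at data row %d",
                   col, which(is.na(v))[1]), call. = FALSE)
    }
    df[[col]] <- v
  }
  key <- paste(df$subject, df$trial, df$repetition, df$t, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("format error: duplicate (subject, trial, repetition, t) key at data row %d",
                 which(duplicated(key))[1]), call. = FALSE)
  }
  df <- df[order(df$subject, df$trial, df$repetition, df$t), , drop = FALSE]
  out <- list()
  for (sb in unique(df$subject)) {
    dsb <- df[df$subject == sb, , drop = FALSE]
    for (tr in unique(dsb$trial)) {
      dtr <- dsb[dsb$trial == tr, , drop = FALSE]
      reps <- lapply(unique(dtr$repetition), function(rp) {
        dr <- dtr[dtr$repetition == rp, , drop = FALSE]
        if (nrow(dr) < 2L) {
          stop(sprintf("format error: repetition %s of subject %s trial %s has fewer than 2 samples",
                       rp, sb, tr), call. = FALSE)
        }
        trajectory(dr$t, dr$x, dr$y)
      })
      out[[length(out) + 1L]] <- motion_pattern(reps, sb, as.integer(tr))
    }
  }
  out
}

#' Write motion patterns to a delimited text file
#'
#' Inverse of [read_patterns()]; the round trip reproduces coordinates to full
#' double precision.
#'
#' @param patterns A list of [motion_pattern()] objects (a single pattern is
#'   accepted too).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  if (inherits(patterns, "motion_pattern")) patterns <- list(patterns)
  rows <- lapply(patterns, function(p) {
    do.call(rbind, lapply(seq_along(p$repetitions), function(i) {
      r <- p$repetitions[[i]]
      data.frame(subject = p$subject, trial = p$trial, repetition = i,
                 t = r$t, x = r$x, y = r$y, stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  # format() would truncate; write full precision via as.character on doubles
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a jury rank table
#'
#' Rank tables are CSV with header `trial,subject,rank` (optionally `juror`);
#' within a trial each juror's ranks are a permutation of 1..m with m the
#' number of compared subjects and m (e.g. 10) = most creative.
#'
#' @param path File path.
#' @return A data frame with columns `trial`, `subject`, `rank` (and `juror`
#'   if present).
#' @export
read_ranks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial", "subject", "rank")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("format error: missing column(s) %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df$rank <- as.numeric(df$rank)
  df
}

#' @rdname read_ranks
#' @param ranks Data frame as returned by [simulate_jury()] or [read_ranks()].
#' @export
write_ranks <- function(ranks, path) {
  utils::write.csv(ranks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an analysis configuration file
#'
#' Reads a YAML key/value file overriding the pipeline defaults
#' (`T`, `cell_size`, `width`, `height`, `n_rep`, `n_basis`, `kappa0`, `nu0`,
#' `sigma_tau`, `min_transitions`, `lmax`).
#'
#' @param path Path to a YAML file, or `NULL` for defaults only.
#' @return A named list of configuration values.
#' @export
load_config <- function(path = NULL) {
  cfg <- list(T = 150L, cell_size = 1, width = 10, height = 10, n_rep = 10L,
              n_basis = 20L, kappa0 = 0.1, nu0 = 10.0, sigma_tau = 1e-10,
              min_transitions = 10000L, lmax = 8L)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read config files", call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg
}
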