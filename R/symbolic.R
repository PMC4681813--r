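#' Convert a trajectory into a grid-cell transition sequence
#'
#' The workspace is tessellated into square cells; each sample is assigned to
#' the half-open cell containing it (points on the top/right workspace
#' boundary belong to the last cell). One symbol is emitted per cell-boundary
#' crossing: `l`/`r` for horizontal, `d`/`u` for vertical crossings.
#' Consecutive samples that cross several boundaries are subdivided at the
#' exact line-grid intersections and crossings emitted in traversal order; an
#' exact corner hit emits the x-crossing first. Samples that stay in one cell
#' emit nothing.
#'
#' @param traj A [trajectory()].
#' @param ws A [workspace()] (default 10 x 10 cm, 1 cm cells).
#' @param warn_clip Warn when points fall outside the workspace and are
#'   clipped to its boundary (default `TRUE`).
#' @return A single character string over the alphabet `{l, r, u, d}`
#'   (possibly empty), of class `symbol_sequence`.
#' @export
#' @examples
#' tr <- trajectory(1:2, c(0.5, 3.5), c(0.5, 0.5))
#' symbolize(tr)  # "rrr"
symbolize <- function(traj, ws = workspace(), warn_clip = TRUE) {
  stopifnot(inherits(traj, "trajectory"), inherits(ws, "workspace"))
  if (length(traj$t) == 0L) {
    stop("invalid input: empty trajectory", call. = FALSE)
  }
  x <- traj$x; y <- traj$y
  out_of_bounds <- any(x < 0 | x > ws$width | y < 0 | y > ws$height)
  if (out_of_bounds && warn_clip) {
    warning("trajectory leaves the workspace; points clipped to its boundary",
            call. = FALSE)
  }
  x <- pmin(pmax(x, 0), ws$width)
  y <- pmin(pmax(y, 0), ws$height)
  s <- symbolize_cpp(x, y, ws$cell_size, ws$nx, ws$ny)
  structure(s, class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  n <- nchar(unclass(x))
  head <- substr(unclass(x), 1L, 60L)
  cat(sprintf("<symbol_sequence> %d transitions: %s%s\n", n, head,
              if (n > 60L) "..." else ""))
  invisible(x)
}

#' Build a large symbol corpus from a fitted movement primitive
#'
#' Repeatedly samples trajectories from the primitive's predictive
#' distribution, clips them to the workspace, symbolizes each, and
#' concatenates until the corpus holds at least `min_transitions` symbols.
#' Deterministic under a fixed seed.
#'
#' @param model A `pmp_fit` (see [fit_pmp()]).
#' @param ws A [workspace()].
#' @param min_transitions Minimum corpus length (default 10000).
#' @param seed Optional integer seed.
#' @param batch Trajectories sampled per batch (default 50).
#' @param max_trajectories Cap on the number of sampled trajectories before a
#'   progress-failure error (default 20000).
#' @return A `symbol_sequence` of length `>= min_transitions`.
#' @export
build_corpus <- function(model, ws = workspace(), min_transitions = 10000L,
                         seed = NULL, batch = 50L, max_trajectories = 20000L) {
  stopifnot(inherits(model, "pmp_fit"))
  if (!is.null(seed)) set.seed(seed)
  pieces <- character(0)
  total <- 0L
  drawn <- 0L
  while (total < min_transitions) {
    if (drawn >= max_trajectories) {
      stop(sprintf(
        "progress failure: %d sampled trajectories yielded only %d of %d transitions (degenerate single-cell model?)",
        drawn, total, min_transitions), call. = FALSE)
    }
    trajs <- simulate.pmp_fit(model, nsim = batch)
    drawn <- drawn + batch
    for (tr in trajs) {
      s <- unclass(symbolize(tr, ws, warn_clip = FALSE))
      if (nchar(s)) {
        pieces[[length(pieces) + 1L]] <- s
        total <- total + nchar(s)
      }
    }
  }
  structure(paste(pieces, collapse = ""), class = "symbol_sequence")
}
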