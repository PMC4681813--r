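#' Score a collection of motion patterns with all five complexity measures
#'
#' Runs the full analysis for each pattern:
#' 1. resample repetitions to `T` points and compute the across-repetition
#'    variance (`var`, cm^2);
#' 2. fit the Gaussian-process model per dimension and record the entropic
#'    complexity (`gp`, nats, see [fit_gp()]);
#' 3. fit the probabilistic movement primitive under a Normal-inverse-Wishart
#'    prior pooled over the whole collection and record the predictive
#'    entropy (`pmp`, nats, see [fit_pmp()]);
#' 4. sample a symbol corpus of at least `min_transitions` grid-cell
#'    transitions from the fitted primitive and record the normalized
#'    Lempel-Ziv complexity (`lzc`) and effective measure complexity
#'    (`emc`, bits).
#'
#' @param patterns List of [motion_pattern()] objects (or a single pattern).
#' @param T Resampling length (default 150).
#' @param ws A [workspace()] used for symbolization.
#' @param basis A [pmp_basis()].
#' @param kappa0,nu0 Normal-inverse-Wishart prior parameters (defaults 0.1,
#'   10).
#' @param sigma_tau Trajectory noise variance of the primitive (default
#'   1e-10).
#' @param min_transitions Minimum corpus length for the symbolic measures
#'   (default 10000).
#' @param lmax Maximum history length for [emc()] (`NULL` = automatic).
#' @param seed Optional integer seed controlling corpus sampling.
#' @param measures Subset of `c("gp", "pmp", "lzc", "emc", "var")` to
#'   compute; others are `NA` (useful to skip the expensive symbolic stage).
#' @return Data frame with one row per pattern: `subject`, `trial`, `gp`,
#'   `pmp`, `lzc`, `emc`, `var`.
#' @export
#' @examples
#' pats <- lapply(1:2, function(i)
#'   generate_pattern("ellipse_low_var", seed = i, T = 60, trial = i))
#' score_patterns(pats, T = 60, min_transitions = 500, seed = 1,
#'                measures = c("var", "pmp"))
score_patterns <- function(patterns, T = 150L, ws = workspace(),
                           basis = pmp_basis(), kappa0 = 0.1, nu0 = 10.0,
                           sigma_tau = 1e-10, min_transitions = 10000L,
                           lmax = NULL, seed = NULL,
                           measures = c("gp", "pmp", "lzc", "emc", "var")) {
  if (inherits(patterns, "motion_pattern")) patterns <- list(patterns)
  measures <- match.arg(measures, several.ok = TRUE)
  need_pmp <- any(c("pmp", "lzc", "emc") %in% measures)
  prior <- if (need_pmp) {
    pmp_prior(patterns, basis, T, kappa0 = kappa0, nu0 = nu0)
  } else NULL
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_along(patterns), function(i) {
    p <- patterns[[i]]
    gp <- pmp <- lzc <- emc_v <- var_v <- NA_real_
    if ("var" %in% measures) {
      var_v <- pattern_variance(resample_pattern(p, T))
    }
    if ("gp" %in% measures) {
      gp <- suppressWarnings(fit_gp(p, T = T)$complexity)
    }
    if (need_pmp) {
      fitp <- fit_pmp(p, basis, prior, T = T, sigma_tau = sigma_tau)
      if ("pmp" %in% measures) pmp <- fitp$complexity
      if (any(c("lzc", "emc") %in% measures)) {
        corpus <- build_corpus(fitp, ws, min_transitions = min_transitions)
        if ("lzc" %in% measures) lzc <- lz76_normalized(corpus, 4L)
        if ("emc" %in% measures) emc_v <- emc(corpus, L_max = lmax)$emc
      }
    }
    data.frame(subject = p$subject, trial = p$trial, gp = gp, pmp = pmp,
               lzc = lzc, emc = emc_v, var = var_v, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
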