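#' Spearman rank correlation with t-approximation or permutation p-value
#'
#' Both vectors are rank-transformed with midranks for ties and the Pearson
#' correlation of the ranks is returned. The default p-value uses the
#' standard t-approximation with `n - 2` degrees of freedom; a seeded
#' permutation test is available for small samples.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional seed for the permutation p-value.
#' @return List with `rho` and `p`.
#' @export
spearman_cor <- function(x, y, p_method = c("t", "permutation"),
                         n_perm = 10000L, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("invalid input: unequal lengths", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("invalid input: need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (p_method == "t") {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    if (!is.null(seed)) set.seed(seed)
    ref <- replicate(n_perm, abs(stats::cor(rx, sample(ry))))
    p <- (1 + sum(ref >= abs(rho))) / (1 + n_perm)
  }
  list(rho = rho, p = p)
}

check_coverage <- function(records, ranks) {
  kr <- paste(records$subject, records$trial)
  kk <- paste(ranks$subject, ranks$trial)
  miss_r <- setdiff(kk, kr); miss_k <- setdiff(kr, kk)
  if (length(miss_r) || length(miss_k)) {
    stop(sprintf(
      "invalid input: records and ranks cover different (subject, trial) sets; missing from records: %s; missing from ranks: %s",
      paste(utils::head(miss_r, 5), collapse = ", "),
      paste(utils::head(miss_k, 5), collapse = ", ")), call. = FALSE)
  }
}

rank_table <- function(ranks) {
  if ("avg_rank" %in% names(ranks)) return(ranks)
  average_ranks(ranks)
}

#' Trial-wise correlation between a complexity measure and creativity ranks
#'
#' Pools every (subject, trial) pair of (average creativity rank, complexity
#' measure) across the whole experiment and returns the Spearman correlation,
#' so n = subjects x trials.
#'
#' @param records Data frame of complexity scores with columns `subject`,
#'   `trial` and the measure columns (see [score_patterns()]).
#' @param ranks Rank table: columns `trial`, `subject` and `avg_rank` (or
#'   per-juror `rank` rows, which are averaged first).
#' @param measure Name of the measure column (`"gp"`, `"pmp"`, `"lzc"`,
#'   `"emc"`, `"var"`, ...).
#' @param ... Passed to [spearman_cor()].
#' @return List with `rho`, `p` and `n`.
#' @export
trialwise_correlation <- function(records, ranks, measure, ...) {
  if (!measure %in% names(records)) {
    stop(sprintf("invalid input: no measure column '%s'", measure), call. = FALSE)
  }
  rt <- rank_table(ranks)
  check_coverage(records, rt)
  m <- merge(records, rt, by = c("subject", "trial"))
  out <- spearman_cor(m$avg_rank, m[[measure]], ...)
  out$n <- nrow(m)
  out
}

significance_band <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "p<0.001" else if (p < 0.01) "p<0.01"
  else if (p < 0.05) "p<0.05" else "ns"
}

#' Per-subject correlation between a complexity measure and creativity ranks
#'
#' Computes the Spearman correlation over each subject's trials separately
#' and assigns each subject a significance band (p < 0.001 / 0.01 / 0.05 /
#' ns, uncorrected). A subject with a constant measure or constant ranks is
#' flagged undefined (`NA`) without affecting the others.
#'
#' @inheritParams trialwise_correlation
#' @return List with `table` (data frame: subject, n, rho, p, band) and
#'   `n_significant` (subjects with p < 0.05).
#' @export
subjectwise_correlation <- function(records, ranks, measure, ...) {
  rt <- rank_table(ranks)
  check_coverage(records, rt)
  m <- merge(records, rt, by = c("subject", "trial"))
  subjects <- sort(unique(m$subject))
  rows <- lapply(subjects, function(s) {
    d <- m[m$subject == s, , drop = FALSE]
    res <- tryCatch(spearman_cor(d$avg_rank, d[[measure]], ...),
                    error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(subject = s, n = nrow(d), rho = res$rho, p = res$p,
               band = significance_band(res$p), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, n_significant = sum(tab$p < 0.05, na.rm = TRUE))
}

#' Rank-rank coincidence histogram and per-subject rank correlations
#'
#' Within each trial the complexity measure is converted to within-trial
#' ranks and the jury average ranks to full ranks 1..m (ties resolved
#' deterministically toward the lower subject index for the histogram;
#' midranks are used for the correlations). The m x m coincidence histogram
#' accumulates one count per (jury rank, measure rank) pair per trial, so
#' every row and column sums to the number of trials.
#'
#' @inheritParams trialwise_correlation
#' @return List with `histogram` (m x m matrix, rows = jury rank 1..m,
#'   columns = measure rank) and `per_subject` as in
#'   [subjectwise_correlation()].
#' @export
rank_rank_analysis <- function(records, ranks, measure, ...) {
  rt <- rank_table(ranks)
  check_coverage(records, rt)
  m <- merge(records, rt, by = c("subject", "trial"))
  trials <- unique(m$trial)
  msize <- length(unique(m$subject))
  per_trial <- table(m$trial)
  if (length(unique(per_trial)) != 1L || per_trial[1] != msize) {
    stop("invalid input: every trial must compare the same subjects", call. = FALSE)
  }
  H <- matrix(0L, msize, msize,
              dimnames = list(jury = seq_len(msize), measure = seq_len(msize)))
  m$jury_rank_mid <- NA_real_; m$meas_rank_mid <- NA_real_
  for (tr in trials) {
    idx <- which(m$trial == tr)
    d <- m[idx, , drop = FALSE]
    jr <- rank(d$avg_rank, ties.method = "first")
    mr <- rank(d[[measure]], ties.method = "first")
    H[cbind(jr, mr)] <- H[cbind(jr, mr)] + 1L
    m$jury_rank_mid[idx] <- rank(d$avg_rank)
    m$meas_rank_mid[idx] <- rank(d[[measure]])
  }
  subjects <- sort(unique(m$subject))
  rows <- lapply(subjects, function(s) {
    d <- m[m$subject == s, , drop = FALSE]
    res <- tryCatch(spearman_cor(d$jury_rank_mid, d$meas_rank_mid, ...),
                    error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(subject = s, n = nrow(d), rho = res$rho, p = res$p,
               band = significance_band(res$p), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(histogram = H,
       per_subject = list(table = tab,
                          n_significant = sum(tab$p < 0.05, na.rm = TRUE)))
}

#' Score divergent-thinking responses
#'
#' Responses are case-folded and trimmed, then scored per subject:
#' * fluency: number of responses;
#' * originality: responses given by fewer than 20% of subjects;
#' * percentage: originality / fluency;
#' * mean originality: the mean over the subject's responses of one minus
#'   the fraction of subjects giving that response.
#'
#' Frequencies are computed over subjects (a subject counts once per distinct
#' response).
#'
#' @param responses Named list: one character vector of free-text responses
#'   per subject.
#' @return Data frame with columns `subject`, `fluency`, `originality`,
#'   `percentage`, `mean_originality` (the latter three `NA` for an empty
#'   response list).
#' @export
#' @examples
#' divergent_scores(list(a = c("hat", "boat"), b = c("hat"), c = c("hat", "kite")))
divergent_scores <- function(responses) {
  if (!length(responses)) stop("invalid input: no subjects", call. = FALSE)
  if (is.null(names(responses))) {
    names(responses) <- paste0("s", seq_along(responses))
  }
  norm <- lapply(responses, function(r) {
    tolower(trimws(as.character(r)))
  })
  n_subj <- length(norm)
  # fraction of subjects giving each distinct response
  per_subject_unique <- lapply(norm, unique)
  freq <- table(unlist(per_subject_unique)) / n_subj
  rows <- lapply(names(norm), function(s) {
    r <- norm[[s]]
    fl <- length(r)
    if (fl == 0L) {
      return(data.frame(subject = s, fluency = 0L, originality = NA_integer_,
                        percentage = NA_real_, mean_originality = NA_real_,
                        stringsAsFactors = FALSE))
    }
    f <- as.numeric(freq[r])
    data.frame(subject = s, fluency = fl,
               originality = sum(f < 0.2),
               percentage = sum(f < 0.2) / fl,
               mean_originality = mean(1 - f), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
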