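test_that("Spearman correlation handles monotone transforms, ties, and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- exp(x)
  expect_equal(spearman_cor(x, y)$rho, 1)
  expect_equal(spearman_cor(x, -y)$rho, -1)
  expect_equal(spearman_cor(x, y)$p, 0)

  # monotone-transform invariance with ties present
  set.seed(3)
  a <- sample(1:4, 30, replace = TRUE)
  b <- rnorm(30)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(a^3 + 1, b)$rho)

  # 6-point toy with a tie, against the definitional midrank oracle
  xt <- c(1, 2, 2, 3, 5, 4); yt <- c(2, 1, 4, 3, 6, 5)
  got <- spearman_cor(xt, yt)
  oracle <- stats::cor(rank(xt), rank(yt))   # Pearson on midranks
  expect_equal(got$rho, oracle)
  ct <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman"))
  expect_equal(got$rho, unname(ct$estimate))

  # t-approximation agrees with the reference implementation without ties
  set.seed(4)
  u <- rnorm(25); v <- u + rnorm(25)
  ct2 <- stats::cor.test(u, v, method = "spearman", exact = FALSE)
  got2 <- spearman_cor(u, v)
  expect_equal(got2$p, ct2$p.value, tolerance = 1e-12)

  # permutation p-value is consistent with the t-approximation
  pp <- spearman_cor(u, v, p_method = "permutation", n_perm = 2000, seed = 1)$p
  expect_lt(abs(log10(pp + 1e-4) - log10(got2$p + 1e-4)), 2)

  expect_error(spearman_cor(rep(1, 5), 1:5), "undefined correlation")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

make_fake_records <- function(n_subj = 5L, n_trial = 8L, seed = 1L) {
  set.seed(seed)
  expand.grid(subject = paste0("s", seq_len(n_subj)),
              trial = seq_len(n_trial), stringsAsFactors = FALSE) |>
    transform(gp = rnorm(n_subj * n_trial),
              var = stats::runif(n_subj * n_trial))
}

# jury ranks are trial-relative, so the exact self-ranking identity holds on
# the within-trial rank representation of a measure
rank_within_trials <- function(rec, measure) {
  rec[[measure]] <- stats::ave(rec[[measure]], rec$trial, FUN = rank)
  rec
}

test_that("trial-wise correlation is exact for a self-ranking jury and near zero for a random one", {
  rec <- make_fake_records()
  truth <- data.frame(trial = rec$trial, subject = rec$subject, score = rec$gp)
  jury <- simulate_jury(truth, n_jurors = 4L, noise_sd = 0)
  out <- trialwise_correlation(rank_within_trials(rec, "gp"), jury, "gp")
  expect_equal(out$rho, 1)
  expect_identical(out$n, nrow(rec))

  # independent random jury scores: small correlation, calibrated null
  rhos <- sapply(1:30, function(s) {
    set.seed(700 + s)
    truth$score <- rnorm(nrow(truth))
    trialwise_correlation(rec, simulate_jury(truth, 1L, 0), "gp")$rho
  })
  expect_lt(stats::median(abs(rhos)), 0.25)
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("coverage mismatches are reported with the missing keys", {
  rec <- make_fake_records()
  truth <- data.frame(trial = rec$trial, subject = rec$subject, score = rec$gp)
  jury <- simulate_jury(truth, 2L, 0)
  expect_error(trialwise_correlation(rec[-1, ], jury, "gp"), "missing from records")
  expect_error(trialwise_correlation(rec, jury[jury$trial != 1, ], "gp"),
               "cover different")
  expect_error(trialwise_correlation(rec, jury, "nope"), "no measure column")
})

test_that("subject-wise correlations isolate degenerate subjects and band significance", {
  rec <- make_fake_records(n_subj = 4L, n_trial = 12L, seed = 2L)
  truth <- data.frame(trial = rec$trial, subject = rec$subject, score = rec$gp)
  jury <- simulate_jury(truth, 3L, 0)
  out <- subjectwise_correlation(rank_within_trials(rec, "gp"), jury, "gp")
  expect_equal(out$table$rho, rep(1, 4))
  expect_identical(out$n_significant, 4L)
  expect_true(all(out$table$band == "p<0.001"))

  # one subject with a constant measure is flagged NA, others unaffected
  rec2 <- rank_within_trials(rec, "gp")
  rec2$gp[rec2$subject == "s2"] <- 5
  out2 <- subjectwise_correlation(rec2, jury, "gp")
  expect_true(is.na(out2$table$rho[out2$table$subject == "s2"]))
  expect_equal(out2$table$rho[out2$table$subject != "s2"], rep(1, 3))
})

test_that("rank-rank histograms concentrate on the diagonal for identical orderings and stay uniform under the null", {
  rec <- make_fake_records(n_subj = 6L, n_trial = 10L, seed = 3L)
  truth <- data.frame(trial = rec$trial, subject = rec$subject, score = rec$gp)
  jury <- simulate_jury(truth, 3L, 0)
  out <- rank_rank_analysis(rec, jury, "gp")
  expect_identical(sum(out$histogram), 60L)
  expect_identical(sum(diag(out$histogram)), 60L)
  expect_true(all(rowSums(out$histogram) == 10L))
  expect_true(all(colSums(out$histogram) == 10L))
  expect_equal(out$per_subject$table$rho, rep(1, 6))

  # independent orderings: off-diagonal mass, chi-square vs uniform not extreme
  hits <- 0L
  for (s in 1:3) {
    set.seed(900 + s)
    rec_n <- rec; rec_n$gp <- rnorm(nrow(rec))
    truth_n <- data.frame(trial = rec$trial, subject = rec$subject,
                          score = rnorm(nrow(rec)))
    H <- rank_rank_analysis(rec_n, simulate_jury(truth_n, 1L, 0), "gp")$histogram
    expcnt <- sum(H) / length(H)
    chi <- sum((H - expcnt)^2 / expcnt)
    if (stats::pchisq(chi, df = length(H) - 1L, lower.tail = FALSE) > 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 2L)
})

test_that("divergent-thinking metrics follow the three-step definition", {
  # single subject: every response shared by 100% of subjects
  one <- divergent_scores(list(s1 = c("hat", "boat", "kite")))
  expect_identical(one$fluency, 3L)
  expect_equal(one$originality, 0)
  expect_equal(one$mean_originality, 0)

  # 10 subjects; one response unique to one subject
  resp <- c(list(special = c("common", "unicorn")),
            lapply(1:9, function(i) "common"))
  names(resp)[-1] <- paste0("s", 1:9)
  out <- divergent_scores(resp)
  sp <- out[out$subject == "special", ]
  expect_identical(sp$fluency, 2L)
  expect_equal(sp$originality, 1)          # 1/10 of subjects < 20%
  expect_equal(sp$percentage, 0.5)
  expect_equal(sp$mean_originality, mean(c(1 - 1, 1 - 0.1)))

  # all subjects identical: no originality anywhere
  same <- divergent_scores(lapply(1:5, function(i) "Tree "))
  expect_true(all(same$percentage == 0))
  expect_true(all(same$mean_originality == 0))

  # normalization: case and whitespace folded
  norm <- divergent_scores(list(a = "Hat ", b = "hat"))
  expect_equal(norm$originality, c(0, 0))

  empty <- divergent_scores(list(a = character(0), b = c("x", "y")))
  expect_identical(empty$fluency[1], 0L)
  expect_true(is.na(empty$mean_originality[1]))
})
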