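# ROC thresholds, Kaplan-Meier, log-rank, Cox regression, forward-Wald
# selection.

test_that("ROC points and AUC satisfy the Mann-Whitney identity", {
  score <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  roc <- roc_points(score, y)
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  expect_equal(roc_auc(roc), 1)
  # constant score: only the two corner points, AUC 1/2
  rc <- roc_points(rep(4, 6), y)
  expect_equal(roc_auc(rc), 0.5)
  expect_error(roc_points(score, rep(1, 6)), "both label values")
  set.seed(18)
  for (k in 1:200) {
    s <- sample(1:20, 50, replace = TRUE)  # heavy ties
    yy <- rbinom(50, 1, 0.4)
    if (length(unique(yy)) < 2) next
    expect_equal(roc_auc(roc_points(s, yy)), auc_mannwhitney(s, yy),
                 tolerance = 1e-12)
  }
})

test_that("Youden threshold equals exhaustive maximization", {
  score <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  yt <- youden_threshold(roc_points(score, y))
  expect_equal(yt$threshold, 6.5)  # midpoint of the adjacent class values
  expect_equal(yt$j, 1)
  flat <- youden_threshold(roc_points(rep(4, 6), y))
  expect_equal(flat$j, 0)
  set.seed(19)
  s <- rnorm(20); yy <- rbinom(20, 1, 0.5)
  roc <- roc_points(s, yy)
  yt2 <- youden_threshold(roc)
  # brute force over every candidate threshold
  j_best <- -Inf; t_best <- NA
  for (t in roc$threshold) {
    tpr <- sum(s >= t & yy == 1) / sum(yy == 1)
    fpr <- sum(s >= t & yy == 0) / sum(yy == 0)
    j <- tpr - fpr
    if (j > j_best + 1e-12) { j_best <- j; t_best <- t }
  }
  expect_equal(yt2$j, j_best, tolerance = 1e-12)
})

test_that("Kaplan-Meier matches hand-evaluated product-limit terms", {
  # 10 subjects, 5 events, no censoring before the last event
  rec <- data.frame(time = c(1:5, rep(9, 5)),
                    event = c(rep(1, 5), rep(0, 5)))
  km <- km_estimate(rec)
  expect_equal(km$survival[km$time == 5], 0.5)
  allc <- km_estimate(data.frame(time = 1:4, event = 0))
  expect_true(all(allc$survival == 1))
  # 8 subjects with interleaved censoring:
  # events at 1 (n=8), 3 (n=6), 5 (n=3); censored at 2, 4, 4, 6, 7
  rec2 <- data.frame(time = c(1, 2, 3, 4, 4, 5, 6, 7),
                     event = c(1, 0, 1, 0, 0, 1, 0, 0))
  km2 <- km_estimate(rec2)
  s1 <- 1 - 1 / 8
  s3 <- s1 * (1 - 1 / 6)
  s5 <- s3 * (1 - 1 / 3)
  expect_equal(km2$survival[km2$time == 1], s1)
  expect_equal(km2$survival[km2$time == 3], s3)
  expect_equal(km2$survival[km2$time == 5], s5)
  expect_error(km_estimate(data.frame(time = -1, event = 1)), "negative")
})

test_that("log-rank test matches hand-computed observed-minus-expected", {
  # duplicated records: identical groups give chi-square 0
  rec <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 0), 2))
  lr0 <- logrank_test(rec, rep(c("a", "b"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)
  # 6-subject toy, hand evaluation of the O-E and variance sums
  rec2 <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                     event = c(1, 1, 1, 1, 0, 1))
  grp <- c("a", "b", "a", "b", "a", "b")
  # event times 1,2,3,4,6 with group-a at-risk 3,2,2,1,0
  o_a <- 2
  e_a <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 0 / 1
  v <- (3 * 3 / 36) + (2 * 3 / 25) + (2 * 2 / 16) + (1 * 2 / 9) + 0
  lr <- logrank_test(rec2, grp)
  expect_equal(lr$chisq, (o_a - e_a)^2 / v, tolerance = 1e-10)
  # symmetry under label swap
  expect_equal(lr$chisq,
               logrank_test(rec2, ifelse(grp == "a", "b", "a"))$chisq)
  expect_error(logrank_test(data.frame(time = 1:4, event = 0),
                            c("a", "a", "b", "b")), "no events")
})

test_that("Cox fit agrees with grid maximization of the partial likelihood", {
  rec <- data.frame(time = c(2, 4, 5, 7, 9, 12),
                    event = c(1, 1, 0, 1, 1, 0))
  x <- c(1, 0, 1, 0, 1, 0)
  f <- cox_fit(rec, data.frame(high = x))
  beta_star <- cox_grid_oracle(rec$time, rec$event, x)
  expect_equal(f$coef[1], beta_star, tolerance = 1e-4)
  expect_equal(f$hr[1], exp(f$coef[1]))
  expect_equal(f$ci_lo[1], exp(f$coef[1] - 1.96 * f$se[1]))
  # constant covariate: no information, HR 1
  fc <- cox_fit(rec, data.frame(z = rep(2, 6)))
  expect_equal(fc$coef[1], 0)
  expect_equal(fc$hr[1], 1)
})

test_that("zero-event strata are reported as infinite hazard ratios", {
  rec <- data.frame(time = c(1, 2, 3, rep(8, 7)),
                    event = c(1, 1, 1, rep(0, 7)))
  x <- c(1, 1, 1, 1, rep(0, 6))
  f <- cox_fit(rec, data.frame(high = x))
  expect_true(f$monotone[1])
  expect_equal(f$hr[1], Inf)
  expect_true(is.na(f$wald[1]))
  expect_true(f$p_value[1] > 0 && f$p_value[1] < 1)  # likelihood-ratio p
})

test_that("Cox-scan threshold confirmation recovers generative cutpoints", {
  rec1 <- data.frame(time = c(1, 2, 8, 8), event = c(1, 1, 0, 0))
  one <- cox_threshold_confirm(c(5, 6, 1, 2), rec1, candidates = 3)
  expect_equal(one$cutoff, 3)
  # candidates producing identical dichotomizations give identical Walds
  scan <- cox_threshold_confirm(c(5, 6, 1, 2), rec1,
                                candidates = c(3, 3.5, 4))$scan
  expect_equal(scan$wald[1], scan$wald[2], tolerance = 1e-10)
  # change-point recovery across simulated cohorts
  hits <- 0
  n_sim <- 100
  for (k in seq_len(n_sim)) {
    set.seed(500 + k)
    n <- 200
    v <- runif(n, 0, 10)
    hi <- as.numeric(v >= 5)
    t_raw <- rexp(n, rate = 0.05 * 8^hi)
    rec <- data.frame(time = pmin(t_raw, 10),
                      event = as.integer(t_raw <= 10))
    cands <- seq(1, 9, by = 0.5)
    best <- cox_threshold_confirm(v, rec, cands)$cutoff
    if (abs(best - 5) <= 0.5) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.80)
})

test_that("forward-Wald selection keeps signal and drops noise", {
  sim_records <- function(seed, strong_hr) {
    set.seed(seed)
    n <- 150
    strong <- rbinom(n, 1, 0.5)
    noise1 <- rbinom(n, 1, 0.5); noise2 <- rbinom(n, 1, 0.5)
    t_raw <- rexp(n, rate = 0.03 * strong_hr^strong)
    list(rec = data.frame(time = pmin(t_raw, 10),
                          event = as.integer(t_raw <= 10)),
         cov = data.frame(strong = strong, noise1 = noise1,
                          noise2 = noise2))
  }
  ok <- 0
  for (k in 1:100) {
    s <- sim_records(700 + k, strong_hr = 8)
    sel <- forward_wald_selection(s$rec, s$cov[, c("strong", "noise1")])
    if (identical(sel$selected, "strong")) ok <- ok + 1
  }
  expect_gte(ok / 100, 0.90)
  # two pure-noise candidates: null model in most runs
  nulls <- 0
  for (k in 1:100) {
    s <- sim_records(900 + k, strong_hr = 1)
    sel <- forward_wald_selection(s$rec, s$cov[, c("noise1", "noise2")])
    if (length(sel$selected) == 0) nulls <- nulls + 1
  }
  expect_gte(nulls / 100, 0.90)
})

test_that("collinear candidates trigger the backward fallback", {
  set.seed(44)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  t_raw <- rexp(n, rate = 0.05 * 6^x)
  rec <- data.frame(time = pmin(t_raw, 10), event = as.integer(t_raw <= 10))
  sel <- forward_wald_selection(rec, data.frame(a = x, b = x))
  expect_equal(sel$method, "backward")
  expect_length(sel$selected, 1)
})
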