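test_that("RLU, fold stimulated, and WT normalization compute the stated ratios", {
  expect_equal(compute_rlu(100, 100), 1)
  expect_equal(compute_rlu(300, 100), 3)
  expect_error(compute_rlu(10, 0), "renilla")

  wells <- make_wells(mult = c(WT = 1, VAR = 3), wt_fold = 5)
  folds <- fold_stimulated(wells)
  expect_equal(folds$fold_stimulated[folds$construct == "WT"], c(5, 5))
  expect_equal(folds$fold_stimulated[folds$construct == "VAR"], c(15, 15))
  rel <- normalize_to_wt(folds)
  expect_equal(rel$relative_fold[rel$construct == "WT"], c(1, 1))
  expect_equal(rel$relative_fold[rel$construct == "VAR"], c(3, 3))

  # duplicate wells average at the RLU stage: hand computation on 2 wells
  two <- data.frame(construct = "WT", experiment = 1,
                    stimulated = c(TRUE, TRUE, FALSE, FALSE),
                    firefly = c(200, 400, 100, 100),
                    renilla = c(100, 100, 100, 100))
  expect_equal(fold_stimulated(two)$fold_stimulated,
               mean(c(2, 4)) / mean(c(1, 1)))

  expect_error(fold_stimulated(wells[wells$stimulated, ]), "unstimulated")
  noWT <- wells[wells$construct != "WT", ]
  expect_error(normalize_to_wt(fold_stimulated(noWT)), "wild-type")
})

test_that("the chain is invariant to per-experiment Firefly and Renilla rescaling", {
  sim <- simulate_reporter_plate(plate_sim_spec(replicate_cv = 0.15,
                                                n_experiments = 3,
                                                seed = 31))
  wells <- sim$wells
  base <- normalize_to_wt(fold_stimulated(wells))
  scaled <- wells
  e1 <- scaled$experiment == 1
  scaled$firefly[e1] <- scaled$firefly[e1] * 7.3
  scaled$renilla[scaled$experiment == 2] <-
    scaled$renilla[scaled$experiment == 2] * 0.21
  rescaled <- normalize_to_wt(fold_stimulated(scaled))
  expect_equal(rescaled$relative_fold, base$relative_fold)
})

test_that("one-way ANOVA reduces to known special cases", {
  # equal group means with nonzero within-group variance
  res <- one_way_anova(c(1, 3, 2, 2, 0, 4), rep(c("a", "b", "c"), each = 2))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # two groups: F equals the squared equal-variance t statistic
  set.seed(101)
  x <- rnorm(8); y <- rnorm(8) + 1
  res2 <- one_way_anova(c(x, y), rep(c("a", "b"), each = 8))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-12)

  # hand-computed sums of squares on a 3 x 3 table
  vals <- c(1, 2, 3, 2, 4, 6, 5, 7, 9)
  grp <- rep(c("g1", "g2", "g3"), each = 3)
  gm <- mean(vals)
  ssb <- 3 * sum((tapply(vals, grp, mean) - gm)^2)
  ssw <- sum((vals - ave(vals, grp))^2)
  f_manual <- (ssb / 2) / (ssw / 6)
  res3 <- one_way_anova(vals, grp)
  expect_equal(res3$F, f_manual, tolerance = 1e-12)
  expect_equal(res3$p, pf(f_manual, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "two observations")
})

test_that("Monte Carlo Dunnett collapses to the t test for a single comparison", {
  set.seed(5)
  vals <- c(rnorm(6), rnorm(6) + 1.2)
  grp <- rep(c("WT", "VAR"), each = 6)
  d <- dunnett_vs_control(vals, grp, control = "WT", n_mc = 2e5, seed = 2)
  expect_equal(d$p_adjusted, d$p_unadjusted, tolerance = 0.02)
})

test_that("Monte Carlo Dunnett matches a brute-force resampling oracle", {
  set.seed(77)
  n_per <- 5
  vals <- c(rnorm(n_per, 0), rnorm(n_per, 0.9), rnorm(n_per, 1.6))
  grp <- rep(c("WT", "A", "B"), each = n_per)
  n_mc <- 2e5
  d <- dunnett_vs_control(vals, grp, control = "WT", n_mc = n_mc, seed = 3)

  # oracle: simulate whole null datasets and recompute max |t| from raw data
  n_oracle <- 2e5
  set.seed(991)
  maxT <- replicate(n_oracle, {
    y <- matrix(rnorm(3 * n_per), ncol = 3)
    m <- colMeans(y)
    s2 <- sum(sweep(y, 2, m)^2) / (3 * n_per - 3)
    max(abs(m[2:3] - m[1]) / sqrt(s2 * (2 / n_per)))
  })
  t_obs <- abs(d$t)
  p_oracle <- vapply(t_obs, function(t0) mean(maxT >= t0), numeric(1))
  se <- sqrt(p_oracle * (1 - p_oracle) / n_oracle +
               d$p_adjusted * (1 - d$p_adjusted) / n_mc)
  expect_true(all(abs(d$p_adjusted - p_oracle) <= 2 * se + 1e-4))
})

test_that("Monte Carlo Dunnett agrees with the multivariate-t implementation", {
  set.seed(21)
  grp <- factor(rep(c("WT", "A", "B"), each = 6),
                levels = c("WT", "A", "B"))
  vals <- rnorm(18) + c(0, 1.0, 0.4)[as.integer(grp)]
  d <- dunnett_vs_control(vals, grp, control = "WT", n_mc = 2e5, seed = 8)
  fit <- stats::aov(vals ~ grp)
  gl <- summary(multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett")))
  p_ref <- as.numeric(gl$test$pvalues)
  expect_equal(sort(d$p_adjusted), sort(p_ref), tolerance = 0.03)
})

test_that("adjusted p-values respect ordering invariants and the null", {
  set.seed(13)
  vals <- rnorm(20)
  grp <- rep(c("WT", "A", "B", "C"), each = 5)
  d <- dunnett_vs_control(vals, grp, control = "WT", n_mc = 2e4, seed = 4)
  expect_true(all(d$p_adjusted >= d$p_unadjusted))
  expect_true(all(d$p_adjusted >= 0 & d$p_adjusted <= 1))
  expect_gt(median(d$p_adjusted), 0.1)  # identical populations
  expect_error(dunnett_vs_control(vals, grp, control = "missing"),
               "control")
})

test_that("Sidak adjustment follows its closed form", {
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(0.05, 3), 0.142625)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(sidak_adjust(p, 4) >= p))
  expect_true(all(sidak_adjust(p, 4) <= 1))
  expect_error(sidak_adjust(1.5, 2), "\\[0, 1\\]")
})

test_that("the reporter chain recovers a planted multiplier with low bias", {
  sim <- simulate_reporter_plate(plate_sim_spec(
    constructs = c("WT", "VAR"), effect_multiplier = c(WT = 1, VAR = 2),
    replicate_cv = 0.1, n_experiments = 50, seed = 41))
  rel <- normalize_to_wt(fold_stimulated(sim$wells))
  est <- mean(rel$relative_fold[rel$construct == "VAR"])
  expect_lt(abs(est / 2 - 1), 0.05)
})

test_that("the full reporter analysis flags a planted effect and not the WT", {
  sim <- simulate_reporter_plate(plate_sim_spec(
    constructs = c("EV", "WT", "GOF"),
    effect_multiplier = c(EV = 0.2, WT = 1, GOF = 3),
    replicate_cv = 0.1, n_experiments = 4, seed = 43))
  res <- reporter_assay(sim$wells, n_mc = 2e4, seed = 6)
  expect_s3_class(res, "reporter_assay")
  est <- res$estimates
  expect_equal(est$mean_relative_fold[est$construct == "WT"], 1)
  expect_equal(est$mean_relative_fold[est$construct == "GOF"], 3,
               tolerance = 0.25)
  cmp <- res$comparisons
  expect_true(all(cmp$p_adjusted[grepl("GOF|EV", cmp$comparison)] < 0.05))
  expect_output(print(res), "Dunnett")
})
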