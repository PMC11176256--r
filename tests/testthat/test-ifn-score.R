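test_that("qPCR relative expression follows 2^(-dCt) with replicate averaging", {
  panel <- qpcr_panel()
  genes <- c(panel$isgs, panel$housekeeping)
  ct <- data.frame(sample = "S1", gene = genes,
                   ct = c(rep(25, 6), 25, 25))
  rel <- qpcr_relative_expression(ct, panel)
  expect_equal(unname(rel["S1", ]), rep(1, 6))  # Ct at the HK mean

  ct$ct[ct$gene == "IFI27"] <- 22  # three cycles below the HK mean
  expect_equal(qpcr_relative_expression(ct, panel)["S1", "IFI27"],
               8, ignore_attr = TRUE)

  # technical replicates average on the Ct scale, not the linear scale
  reps <- rbind(ct, ct)
  reps$ct[reps$gene == "IFI44L"] <- c(23, 27)  # Ct-scale mean is 25
  rel <- qpcr_relative_expression(reps, panel)
  expect_equal(rel["S1", "IFI44L"], 1, ignore_attr = TRUE)

  expect_error(qpcr_relative_expression(ct[ct$gene != "HPRT1", ], panel),
               "HPRT1")
  expect_error(qpcr_relative_expression(ct[ct$gene != "RSAD2", ], panel),
               "RSAD2")
})

test_that("fold versus control median is scale invariant", {
  rel <- matrix(c(1, 1, 2,
                  2, 2, 4), nrow = 3,
                dimnames = list(c("C1", "C2", "P1"), c("g1", "g2")))
  folds <- fold_vs_control_median(rel, c("C1", "C2"))
  expect_equal(unname(folds["P1", ]), c(2, 2))
  expect_equal(unname(folds["C1", ]), c(1, 1))
  folds2 <- fold_vs_control_median(rel * 2, c("C1", "C2"))
  expect_equal(folds, folds2)
  expect_error(fold_vs_control_median(rel, "C1"), "2 controls")
  expect_error(fold_vs_control_median(rel * 0, c("C1", "C2")), "median")
})

test_that("qPCR interferon score is the median of six folds with strict positivity", {
  f1 <- setNames(rep(1, 6), qpcr_panel()$isgs)
  s1 <- ifn_score_qpcr(f1)
  expect_equal(s1$score, 1)
  expect_false(s1$positive)

  f2 <- setNames(c(9.63, 10, 12, 15, 20, 21.48), qpcr_panel()$isgs)
  s2 <- ifn_score_qpcr(f2)
  expect_equal(s2$score, 13.5)
  expect_true(s2$positive)

  f3 <- setNames(rep(2.46, 6), qpcr_panel()$isgs)
  s3 <- ifn_score_qpcr(f3)
  expect_equal(s3$score, 2.46)
  expect_false(s3$positive)  # strictly above the threshold only

  expect_error(ifn_score_qpcr(f2[-1]), "IFI27")
})

test_that("the median score tolerates corruption of a minority of genes", {
  f <- setNames(rep(1, 6), qpcr_panel()$isgs)
  f[c(1, 4)] <- c(500, 1e-3)  # 2 of 6 corrupted
  expect_equal(ifn_score_qpcr(f)$score, 1)
})

test_that("NanoString normalization removes per-sample scale distortion exactly", {
  sim <- simulate_nanostring(
    expression_sim_spec(n_patients = 1, n_controls = 3, injected_fold = 1,
                        ct_noise_sd = 0, seed = 21),
    distortion_sdlog = 0, background_mean = 0)
  counts <- sim$counts
  norm0 <- nanostring_normalize(counts)
  # undistorted, background-free, noise-free: normalization is the identity
  raw_mat <- with(counts[counts$role == "isg" & counts$sample == "P01", ],
                  setNames(count, probe))
  expect_equal(norm0["P01", names(raw_mat)], raw_mat)

  # doubling every count of one sample (calibrators included) is removed:
  # the distorted sample becomes identical to the undistorted ones again
  # (the grand calibrator mean shifts all samples by one common factor)
  distorted <- counts
  idx <- distorted$sample == "C01"
  distorted$count[idx] <- distorted$count[idx] * 2
  norm2 <- nanostring_normalize(distorted)
  expect_equal(norm2["C01", ], norm2["P01", ])
  ratio <- norm2 / norm0
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)

  bad <- counts
  bad$count[bad$role == "pos_cal"][1] <- 0
  expect_error(nanostring_normalize(bad), "positive calibrators")
})

test_that("NanoString scores derive their threshold from control moments", {
  sim <- simulate_nanostring(
    expression_sim_spec(n_patients = 2, n_controls = 27, injected_fold = 1,
                        ct_noise_sd = 0.2, seed = 33))
  norm <- nanostring_normalize(sim$counts)
  res <- ifn_score_nanostring(norm, sim$truth$controls)
  # independent recomputation of the control scores and threshold
  folds <- sweep(norm, 2,
                 apply(norm[sim$truth$controls, ], 2, median), "/")
  ctrl_scores <- apply(folds[sim$truth$controls, ], 1, median)
  expect_equal(res$threshold, mean(ctrl_scores) + 2 * sd(ctrl_scores))

  # identical controls with a sample equal to them: score 1, threshold 1,
  # negative under strict positivity
  panel <- nanostring_panel()
  flat <- matrix(100, nrow = 3, ncol = 24,
                 dimnames = list(c("C1", "C2", "S1"), panel$probes))
  res0 <- ifn_score_nanostring(flat, c("C1", "C2"), panel)
  expect_equal(res0$threshold, 1)
  expect_equal(res0$scores$score, rep(1, 3))
  expect_false(any(res0$scores$positive))
  expect_error(ifn_score_nanostring(flat, "C1"), "2 controls")
})

test_that("simulated qPCR and NanoString runs recover the injected fold", {
  qsim <- simulate_qpcr(expression_sim_spec(
    n_patients = 8, n_controls = 29, injected_fold = 10, ct_noise_sd = 0.2,
    seed = 17))
  rel <- qpcr_relative_expression(qsim$ct)
  folds <- fold_vs_control_median(rel, qsim$truth$controls)
  scores <- ifn_score_qpcr(folds[qsim$truth$patients, ])
  expect_true(all(abs(scores$score / 10 - 1) < 0.2))
  expect_true(all(scores$positive))

  nsim <- simulate_nanostring(expression_sim_spec(
    n_patients = 6, n_controls = 27, injected_fold = 5, ct_noise_sd = 0.2,
    seed = 19))
  norm <- nanostring_normalize(nsim$counts)
  res <- ifn_score_nanostring(norm, nsim$truth$controls)
  pat <- res$scores[!res$scores$is_control, ]
  expect_true(all(abs(pat$score / 5 - 1) < 0.2))
  expect_true(all(pat$positive))
})

test_that("a global multiplicative rescaling of one sample cancels in the qPCR score", {
  sim <- simulate_qpcr(expression_sim_spec(
    n_patients = 1, n_controls = 3, injected_fold = 4, ct_noise_sd = 0,
    seed = 23))
  ct <- sim$ct
  base <- fold_vs_control_median(qpcr_relative_expression(ct),
                                 sim$truth$controls)
  # scaling expression by 8 shifts every Ct of the sample down 3 cycles
  ct$ct[ct$sample == "P01"] <- ct$ct[ct$sample == "P01"] - 3
  shifted <- fold_vs_control_median(qpcr_relative_expression(ct),
                                    sim$truth$controls)
  expect_equal(shifted, base)
})

test_that("null qPCR simulations stay below the positivity threshold at nominal rates", {
  sim <- simulate_qpcr(expression_sim_spec(
    n_patients = 1000, n_controls = 29, injected_fold = 1,
    ct_noise_sd = 0.3, seed = 29))
  rel <- qpcr_relative_expression(sim$ct)
  folds <- fold_vs_control_median(rel, sim$truth$controls)
  scores <- ifn_score_qpcr(folds[sim$truth$patients, ])
  expect_lt(mean(scores$positive), 0.05)
})
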