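# Dual-luciferase reporter normalization chain and the comparison
# statistics applied to it: one-way ANOVA, Monte Carlo Dunnett against the
# wild-type control, and the Sidak closed-form adjustment.

#' Relative luciferase units
#'
#' @param firefly Firefly luminescence (>= 0).
#' @param renilla Renilla luminescence (> 0); the co-transfected
#'   constitutive reporter that absorbs well-to-well transfection and lysis
#'   differences.
#' @return `firefly / renilla`, vectorized.
#' @export
compute_rlu <- function(firefly, renilla) {
  stop_if_not(all(is.finite(firefly)) && all(firefly >= 0),
              "firefly must be finite and non-negative")
  stop_if_not(all(is.finite(renilla)) && all(renilla > 0),
              "renilla must be finite and positive")
  firefly / renilla
}

#' Fold induction on stimulation
#'
#' Replicate wells are averaged at the RLU stage; the fold stimulated of a
#' construct within an experiment is the mean stimulated RLU over the mean
#' of its matched unstimulated wells.
#'
#' @param wells `data.frame` with columns `construct`, `experiment`,
#'   `stimulated` (logical), `firefly`, `renilla`.
#' @return `data.frame` with columns `construct`, `experiment`,
#'   `fold_stimulated`.
#' @export
fold_stimulated <- function(wells) {
  req <- c("construct", "experiment", "stimulated", "firefly", "renilla")
  stop_if_not(all(req %in% names(wells)),
              "well table needs columns: ", paste(req, collapse = ", "))
  wells$rlu <- compute_rlu(wells$firefly, wells$renilla)
  key <- interaction(wells$construct, wells$experiment, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    w <- wells[key == k, ]
    stim <- w$rlu[w$stimulated]
    ns <- w$rlu[!w$stimulated]
    if (length(stim) == 0 || length(ns) == 0)
      stop("construct ", w$construct[1], ", experiment ", w$experiment[1],
           " lacks ", if (length(ns) == 0) "unstimulated" else "stimulated",
           " wells", call. = FALSE)
    data.frame(construct = w$construct[1], experiment = w$experiment[1],
               fold_stimulated = mean(stim) / mean(ns),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalize fold inductions to the wild-type construct
#'
#' Divides every construct's fold stimulated by the wild-type fold of the
#' same experiment, so the wild type is 1 by construction within each
#' experiment.
#'
#' @param folds Output of [fold_stimulated()].
#' @param wildtype Wild-type construct label.
#' @return `folds` with an added `relative_fold` column.
#' @export
normalize_to_wt <- function(folds, wildtype = "WT") {
  stop_if_not(all(c("construct", "experiment", "fold_stimulated") %in%
                    names(folds)), "expected output of fold_stimulated()")
  out <- folds
  out$relative_fold <- NA_real_
  for (e in unique(folds$experiment)) {
    idx <- folds$experiment == e
    wt <- folds$fold_stimulated[idx & folds$construct == wildtype]
    if (length(wt) != 1)
      stop("experiment ", e, " lacks a unique wild-type ('", wildtype,
           "') fold", call. = FALSE)
    out$relative_fold[idx] <- folds$fold_stimulated[idx] / wt
  }
  out
}

#' One-way ANOVA across construct groups
#'
#' Standard between/within sums-of-squares F test with a pooled (equal)
#' variance, as applied to per-experiment relative folds.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/character of the same length; at least two
#'   groups with at least two observations each.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  stop_if_not(nlevels(groups) >= 2, "need at least two groups")
  stop_if_not(all(table(groups) >= 2),
              "every group needs at least two observations")
  stop_if_not(all(is.finite(values)), "values must be finite")
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1]),
       df2 = unname(ht$parameter[2]), p = unname(ht$p.value))
}

#' Dunnett many-to-one comparisons by Monte Carlo
#'
#' Compares each treatment group mean against the shared control using
#' pooled-variance t statistics, and adjusts for the correlated family by
#' Monte Carlo sampling of the null max-|t| distribution: group means are
#' drawn as independent normals scaled by `1/sqrt(n_i)`, the pooled variance
#' as a scaled chi-square with the error degrees of freedom, and each
#' comparison's adjusted p-value is the null probability that the family
#' maximum of |t| exceeds its observed |t|. Adjusted p-values are floored at
#' the unadjusted two-sided p so the adjustment never increases apparent
#' evidence, and are seed-reproducible.
#'
#' @param values Numeric response vector.
#' @param groups Grouping factor/character of the same length.
#' @param control Label of the control group.
#' @param n_mc Number of Monte Carlo draws (>= 10^4).
#' @param seed Integer seed for the Monte Carlo stream; the caller's RNG
#'   state is left untouched.
#' @return `data.frame` with one row per non-control group: `comparison`,
#'   `estimate` (mean difference from control), `t`, `p_unadjusted`,
#'   `p_adjusted`.
#' @export
dunnett_vs_control <- function(values, groups, control, n_mc = 1e5,
                               seed = 1) {
  groups <- factor(groups)
  stop_if_not(control %in% levels(groups),
              "control group '", control, "' not present")
  stop_if_not(nlevels(groups) >= 2, "need at least one treatment group")
  stop_if_not(n_mc >= 1e4, "n_mc must be at least 10^4")
  stop_if_not(all(is.finite(values)), "values must be finite")
  ni <- table(groups)
  stop_if_not(all(ni >= 2), "every group needs at least two observations")
  means <- tapply(values, groups, mean)
  sse <- sum(tapply(values, groups,
                    function(x) sum((x - mean(x))^2)))
  df <- length(values) - nlevels(groups)
  s2 <- sse / df
  stop_if_not(s2 > 0, "zero pooled variance; comparisons are degenerate")
  trt <- setdiff(levels(groups), control)
  n_trt <- as.numeric(ni[trt])
  n_ctl <- as.numeric(ni[[control]])
  se <- sqrt(s2 * (1 / n_trt + 1 / n_ctl))
  tstat <- as.numeric(means[trt] - means[control]) / se
  p_unadj <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  maxT <- with_seed(seed, {
    m <- length(trt)
    z0 <- stats::rnorm(n_mc, sd = sqrt(1 / n_ctl))
    zt <- matrix(stats::rnorm(n_mc * m), n_mc, m)
    zt <- sweep(zt, 2, sqrt(1 / n_trt), "*")
    sfac <- sqrt(stats::rchisq(n_mc, df) / df)
    tnull <- abs(zt - z0) / rep(sfac, times = m)
    tnull <- sweep(tnull, 2, sqrt(1 / n_trt + 1 / n_ctl), "/")
    apply(tnull, 1, max)
  })
  p_adj <- vapply(abs(tstat), function(t0) mean(maxT >= t0), numeric(1))
  p_adj <- pmin(1, pmax(p_adj, p_unadj))
  data.frame(comparison = paste(trt, "-", control),
             estimate = unname(means[trt] - means[control]),
             t = unname(tstat),
             p_unadjusted = unname(p_unadj),
             p_adjusted = unname(p_adj),
             stringsAsFactors = FALSE)
}

#' Sidak multiple-comparison adjustment
#'
#' @param p Unadjusted p-value(s) in `[0, 1]`.
#' @param m Number of comparisons in the family (>= 1).
#' @return `1 - (1 - p)^m`, capped at 1.
#' @examples
#' sidak_adjust(0.05, 3)  # 0.142625
#' @export
sidak_adjust <- function(p, m) {
  stop_if_not(all(is.finite(p)) && all(p >= 0 & p <= 1),
              "p must lie in [0, 1]")
  stop_if_not(length(m) == 1 && is.finite(m) && m >= 1,
              "m must be a single count >= 1")
  pmin(1, 1 - (1 - p)^m)
}

#' Full dual-luciferase reporter analysis
#'
#' Runs the complete chain on a well table: per-well RLU, replicate
#' averaging, per-construct-per-experiment fold stimulated, normalization to
#' the wild type of each experiment, then one-way ANOVA over constructs and
#' Monte Carlo Dunnett comparisons of each construct against the wild type.
#' Observations for the statistics are the per-experiment relative folds
#' (one value per construct per experiment).
#'
#' @inheritParams fold_stimulated
#' @param wildtype Wild-type construct label (the Dunnett control).
#' @param n_mc,seed Monte Carlo settings for [dunnett_vs_control()].
#' @return Object of class `"reporter_assay"`: `folds`, `relative`
#'   (per-experiment relative folds), `estimates` (per-construct mean, SEM,
#'   n), `anova`, and `comparisons` (Dunnett table).
#' @export
reporter_assay <- function(wells, wildtype = "WT", n_mc = 1e5, seed = 1) {
  folds <- fold_stimulated(wells)
  rel <- normalize_to_wt(folds, wildtype)
  est <- do.call(rbind, lapply(split(rel, rel$construct), function(d)
    data.frame(construct = d$construct[1],
               mean_relative_fold = mean(d$relative_fold),
               sem = stats::sd(d$relative_fold) / sqrt(nrow(d)),
               n = nrow(d), stringsAsFactors = FALSE)))
  rownames(est) <- NULL
  anova <- one_way_anova(rel$relative_fold, rel$construct)
  comparisons <- dunnett_vs_control(rel$relative_fold, rel$construct,
                                    control = wildtype, n_mc = n_mc,
                                    seed = seed)
  structure(list(folds = folds, relative = rel, estimates = est,
                 anova = anova, comparisons = comparisons,
                 wildtype = wildtype),
            class = "reporter_assay")
}

#' @export
print.reporter_assay <- function(x, ...) {
  cat("Dual-luciferase reporter analysis (fold stimulated, relative to ",
      x$wildtype, ")\n", sep = "")
  est <- x$estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-10s %.3g +/- %.2g (n = %d)\n", est$construct[i],
                est$mean_relative_fold[i], est$sem[i], est$n[i]))
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
              x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  cat("Dunnett vs", x$wildtype, "(Monte Carlo):\n")
  cmp <- x$comparisons
  for (i in seq_len(nrow(cmp)))
    cat(sprintf("  %-16s diff %+.3g  adj. p = %.3g\n", cmp$comparison[i],
                cmp$estimate[i], cmp$p_adjusted[i]))
  invisible(x)
}

#' @export
summary.reporter_assay <- function(object, ...) print(object, ...)

#' @export
plot.reporter_assay <- function(x, ...) {
  est <- x$estimates
  bp <- graphics::barplot(est$mean_relative_fold, names.arg = est$construct,
                          ylab = "fold stimulated (relative to WT)",
                          ylim = c(0, max(est$mean_relative_fold +
                                            2 * est$sem, na.rm = TRUE)), ...)
  graphics::arrows(bp, est$mean_relative_fold - est$sem,
                   bp, est$mean_relative_fold + est$sem,
                   angle = 90, code = 3, length = 0.05)
  invisible(x)
}
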