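# Combined variant-effect-predictor (VEP) damage score: percentile
# normalization of raw predictor scores against a gene-specific reference
# background, averaged across predictors.

#' Catalog of variant-effect predictors
#'
#' The default catalog lists seven top-performing missense predictors with
#' the orientation of their native scales: `higher_is_damaging` is `TRUE`
#' when a larger raw score indicates a more damaging variant (REVEL,
#' ClinPred, MetaRNN, VARITY), and `FALSE` for log-likelihood-style scores
#' where more negative means more damaging (DeepSequence, ESM-1v). The
#' catalog is plain data and can be edited or replaced to accommodate other
#' predictors.
#'
#' @param names Predictor names.
#' @param higher_is_damaging Logical vector, one flag per predictor.
#' @return A `data.frame` of class `"predictor_catalog"` with columns
#'   `name` and `higher_is_damaging`.
#' @export
predictor_catalog <- function(names = c("DeepSequence", "VARITY_R",
                                        "VARITY_ER", "ESM-1v", "MetaRNN",
                                        "ClinPred", "REVEL"),
                              higher_is_damaging = c(FALSE, TRUE, TRUE,
                                                     FALSE, TRUE, TRUE,
                                                     TRUE)) {
  stop_if_not(length(names) >= 1 && length(names) == length(higher_is_damaging),
              "catalog needs one orientation flag per predictor")
  stop_if_not(!anyNA(higher_is_damaging),
              "orientation must be defined for every predictor")
  stop_if_not(!anyDuplicated(names), "duplicate predictor names")
  structure(data.frame(name = as.character(names),
                       higher_is_damaging = as.logical(higher_is_damaging),
                       stringsAsFactors = FALSE),
            class = c("predictor_catalog", "data.frame"))
}

#' Percentile-normalize one raw predictor score
#'
#' Returns the fraction of the reference background predicted to be less
#' damaging than the variant of interest, after orienting the scale so that
#' larger means more damaging. Exact ties count one half (mid-rank), so a
#' background member scores 0.5 against its own distribution.
#'
#' @param raw Raw predictor score (finite scalar).
#' @param background Numeric vector of raw scores for the gene's reference
#'   missense variants (non-empty, finite).
#' @param higher_is_damaging Orientation of the predictor's native scale.
#' @return Fraction in `[0, 1]`.
#' @examples
#' normalize_score(2, c(1, 2, 2, 3))  # (1 + 0.5 * 2) / 4 = 0.5
#' @export
normalize_score <- function(raw, background, higher_is_damaging = TRUE) {
  stop_if_not(is.numeric(raw) && length(raw) == 1 && is.finite(raw),
              "raw score must be a single finite number")
  stop_if_not(length(background) >= 1 && all(is.finite(background)),
              "background must be a non-empty finite score vector")
  if (!higher_is_damaging) {
    raw <- -raw
    background <- -background
  }
  (sum(background < raw) + 0.5 * sum(background == raw)) / length(background)
}

#' Combined VEP damage score for one variant
#'
#' Percentile-normalizes the variant's raw score against the gene-specific
#' background separately for each predictor, then averages the normalized
#' values over the predictors for which both a raw score and a background
#' are available. Missing predictors are excluded from the mean (no
#' imputation) and reflected in `n_used`.
#'
#' @param raw_scores Named numeric vector of raw predictor scores; `NA`
#'   marks a missing prediction.
#' @param backgrounds Named list of numeric vectors: per-predictor raw
#'   scores of the gene's reference missense variants.
#' @param catalog A [predictor_catalog()].
#' @return An object of class `"damage_score"`: per-predictor normalized
#'   values, `combined` (their unweighted mean), and `n_used`.
#' @export
combined_damage_score <- function(raw_scores, backgrounds,
                                  catalog = predictor_catalog()) {
  stop_if_not(inherits(catalog, "predictor_catalog"),
              "catalog must come from predictor_catalog()")
  stop_if_not(!is.null(names(raw_scores)),
              "raw_scores must be named by predictor")
  per <- stats::setNames(rep(NA_real_, nrow(catalog)), catalog$name)
  for (i in seq_len(nrow(catalog))) {
    p <- catalog$name[i]
    raw <- raw_scores[[p]] %||% NA_real_
    bg <- backgrounds[[p]]
    if (is.null(bg) || !is.finite(raw)) next
    per[p] <- normalize_score(raw, bg, catalog$higher_is_damaging[i])
  }
  used <- is.finite(per)
  if (!any(used))
    stop("no predictor has both a raw score and a background", call. = FALSE)
  structure(list(per_predictor = per,
                 combined = mean(per[used]),
                 n_used = sum(used)),
            class = "damage_score")
}

#' @export
print.damage_score <- function(x, ...) {
  cat("Combined VEP damage score\n")
  for (p in names(x$per_predictor))
    cat(sprintf("  %-14s %s\n", p,
                if (is.finite(x$per_predictor[p]))
                  sprintf("%.3f", x$per_predictor[p]) else "missing"))
  cat(sprintf("  combined: %.3f over %d predictor(s)\n",
              x$combined, x$n_used))
  invisible(x)
}

#' Classify a combined damage score as damaging
#'
#' @param score Combined damage score(s) in `[0, 1]` (numeric or a
#'   `"damage_score"` object).
#' @param threshold Inclusive threshold; the default calls a variant
#'   damaging at a combined score of 0.7 or more.
#' @return Logical, `TRUE` when `score >= threshold`.
#' @export
classify_damaging <- function(score, threshold = 0.7) {
  if (inherits(score, "damage_score")) score <- score$combined
  stop_if_not(all(is.finite(score)) && all(score >= 0 & score <= 1),
              "score must lie in [0, 1]")
  stop_if_not(is.finite(threshold) && threshold >= 0 && threshold <= 1,
              "threshold must lie in [0, 1]")
  score >= threshold
}
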