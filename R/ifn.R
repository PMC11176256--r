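# Interferon-signature scores: the six-gene RT-qPCR score and the 24-probe
# NanoString score, each with a control-derived positivity threshold.

#' Six-gene qPCR interferon-signature panel
#'
#' The panel scores six interferon-stimulated genes (ISGs) measured by
#' RT-qPCR, normalized to two housekeeping genes, with positivity defined
#' strictly above a fixed threshold (2.46, derived once from a reference
#' control cohort and carried as configuration).
#'
#' @param isgs The scored ISGs.
#' @param housekeeping The housekeeping genes averaged on the Ct scale.
#' @param threshold Positivity threshold on the median fold-change score.
#' @return A list of class `"qpcr_panel"`.
#' @export
qpcr_panel <- function(isgs = c("IFI27", "IFI44L", "IFIT1", "ISG15",
                                "RSAD2", "SIGLEC1"),
                       housekeeping = c("HPRT1", "18S"),
                       threshold = 2.46) {
  stop_if_not(length(intersect(isgs, housekeeping)) == 0,
              "ISG and housekeeping panels must be disjoint")
  stop_if_not(is.finite(threshold) && threshold > 0,
              "threshold must be positive")
  structure(list(isgs = isgs, housekeeping = housekeeping,
                 threshold = threshold),
            class = "qpcr_panel")
}

#' 24-probe NanoString interferon-signature panel
#'
#' Scores 24 ISG probes against three reference probes, with per-run
#' positive/negative calibrators. The positivity threshold is derived from
#' the healthy-control cohort of the run as mean + 2 SD of the control
#' scores (sample SD, n-1 denominator); the reference control cohort of
#' record comprised 27 healthy controls and yielded 2.75.
#'
#' @param probes The 24 scored ISG probes.
#' @param reference_probes The three reference (housekeeping) probes.
#' @param published_threshold The threshold reported for the reference
#'   control cohort, carried for context only; scoring always recomputes
#'   the threshold from the controls supplied.
#' @return A list of class `"nanostring_panel"`.
#' @export
nanostring_panel <- function(probes = c("IFI27", "IFI44L", "IFIT1", "ISG15",
                                        "RSAD2", "SIGLEC1", "CMPK2",
                                        "DDX60", "EPSTI1", "FBXO39",
                                        "HERC5", "HES4", "IFI44", "IFI6",
                                        "IFIH1", "IRF7", "LAMP3", "LY6E",
                                        "MX1", "NRIR", "OAS1", "OASL",
                                        "OTOF", "SPATS2L"),
                             reference_probes = c("NRDC", "OTUD5", "TUBB"),
                             published_threshold = 2.75) {
  stop_if_not(length(probes) == 24, "panel requires 24 ISG probes")
  stop_if_not(length(reference_probes) == 3,
              "panel requires 3 reference probes")
  structure(list(probes = probes, reference_probes = reference_probes,
                 published_threshold = published_threshold),
            class = "nanostring_panel")
}

#' Relative expression from qPCR Ct values
#'
#' Technical replicates are averaged on the Ct scale, then each gene's
#' relative expression is `2^(-dCt)` with `dCt = Ct_gene - mean(Ct_HK)` over
#' the two housekeeping genes (arithmetic mean of Ct, i.e. geometric mean of
#' expression).
#'
#' @param ct Long-format `data.frame` with columns `sample`, `gene`, `ct`
#'   (replicate rows allowed).
#' @param panel A [qpcr_panel()].
#' @return Numeric matrix of relative expression, samples in rows, scored
#'   ISGs in columns.
#' @export
qpcr_relative_expression <- function(ct, panel = qpcr_panel()) {
  stop_if_not(all(c("sample", "gene", "ct") %in% names(ct)),
              "ct table needs columns sample, gene, ct")
  stop_if_not(all(is.finite(ct$ct)), "non-finite Ct value")
  mean_ct <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  samples <- unique(as.character(ct$sample))
  rel <- matrix(NA_real_, nrow = length(samples), ncol = length(panel$isgs),
                dimnames = list(samples, panel$isgs))
  for (s in samples) {
    rows <- mean_ct[mean_ct$sample == s, ]
    hk <- rows$ct[match(panel$housekeeping, rows$gene)]
    if (anyNA(hk))
      stop("sample ", s, " lacks housekeeping Ct for: ",
           paste(panel$housekeeping[is.na(hk)], collapse = ", "),
           call. = FALSE)
    gct <- rows$ct[match(panel$isgs, rows$gene)]
    if (anyNA(gct))
      stop("sample ", s, " lacks Ct for scored gene(s): ",
           paste(panel$isgs[is.na(gct)], collapse = ", "), call. = FALSE)
    rel[s, ] <- 2^(-(gct - mean(hk)))
  }
  rel
}

#' Per-gene fold change versus the control median
#'
#' @param rel Relative-expression matrix (samples x genes), e.g. from
#'   [qpcr_relative_expression()] or [nanostring_normalize()].
#' @param controls Character vector of control sample names (rows of
#'   `rel`); at least two controls per gene.
#' @return Matrix of the same shape: each entry divided by the per-gene
#'   median over the control rows.
#' @export
fold_vs_control_median <- function(rel, controls) {
  stop_if_not(length(controls) >= 2, "need at least 2 controls")
  stop_if_not(all(controls %in% rownames(rel)),
              "controls absent from the expression matrix: ",
              paste(setdiff(controls, rownames(rel)), collapse = ", "))
  med <- apply(rel[controls, , drop = FALSE], 2, stats::median)
  if (any(med <= 0))
    stop("control median is zero or negative for: ",
         paste(colnames(rel)[med <= 0], collapse = ", "), call. = FALSE)
  sweep(rel, 2, med, "/")
}

#' @keywords internal
#' @noRd
new_ifn_score <- function(folds, threshold, assay) {
  score <- stats::median(folds)
  structure(list(folds = folds, score = score, threshold = threshold,
                 positive = score > threshold, assay = assay),
            class = "ifn_score")
}

#' qPCR interferon score for one sample
#'
#' The score is the exact median of the six per-gene fold changes versus the
#' control medians; an even-length median is the mean of the two central
#' order statistics. Positivity is strict: score > threshold.
#'
#' @param folds Named numeric vector of per-gene folds for one sample (all
#'   six panel genes required), or a matrix of folds (samples x genes) as
#'   from [fold_vs_control_median()].
#' @param panel A [qpcr_panel()]; supplies the gene set and threshold.
#' @return For a vector, an `"ifn_score"` object; for a matrix, a
#'   `data.frame` with one row per sample (`sample`, `score`, `positive`).
#' @examples
#' ifn_score_qpcr(c(IFI27 = 9.63, IFI44L = 10, IFIT1 = 12, ISG15 = 15,
#'                  RSAD2 = 20, SIGLEC1 = 21.48))
#' @export
ifn_score_qpcr <- function(folds, panel = qpcr_panel()) {
  if (is.matrix(folds)) {
    res <- lapply(rownames(folds), function(s)
      ifn_score_qpcr(folds[s, ], panel))
    return(data.frame(sample = rownames(folds),
                      score = vapply(res, `[[`, numeric(1), "score"),
                      positive = vapply(res, `[[`, logical(1), "positive"),
                      stringsAsFactors = FALSE))
  }
  miss <- setdiff(panel$isgs, names(folds))
  if (length(miss) > 0)
    stop("fold change missing for gene(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  f <- folds[panel$isgs]
  stop_if_not(all(is.finite(f)) && all(f > 0), "folds must be positive")
  new_ifn_score(f, panel$threshold, assay = "qPCR")
}

#' @export
print.ifn_score <- function(x, ...) {
  cat(sprintf("%s interferon score: %.3g (threshold %.3g) -> %s\n",
              x$assay, x$score, x$threshold,
              if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' Normalize a NanoString run
#'
#' Three steps, in order: (1) background subtraction — the per-sample mean
#' of the negative calibrators is subtracted from every count and the
#' result floored at 1; (2) positive-calibrator scaling — each sample is
#' multiplied by (grand geometric mean of the per-sample positive-calibrator
#' geometric means) / (that sample's positive-calibrator geometric mean);
#' (3) reference-probe scaling — the analogous geometric-mean factor over
#' the three reference probes, computed after steps 1-2. A uniform
#' multiplicative distortion of a sample (including its calibrators) is
#' removed exactly when the additive background is zero.
#'
#' @param raw Long-format `data.frame` with columns `sample`, `probe`,
#'   `count`, `role` (one of `"isg"`, `"reference"`, `"pos_cal"`,
#'   `"neg_cal"`).
#' @param panel A [nanostring_panel()].
#' @return Normalized-count matrix, samples in rows, the 24 ISG probes in
#'   columns.
#' @export
nanostring_normalize <- function(raw, panel = nanostring_panel()) {
  stop_if_not(all(c("sample", "probe", "count", "role") %in% names(raw)),
              "count table needs columns sample, probe, count, role")
  stop_if_not(all(raw$role %in% c("isg", "reference", "pos_cal", "neg_cal")),
              "unknown probe role")
  stop_if_not(all(is.finite(raw$count)), "non-finite count")
  pos <- raw[raw$role == "pos_cal", ]
  if (nrow(pos) == 0 || any(pos$count <= 0))
    stop("positive calibrators must be present with positive counts",
         call. = FALSE)
  samples <- unique(as.character(raw$sample))
  pos_gm <- vapply(samples, function(s)
    geomean(pos$count[pos$sample == s]), numeric(1))
  stop_if_not(!anyNA(pos_gm), "positive calibrators missing for a sample")
  scale_pos <- geomean(pos_gm) / pos_gm

  neg <- raw[raw$role == "neg_cal", ]
  stop_if_not(nrow(neg) > 0 && all(neg$count >= 0),
              "negative calibrators must be present with non-negative counts")
  bg <- vapply(samples, function(s)
    mean(neg$count[neg$sample == s]), numeric(1))

  probes <- c(panel$probes, panel$reference_probes)
  mat <- matrix(NA_real_, length(samples), length(probes),
                dimnames = list(samples, probes))
  meas <- raw[raw$role %in% c("isg", "reference"), ]
  for (s in samples) {
    rows <- meas[meas$sample == s, ]
    cnt <- rows$count[match(probes, rows$probe)]
    if (anyNA(cnt))
      stop("sample ", s, " lacks counts for probe(s): ",
           paste(probes[is.na(cnt)], collapse = ", "), call. = FALSE)
    mat[s, ] <- pmax(cnt - bg[s], 1) * scale_pos[s]
  }
  ref_gm <- apply(mat[, panel$reference_probes, drop = FALSE], 1, geomean)
  scale_ref <- geomean(ref_gm) / ref_gm
  norm <- mat * scale_ref
  norm[, panel$probes, drop = FALSE]
}

#' NanoString interferon scores with a control-derived threshold
#'
#' Each sample's score is the median over the 24 probes of its fold change
#' versus the per-probe control medians. The positivity threshold is the
#' mean of the control scores plus twice their sample standard deviation
#' (n-1 denominator); positivity is strict (score > threshold).
#'
#' @param norm Normalized-count matrix from [nanostring_normalize()].
#' @param controls Character vector of healthy-control sample names (>= 2).
#' @param panel A [nanostring_panel()].
#' @return A list of class `"nanostring_ifn"`: per-sample `scores`
#'   data.frame (`sample`, `score`, `is_control`, `positive`), the derived
#'   `threshold`, and the control score mean/SD.
#' @export
ifn_score_nanostring <- function(norm, controls,
                                 panel = nanostring_panel()) {
  stop_if_not(length(controls) >= 2, "need at least 2 controls")
  folds <- fold_vs_control_median(norm, controls)
  score <- apply(folds[, panel$probes, drop = FALSE], 1, stats::median)
  ctrl <- score[controls]
  threshold <- mean(ctrl) + 2 * stats::sd(ctrl)
  structure(list(scores = data.frame(sample = names(score),
                                     score = unname(score),
                                     is_control = names(score) %in% controls,
                                     positive = unname(score) > threshold,
                                     stringsAsFactors = FALSE),
                 threshold = threshold,
                 control_mean = mean(ctrl), control_sd = stats::sd(ctrl)),
            class = "nanostring_ifn")
}

#' @export
print.nanostring_ifn <- function(x, ...) {
  cat(sprintf("NanoString interferon score: threshold %.3g (control mean %.3g + 2 x SD %.3g)\n",
              x$threshold, x$control_mean, x$control_sd))
  pats <- x$scores[!x$scores$is_control, , drop = FALSE]
  if (nrow(pats) > 0) {
    cat("Non-control samples:\n")
    for (i in seq_len(nrow(pats)))
      cat(sprintf("  %-12s %.3g -> %s\n", pats$sample[i], pats$score[i],
                  if (pats$positive[i]) "POSITIVE" else "negative"))
  }
  invisible(x)
}
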