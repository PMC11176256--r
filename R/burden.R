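# Qualifying-variant selection and the exact carrier gene-burden test.

QUALIFYING_CONSEQUENCES <- c("missense", "inframe_indel", "frameshift",
                             "stop_gain")
ALL_CONSEQUENCES <- c(QUALIFYING_CONSEQUENCES, "synonymous", "non_coding")

#' Construct a table of coding variant records
#'
#' Builds and validates the variant table consumed by the burden pipeline.
#' One row per variant, with population allele counts as reported by a
#' reference database such as gnomAD. A variant absent from the reference is
#' encoded as `allele_count = 0` with a valid (positive) `allele_number`, so
#' its frequency is 0, not undefined.
#'
#' @param gene Gene symbol.
#' @param coding_change HGVS c. string.
#' @param protein_change HGVS p. string (short form, e.g. `"L330R"`).
#' @param consequence One of `"missense"`, `"inframe_indel"`, `"frameshift"`,
#'   `"stop_gain"`, `"synonymous"`, `"non_coding"`.
#' @param allele_count Reference alternate-allele count (non-negative).
#' @param allele_number Reference total allele number (positive).
#' @param homozygote_count Reference homozygote count (non-negative;
#'   `2 * homozygote_count <= allele_count`).
#' @return A `data.frame` with one row per variant.
#' @examples
#' variant_records(gene = "UNC93B1", coding_change = "c.989T>G",
#'                 protein_change = "L330R", consequence = "missense",
#'                 allele_count = 8, allele_number = 1552226)
#' @export
variant_records <- function(gene, coding_change, protein_change, consequence,
                            allele_count, allele_number,
                            homozygote_count = 0L) {
  df <- data.frame(gene = as.character(gene),
                   coding_change = as.character(coding_change),
                   protein_change = as.character(protein_change),
                   consequence = as.character(consequence),
                   allele_count = as.integer(allele_count),
                   allele_number = as.integer(allele_number),
                   homozygote_count = as.integer(homozygote_count),
                   stringsAsFactors = FALSE)
  validate_variants(df)
  df
}

#' @keywords internal
#' @noRd
validate_variants <- function(df) {
  req <- c("gene", "protein_change", "consequence", "allele_count",
           "allele_number")
  missing_cols <- setdiff(req, names(df))
  stop_if_not(length(missing_cols) == 0,
              "variant table lacks columns: ",
              paste(missing_cols, collapse = ", "))
  if (is.null(df$homozygote_count)) df$homozygote_count <- 0L
  bad <- setdiff(unique(df$consequence), ALL_CONSEQUENCES)
  stop_if_not(length(bad) == 0,
              "unknown consequence class: ", paste(bad, collapse = ", "))
  stop_if_not(all(df$allele_number > 0),
              "allele_number must be positive (encode absent variants as ",
              "allele_count 0 with a valid allele_number)")
  stop_if_not(all(df$allele_count >= 0) &&
                all(df$allele_count <= df$allele_number),
              "need 0 <= allele_count <= allele_number")
  stop_if_not(all(2L * df$homozygote_count <= df$allele_count),
              "need 2 * homozygote_count <= allele_count")
  invisible(df)
}

#' Population allele frequency
#'
#' @param allele_count Alternate-allele count(s).
#' @param allele_number Total allele number(s); must be positive.
#' @return `allele_count / allele_number`, vectorized.
#' @examples
#' allele_frequency(8, 1552226)   # ~5.15e-06
#' @export
allele_frequency <- function(allele_count, allele_number) {
  stop_if_not(all(allele_number > 0),
              "allele_number must be positive; a variant absent from the ",
              "reference has allele_count 0, not allele_number 0")
  stop_if_not(all(allele_count >= 0 & allele_count <= allele_number),
              "need 0 <= allele_count <= allele_number")
  allele_count / allele_number
}

#' Render an allele frequency at a given number of significant figures
#'
#' Formats ultra-rare frequencies the way cohort reports print them, e.g.
#' `8/1,552,226` at one significant figure is `"5e-06"`.
#'
#' @param freq Numeric frequency in `[0, 1]`.
#' @param sig Significant figures (default 1).
#' @return Character scalar in scientific notation (or `"0"`).
#' @export
format_allele_frequency <- function(freq, sig = 1) {
  stop_if_not(is.finite(freq) && freq >= 0 && freq <= 1,
              "freq must be in [0, 1]")
  if (freq == 0) return("0")
  format(signif(freq, sig), scientific = TRUE)
}

#' Qualifying-variant filter criteria
#'
#' The qualifying filter keeps protein-altering variants whose population
#' minor allele frequency is strictly below `max_maf` (default 1e-5) and,
#' when per-variant damage scores are supplied to [select_qualifying()],
#' whose combined damage score is at least `min_damage_score` (default 0.7,
#' inclusive). All qualifying variants here are ultra-rare alternate
#' alleles, so the MAF is the alternate-allele frequency itself.
#'
#' @param max_maf Strict upper bound on allele frequency, in (0, 1).
#' @param qualifying_consequences Consequence classes that qualify; defaults
#'   to all protein-altering classes (everything except synonymous and
#'   non-coding).
#' @param min_damage_score Inclusive combined-damage-score threshold applied
#'   only when scores are supplied.
#' @return A list of class `"filter_criteria"`.
#' @export
filter_criteria <- function(max_maf = 1e-5,
                            qualifying_consequences = QUALIFYING_CONSEQUENCES,
                            min_damage_score = 0.7) {
  stop_if_not(is.numeric(max_maf) && length(max_maf) == 1 &&
                max_maf > 0 && max_maf < 1,
              "max_maf must be a single frequency in (0, 1)")
  stop_if_not(all(qualifying_consequences %in% ALL_CONSEQUENCES),
              "unknown consequence class in qualifying_consequences")
  if (!is.null(min_damage_score))
    stop_if_not(min_damage_score >= 0 && min_damage_score <= 1,
                "min_damage_score must lie in [0, 1]")
  structure(list(max_maf = max_maf,
                 qualifying_consequences = qualifying_consequences,
                 min_damage_score = min_damage_score),
            class = "filter_criteria")
}

#' Select qualifying variants
#'
#' Applies the ultra-rare qualifying filter: allele frequency strictly below
#' `criteria$max_maf`, consequence in the qualifying set, and — only if
#' `damage_scores` is supplied — combined damage score at or above
#' `criteria$min_damage_score`. Row order is preserved and the operation is
#' idempotent.
#'
#' @param variants Variant table as from [variant_records()].
#' @param criteria A [filter_criteria()] object.
#' @param damage_scores Optional numeric vector of combined damage scores,
#'   either named by `"<gene>:<protein_change>"` or unnamed with one value
#'   per row of `variants`. A variant passing the frequency and consequence
#'   filters but lacking a score is an error, never a silent pass.
#' @return The qualifying subset of `variants` (rows, order preserved).
#' @export
select_qualifying <- function(variants, criteria = filter_criteria(),
                              damage_scores = NULL) {
  validate_variants(variants)
  stop_if_not(inherits(criteria, "filter_criteria"),
              "criteria must come from filter_criteria()")
  af <- allele_frequency(variants$allele_count, variants$allele_number)
  keep <- af < criteria$max_maf &
    variants$consequence %in% criteria$qualifying_consequences
  if (!is.null(damage_scores) && !is.null(criteria$min_damage_score)) {
    key <- paste(variants$gene, variants$protein_change, sep = ":")
    if (is.null(names(damage_scores))) {
      stop_if_not(length(damage_scores) == nrow(variants),
                  "unnamed damage_scores must have one value per variant")
      sc <- damage_scores
    } else {
      sc <- unname(damage_scores[key])
    }
    unscored <- keep & !is.finite(sc)
    if (any(unscored))
      stop("damage score missing for qualifying variant(s): ",
           paste(key[unscored], collapse = ", "), call. = FALSE)
    keep <- keep & sc >= criteria$min_damage_score
  }
  variants[keep, , drop = FALSE]
}

#' Count carrier kindreds
#'
#' A kindred is a carrier if any member carries at least one qualifying
#' allele; each kindred counts at most once regardless of how many
#' qualifying variants it carries or of zygosity.
#'
#' @param genotypes Numeric matrix (or data.frame) of allele counts in
#'   `{0, 1, 2}`, kindreds in rows, qualifying variants in columns. A matrix
#'   with zero columns means no qualifying variants.
#' @return A list with `k` (carrier kindreds), `n` (kindreds), and
#'   `carrier_freq = k/n`.
#' @export
cohort_carrier_count <- function(genotypes) {
  g <- as.matrix(genotypes)
  stop_if_not(nrow(g) >= 1, "kindred set must be non-empty")
  stop_if_not(all(g %in% 0:2), "genotypes must be allele counts in {0,1,2}")
  k <- if (ncol(g) == 0) 0L else sum(rowSums(g > 0) > 0)
  list(k = as.integer(k), n = nrow(g), carrier_freq = k / nrow(g))
}

#' Cumulative background carrier frequency under Hardy-Weinberg
#'
#' For each qualifying reference variant with allele frequency `p`, the
#' carrier probability is `c = 2p(1-p) + p^2`. Assuming independent loci the
#' cumulative probability of carrying at least one qualifying allele is
#' `1 - prod(1 - c_i)`, which reduces to `sum(2 p_i)` in the ultra-rare
#' limit.
#'
#' @param reference_variants Reference variant table (as
#'   [variant_records()]); the qualifying filter is applied first.
#' @param criteria A [filter_criteria()] object (frequency and consequence
#'   filters only; damage scores are not consulted here).
#' @return Background carrier probability `p0` in `[0, 1]`; `0` with a
#'   warning when no reference variant qualifies.
#' @export
background_carrier_frequency <- function(reference_variants,
                                         criteria = filter_criteria()) {
  qual <- select_qualifying(reference_variants, criteria)
  if (nrow(qual) == 0) {
    warning("no qualifying reference variants; background carrier ",
            "frequency is 0", call. = FALSE)
    return(0)
  }
  p <- allele_frequency(qual$allele_count, qual$allele_number)
  carrier <- 2 * p * (1 - p) + p^2
  1 - prod(1 - carrier)
}

# Exact upper tail P(X >= k) for X ~ Binomial(n, p), by direct summation of
# log-scale point masses (safe for tails far below double underflow of the
# naive product).
#' @keywords internal
#' @noRd
binom_upper_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  lt <- lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' Exact carrier gene-burden test
#'
#' Tests enrichment of qualifying-variant carriers in a cohort against a
#' fixed background carrier probability, using the exact one-sided binomial
#' upper tail `P(X >= k | n, p0)`. The cohort unit is whatever `k` and `n`
#' count — kindreds by convention, so that a multiplex family contributes
#' once. An alternative Fisher-exact comparison against observed reference
#' carrier counts is available via `background_carriers`/`background_n`.
#'
#' @param k Carrier count in the cohort.
#' @param n Cohort size (kindreds).
#' @param p0 Background carrier probability, strictly inside (0, 1).
#' @param method `"binomial"` (exact tail against the fixed `p0`, the
#'   default) or `"fisher"` (conditional exact test against reference
#'   carrier counts).
#' @param background_carriers,background_n Reference carrier count and
#'   reference cohort size; required for `method = "fisher"`.
#' @return An object of class `"burden_test"` with cohort and background
#'   carrier frequencies, fold enrichment `(k/n)/p0`, and the one-sided
#'   p-value.
#' @examples
#' burden_test(5, 63, 0.004)
#' @export
burden_test <- function(k, n, p0, method = c("binomial", "fisher"),
                        background_carriers = NULL, background_n = NULL) {
  method <- match.arg(method)
  stop_if_not(is.numeric(k) && is.numeric(n) && k >= 0 && n >= 1 && k <= n,
              "need 0 <= k <= n with n >= 1")
  stop_if_not(is.numeric(p0) && length(p0) == 1 && p0 > 0 && p0 < 1,
              "p0 must lie strictly inside (0, 1)")
  k <- as.integer(k); n <- as.integer(n)
  if (method == "binomial") {
    p_value <- binom_upper_tail(k, n, p0)
  } else {
    stop_if_not(!is.null(background_carriers) && !is.null(background_n),
                "method = 'fisher' needs background_carriers and background_n")
    tab <- matrix(c(k, n - k, background_carriers,
                    background_n - background_carriers), nrow = 2)
    p_value <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  structure(list(carriers_cohort = k, units_cohort = n,
                 carrier_freq_cohort = k / n,
                 carrier_freq_background = p0,
                 fold_enrichment = (k / n) / p0,
                 p_value = p_value, method = method),
            class = "burden_test")
}

#' @export
print.burden_test <- function(x, ...) {
  cat("Carrier gene-burden test (", x$method, ")\n", sep = "")
  cat(sprintf("  cohort carriers:     %d / %d (%.1f%%)\n",
              x$carriers_cohort, x$units_cohort,
              100 * x$carrier_freq_cohort))
  cat(sprintf("  background carriers: %.4g\n", x$carrier_freq_background))
  cat(sprintf("  fold enrichment:     %.3g\n", x$fold_enrichment))
  cat(sprintf("  one-sided p-value:   %.3g\n", x$p_value))
  invisible(x)
}

#' @export
summary.burden_test <- function(object, ...) {
  print(object, ...)
}
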