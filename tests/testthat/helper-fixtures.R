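# Shared fixture builders; everything is generated in code at test time.

# A noise-free well table: `mult` maps constructs to fold-stimulated
# multipliers relative to WT, with `wt_fold` the WT stimulation fold.
make_wells <- function(mult = c(WT = 1, VAR = 3), wt_fold = 10,
                       experiments = 1:2, base_rlu = 2, renilla = 1e5) {
  rows <- list()
  for (e in experiments) for (cst in names(mult)) for (stim in c(FALSE, TRUE))
    for (r in 1:2) {
      rlu <- if (stim) base_rlu * wt_fold * mult[[cst]] else base_rlu
      rows[[length(rows) + 1]] <- data.frame(
        construct = cst, experiment = e, stimulated = stim, replicate = r,
        firefly = rlu * renilla, renilla = renilla,
        stringsAsFactors = FALSE)
    }
  do.call(rbind, rows)
}

# Brute-force binomial upper tail from point masses, kept deliberately
# naive and independent of the package's log-space summation.
brute_binom_tail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(choose(n, k:n) * p^(k:n) * (1 - p)^(n - (k:n)))
}

# Independent quartile oracle: linear interpolation of order statistics at
# h = (n - 1) p + 1, written from the definition.
oracle_quantile <- function(x, probs) {
  s <- sort(x)
  n <- length(s)
  vapply(probs, function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}
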