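# Aggregation of per-model folding free-energy changes into box statistics.

#' Box statistics of per-model free-energy changes
#'
#' Summarizes ddG values (kcal/mol) per variant and complex over the
#' structural models (typically five) as box statistics: median, quartiles
#' by linear interpolation of order statistics (the common plotting
#' default), and whiskers at the most extreme data points within 1.5 times
#' the interquartile range of the quartiles.
#'
#' @param records `data.frame` with columns `variant`, `complex`,
#'   `model_index`, `ddg`; `(variant, complex, model_index)` must be
#'   unique and every `ddg` finite.
#' @return `data.frame` with one row per variant x complex: `n`, `median`,
#'   `q25`, `q75`, `whisker_low`, `whisker_high`.
#' @examples
#' rec <- data.frame(variant = "L330R", complex = "TLR7",
#'                   model_index = 1:5, ddg = c(1, 2, 3, 4, 5))
#' summarize_ddg(rec)
#' @export
summarize_ddg <- function(records) {
  req <- c("variant", "complex", "model_index", "ddg")
  stop_if_not(all(req %in% names(records)),
              "ddG table needs columns: ", paste(req, collapse = ", "))
  stop_if_not(all(is.finite(records$ddg)), "ddg values must be finite")
  key <- paste(records$variant, records$complex, records$model_index)
  if (anyDuplicated(key))
    stop("duplicate (variant, complex, model_index): ",
         paste(unique(key[duplicated(key)]), collapse = "; "),
         call. = FALSE)
  grp <- interaction(records$variant, records$complex, drop = TRUE,
                     lex.order = TRUE)
  out <- lapply(split(records, grp), function(d) {
    q <- stats::quantile(d$ddg, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo <- min(d$ddg[d$ddg >= q[1] - 1.5 * iqr])
    hi <- max(d$ddg[d$ddg <= q[3] + 1.5 * iqr])
    data.frame(variant = d$variant[1], complex = d$complex[1],
               n = nrow(d), median = q[2], q25 = q[1], q75 = q[3],
               whisker_low = lo, whisker_high = hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Classify the predicted stability effect of a variant
#'
#' Negative ddG medians indicate the mutation is predicted to stabilize the
#' fold or complex, positive medians to destabilize it. The call uses a
#' symmetric tolerance band around zero (default 0.5 kcal/mol, an artifact
#' convention below which model noise dominates).
#'
#' @param x Median ddG value(s) (kcal/mol), or the summary `data.frame`
#'   from [summarize_ddg()].
#' @param tol Half-width of the neutral band, kcal/mol.
#' @return For numeric input, a character vector in `{"stabilizing",
#'   "neutral", "destabilizing"}`; for a summary table, the table with a
#'   `call` column appended.
#' @export
classify_stability <- function(x, tol = 0.5) {
  stop_if_not(is.finite(tol) && tol >= 0, "tol must be non-negative")
  if (is.data.frame(x)) {
    x$call <- classify_stability(x$median, tol)
    return(x)
  }
  stop_if_not(all(is.finite(x)), "median ddG must be finite")
  ifelse(x < -tol, "stabilizing",
         ifelse(x > tol, "destabilizing", "neutral"))
}

#' Read a FoldX difference table
#'
#' Tolerant parser for `Dif_*.fxout`-style tab tables produced by the FoldX
#' BuildModel command: header banner lines are skipped, the column header
#' row starting with `Pdb` is located, and the PDB label plus total-energy
#' column are returned. Model indices are taken from trailing digits of the
#' PDB label when present.
#'
#' @param path Path to the `.fxout` file (plain text, tab separated).
#' @return `data.frame` with columns `pdb`, `model_index`, `ddg`.
#' @export
read_fxout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^Pdb\\b", lines)
  stop_if_not(length(hdr) >= 1, "no 'Pdb' header row found in ", path)
  tab <- utils::read.delim(text = lines[hdr[1]:length(lines)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  energy_col <- grep("total energy", names(tab), ignore.case = TRUE)
  if (length(energy_col) == 0) energy_col <- 2L
  idx <- suppressWarnings(as.integer(sub(".*?([0-9]+)(\\.pdb)?$", "\\1",
                                         tab$Pdb)))
  data.frame(pdb = tab$Pdb, model_index = idx,
             ddg = as.numeric(tab[[energy_col[1]]]),
             stringsAsFactors = FALSE)
}
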