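# Worked-example fixture: the five ultra-rare UNC93B1 missense
# substitutions reported in probands with early-onset SLE or chilblain
# lupus, with their reference (gnomAD) allele counts and combined VEP
# damage scores, embedded in a 63-kindred cohort.

#' Example UNC93B1 cohort: five ultra-rare missense substitutions
#'
#' Returns the published five-variant UNC93B1 example used throughout the
#' documentation: one proband per variant in a cohort of 63 kindreds
#' (I317M homozygous, the others heterozygous), reference allele counts
#' (four variants absent from gnomAD, L330R at 8/1,552,226), and combined
#' VEP damage scores of 0.81, 0.93, 0.70, 0.86 and 0.93. The background
#' carrier frequency reported for qualifying UNC93B1 variants in gnomAD v4
#' is 0.4%.
#'
#' @return A list: `variants` (a [variant_records()] table), `genotypes`
#'   (63 kindreds x 5 variants allele-count matrix; one carrier kindred per
#'   variant), `damage_scores` (named by `"gene:protein_change"`), and
#'   `background_carrier_freq` (0.004).
#' @examples
#' ex <- unc93b1_example_cohort()
#' qual <- select_qualifying(ex$variants, filter_criteria(),
#'                           ex$damage_scores)
#' cc <- cohort_carrier_count(ex$genotypes)
#' burden_test(cc$k, cc$n, ex$background_carrier_freq)
#' @export
unc93b1_example_cohort <- function() {
  variants <- variant_records(
    gene = "UNC93B1",
    coding_change = c("c.1574_1575delinsCT", "c.989T>G", "c.951C>G",
                      "c.1398A>C", "c.973G>T"),
    protein_change = c("R525P", "L330R", "I317M", "R466S", "G325C"),
    consequence = "missense",
    allele_count = c(0L, 8L, 0L, 0L, 0L),
    allele_number = 1552226L,
    homozygote_count = 0L)
  damage_scores <- stats::setNames(
    c(0.81, 0.93, 0.70, 0.86, 0.93),
    paste(variants$gene, variants$protein_change, sep = ":"))
  kindreds <- sprintf("K%03d", 1:63)
  genotypes <- matrix(0L, 63, 5,
                      dimnames = list(kindreds, variants$protein_change))
  # one proband kindred per variant; I317M was homozygous
  genotypes[cbind(1:5, 1:5)] <- c(1L, 1L, 2L, 1L, 1L)
  list(variants = variants, genotypes = genotypes,
       damage_scores = damage_scores, background_carrier_freq = 0.004)
}
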