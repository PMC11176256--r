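# Plain-text interchange: minimal VCF v4.2, TSV tables, YAML sidecars.

#' Write a variant table as minimal VCF v4.2
#'
#' Emits one record per variant (1-based positions) with population counts
#' and annotations in INFO: `AC`, `AN`, `nhomalt`, `GENE`, `CSQ`
#' (consequence class), `HGVSC`, `HGVSP`.
#'
#' @param variants Variant table with VCF-style columns (`chrom`, `pos`,
#'   `ref`, `alt`) plus the [variant_records()] fields, as produced by
#'   [simulate_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(variants, path) {
  validate_variants(variants)
  stop_if_not(all(c("chrom", "pos", "ref", "alt") %in% names(variants)),
              "VCF output needs chrom, pos, ref, alt columns")
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Reference alternate allele count\">",
           "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Reference total allele number\">",
           "##INFO=<ID=nhomalt,Number=1,Type=Integer,Description=\"Reference homozygote count\">",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
           "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
           "##INFO=<ID=HGVSC,Number=1,Type=String,Description=\"HGVS coding change\">",
           "##INFO=<ID=HGVSP,Number=1,Type=String,Description=\"HGVS protein change\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("AC=%d;AN=%d;nhomalt=%d;GENE=%s;CSQ=%s;HGVSC=%s;HGVSP=%s",
                  variants$allele_count, variants$allele_number,
                  variants$homozygote_count, variants$gene,
                  variants$consequence, variants$coding_change,
                  variants$protein_change)
  id <- variants$id %||% rep(".", nrow(variants))
  rec <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s", variants$chrom,
                 variants$pos, id, variants$ref, variants$alt, info)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read a minimal variant VCF back into a variant table
#'
#' Parses a VCF written by [write_variant_vcf()] (or any VCF carrying
#' `AC`/`AN`/`nhomalt`/`GENE`/`CSQ`/`HGVSC`/`HGVSP` INFO keys) through the
#' vcfR package.
#'
#' @param path Path to an uncompressed VCF v4.2 file.
#' @return Variant table as in [variant_records()], with `chrom`, `pos`,
#'   `ref`, `alt`, `id` columns prepended.
#' @export
read_variant_vcf <- function(path) {
  stop_if_not(requireNamespace("vcfR", quietly = TRUE),
              "read_variant_vcf() requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  grab <- function(key, numeric = FALSE) {
    x <- vcfR::extract.info(v, element = key)
    if (numeric) as.integer(x) else x
  }
  out <- data.frame(id = fix$ID, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF,
                    alt = fix$ALT,
                    gene = grab("GENE"),
                    coding_change = grab("HGVSC"),
                    protein_change = grab("HGVSP"),
                    consequence = grab("CSQ"),
                    allele_count = grab("AC", numeric = TRUE),
                    allele_number = grab("AN", numeric = TRUE),
                    homozygote_count = grab("nhomalt", numeric = TRUE),
                    stringsAsFactors = FALSE)
  validate_variants(out)
  out
}

#' Write/read a kindred genotype matrix as TSV
#'
#' Kindreds in rows (first column `kindred`), variants in columns, entries
#' are per-kindred qualifying-allele counts in `{0, 1, 2}`.
#'
#' @param genotypes Integer matrix with kindred rownames.
#' @param path File path.
#' @return `path` (write) or the genotype matrix (read).
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  df <- data.frame(kindred = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stop_if_not("kindred" %in% names(df),
              "genotype TSV needs a 'kindred' column")
  m <- as.matrix(df[, setdiff(names(df), "kindred"), drop = FALSE])
  rownames(m) <- df$kindred
  storage.mode(m) <- "integer"
  m
}

#' Write a ground-truth sidecar as YAML
#'
#' Simulated datasets carry their planted ground truth in a sidecar file,
#' never inferred from the data.
#'
#' @param truth Named list of ground-truth values.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_yaml <- function(truth, path) {
  yaml::write_yaml(lapply(truth, function(x)
    if (is.numeric(x) || is.character(x) || is.logical(x)) unname(x) else x),
    path)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) yaml::read_yaml(path)

#' @keywords internal
#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @keywords internal
#' @noRd
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
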