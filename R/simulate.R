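# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised offline on data with planted ground truth; the truth is carried
# alongside the data (and written as a YAML sidecar), never inferred from
# it. One global seed drives an independent substream per generator, so
# adding a generator never perturbs another's output.

#' Specification of a simulated candidate-gene cohort
#'
#' Emulates an exome-sequenced cohort of kindreds screened for ultra-rare
#' qualifying variants in one candidate gene: each kindred independently
#' carries one private qualifying variant with probability `carrier_prob`,
#' against a backdrop of non-qualifying noise variants (common alleles or
#' rare non-protein-altering ones).
#'
#' @param n_kindreds Number of kindreds (>= 1).
#' @param carrier_prob Per-kindred probability of carrying one qualifying
#'   variant, in `[0, 1]`.
#' @param n_noise_variants Number of non-qualifying variants.
#' @param background_af_range Allele-frequency interval for noise variants.
#' @param gene Candidate gene symbol used in the emitted tables.
#' @param seed Integer seed; output is reproducible under a fixed seed.
#' @return A list of class `"cohort_sim_spec"`.
#' @export
cohort_sim_spec <- function(n_kindreds = 63, carrier_prob = 0.08,
                            n_noise_variants = 20,
                            background_af_range = c(1e-4, 0.05),
                            gene = "GENE1", seed = 1) {
  stop_if_not(is.numeric(carrier_prob) && length(carrier_prob) == 1 &&
                carrier_prob >= 0 && carrier_prob <= 1,
              "carrier_prob must lie in [0, 1]")
  stop_if_not(n_kindreds >= 1, "n_kindreds must be at least 1")
  stop_if_not(n_noise_variants >= 0, "n_noise_variants must be non-negative")
  stop_if_not(length(background_af_range) == 2 &&
                all(background_af_range > 0 & background_af_range < 1) &&
                background_af_range[1] <= background_af_range[2],
              "background_af_range must be an increasing interval in (0, 1)")
  structure(list(n_kindreds = as.integer(n_kindreds),
                 carrier_prob = carrier_prob,
                 n_noise_variants = as.integer(n_noise_variants),
                 background_af_range = background_af_range,
                 gene = gene, seed = as.integer(seed)),
            class = "cohort_sim_spec")
}

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")

#' Simulate a cohort variant table with planted carriers
#'
#' Each carrier kindred receives one private heterozygous qualifying
#' missense variant (population allele count drawn so that the reference
#' frequency is below 1e-5, or 0 when absent from the reference). Noise
#' variants each fail at least one qualifying criterion: protein-altering
#' noise variants are common (frequency in `background_af_range`, floored
#' at 1e-5), and rare noise variants are synonymous or non-coding.
#'
#' @param spec A [cohort_sim_spec()].
#' @return A list of class `"cohort_sim"`: `variants` (variant table with
#'   VCF-style coordinates and population counts), `genotypes` (kindred x
#'   variant allele-count matrix), and `truth` (carrier kindreds and the
#'   planted carrier probability).
#' @export
simulate_cohort <- function(spec) {
  stop_if_not(inherits(spec, "cohort_sim_spec"),
              "spec must come from cohort_sim_spec()")
  with_seed(substream_seed(spec$seed, "cohort"), {
    kindreds <- sprintf("K%03d", seq_len(spec$n_kindreds))
    is_carrier <- stats::runif(spec$n_kindreds) < spec$carrier_prob
    carriers <- kindreds[is_carrier]
    n_q <- sum(is_carrier)
    an <- 1552226L

    n_var <- n_q + spec$n_noise_variants
    pos <- sort(sample.int(5e4, n_var)) + 1e6L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_var, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    aa_from <- sample(seq_along(AA1), n_var, replace = TRUE)
    aa_to <- vapply(aa_from, function(i)
      sample(setdiff(seq_along(AA1), i), 1), 0L)
    codon <- sample.int(600, n_var, replace = TRUE)

    variants <- data.frame(
      id = sprintf("var%03d", seq_len(n_var)),
      chrom = "11", pos = pos, ref = ref, alt = alt,
      gene = spec$gene,
      coding_change = sprintf("c.%d%s>%s", 3L * codon, ref, alt),
      protein_change = paste0(AA1[aa_from], codon, AA1[aa_to]),
      consequence = NA_character_,
      allele_count = NA_integer_, allele_number = an,
      homozygote_count = 0L, stringsAsFactors = FALSE)

    qual_idx <- seq_len(n_q)
    if (n_q > 0) {
      variants$consequence[qual_idx] <- "missense"
      # absent from the reference half the time, else AC giving MAF < 1e-5
      variants$allele_count[qual_idx] <- ifelse(
        stats::runif(n_q) < 0.5, 0L, sample.int(15L, n_q, replace = TRUE))
    }
    if (spec$n_noise_variants > 0) {
      noise_idx <- n_q + seq_len(spec$n_noise_variants)
      af <- stats::runif(spec$n_noise_variants,
                         spec$background_af_range[1],
                         spec$background_af_range[2])
      common <- af >= 1e-5
      cons <- ifelse(common,
                     sample(c("missense", "synonymous", "non_coding"),
                            spec$n_noise_variants, replace = TRUE),
                     sample(c("synonymous", "non_coding"),
                            spec$n_noise_variants, replace = TRUE))
      variants$consequence[noise_idx] <- cons
      variants$allele_count[noise_idx] <- pmax(1L, as.integer(round(af * an)))
    }

    genotypes <- matrix(0L, spec$n_kindreds, n_var,
                        dimnames = list(kindreds, variants$id))
    if (n_q > 0)
      genotypes[cbind(which(is_carrier), qual_idx)] <- 1L
    if (spec$n_noise_variants > 0) {
      noise_idx <- n_q + seq_len(spec$n_noise_variants)
      af <- variants$allele_count[noise_idx] / an
      for (j in seq_along(noise_idx))
        genotypes[, noise_idx[j]] <-
          stats::rbinom(spec$n_kindreds, 2, af[j])
    }
    validate_variants(variants)
    structure(list(variants = variants, genotypes = genotypes,
                   truth = list(carrier_kindreds = carriers,
                                n_carriers = n_q,
                                carrier_prob = spec$carrier_prob)),
              class = "cohort_sim")
  })
}

# Native-scale simulation parameters per predictor (location, spread);
# orientation comes from the catalog.
#' @keywords internal
#' @noRd
predictor_sim_params <- function(name) {
  switch(name,
         "DeepSequence" = c(-6, 3),   # delta ELBO, more negative = damaging
         "ESM-1v" = c(-8, 4),         # log-likelihood ratio, same
         c(0, 1))                     # [0, 1]-scaled meta-predictors
}

#' Simulate a per-predictor background score table
#'
#' Draws one raw score per predictor per reference missense variant on each
#' predictor's native scale (bounded Beta draws for [0, 1]-scaled
#' meta-predictors; Gaussian log-likelihood-style draws for DeepSequence and
#' ESM-1v, whose orientation is reversed).
#'
#' @param n_variants Number of background variants (>= 2).
#' @param catalog A [predictor_catalog()]; must be non-empty.
#' @param seed Integer seed.
#' @param generator Optional `function(n, predictor_name)` overriding the
#'   native-scale draw (e.g. a constant generator for degenerate tests).
#' @return `data.frame` with a `variant` column and one raw-score column
#'   per predictor.
#' @export
simulate_background_scores <- function(n_variants,
                                       catalog = predictor_catalog(),
                                       seed = 1, generator = NULL) {
  stop_if_not(n_variants >= 2, "n_variants must be at least 2")
  stop_if_not(inherits(catalog, "predictor_catalog") && nrow(catalog) >= 1,
              "catalog must be a non-empty predictor_catalog()")
  with_seed(substream_seed(seed, "background_scores"), {
    out <- data.frame(variant = sprintf("bg%05d", seq_len(n_variants)),
                      stringsAsFactors = FALSE)
    for (p in catalog$name) {
      if (!is.null(generator)) {
        out[[p]] <- generator(n_variants, p)
      } else {
        par <- predictor_sim_params(p)
        out[[p]] <- if (identical(par, c(0, 1)))
          stats::rbeta(n_variants, 2, 2)
        else stats::rnorm(n_variants, par[1], par[2])
      }
    }
    out
  })
}

#' Specification of a simulated expression experiment
#'
#' Shared by the qPCR and NanoString generators: patients carry a planted
#' multiplicative induction of every ISG (`injected_fold`), controls sit at
#' baseline, and housekeeping/reference genes are unshifted in both groups.
#'
#' @param n_patients,n_controls Sample counts (`n_controls >= 2`).
#' @param injected_fold Per-ISG multiplicative induction (scalar or named
#'   per gene/probe); must be positive.
#' @param ct_noise_sd Gaussian measurement noise on the Ct scale; the
#'   NanoString generator reuses it as log2-scale log-normal count noise.
#' @param hk_ct_mean Baseline housekeeping Ct.
#' @param seed Integer seed.
#' @return A list of class `"expression_sim_spec"`.
#' @export
expression_sim_spec <- function(n_patients = 4, n_controls = 29,
                                injected_fold = 10, ct_noise_sd = 0.2,
                                hk_ct_mean = 20, seed = 1) {
  stop_if_not(all(is.finite(injected_fold)) && all(injected_fold > 0),
              "injected_fold must be positive for every gene")
  stop_if_not(n_controls >= 2, "need at least 2 controls")
  stop_if_not(n_patients >= 1, "need at least 1 patient")
  stop_if_not(ct_noise_sd >= 0, "ct_noise_sd must be non-negative")
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 injected_fold = injected_fold,
                 ct_noise_sd = ct_noise_sd, hk_ct_mean = hk_ct_mean,
                 seed = as.integer(seed)),
            class = "expression_sim_spec")
}

#' @keywords internal
#' @noRd
expand_fold <- function(injected_fold, genes) {
  if (length(injected_fold) == 1 && is.null(names(injected_fold)))
    return(stats::setNames(rep(injected_fold, length(genes)), genes))
  stop_if_not(all(genes %in% names(injected_fold)),
              "injected_fold must cover every scored gene")
  injected_fold[genes]
}

#' Simulate an RT-qPCR Ct table
#'
#' Control samples sit at gene-specific baseline Ct values; patient ISG Ct
#' values are shifted down by `log2(injected_fold)` (one PCR cycle per
#' doubling); housekeeping genes are unshifted. A per-sample loading offset
#' is added to every gene of a sample (it cancels in the housekeeping
#' normalization), plus Gaussian Ct noise and two technical replicates per
#' measurement. With `ct_noise_sd = 0` the output is fully deterministic:
#' the loading offset is suppressed as well, so patient ISG Ct values sit
#' exactly `log2(injected_fold)` cycles below the control baseline.
#'
#' @param spec An [expression_sim_spec()].
#' @param panel A [qpcr_panel()].
#' @return A list of class `"qpcr_sim"`: `ct` (long table: `sample`,
#'   `group`, `gene`, `role`, `replicate`, `ct`) and `truth`.
#' @export
simulate_qpcr <- function(spec, panel = qpcr_panel()) {
  stop_if_not(inherits(spec, "expression_sim_spec"),
              "spec must come from expression_sim_spec()")
  fold <- expand_fold(spec$injected_fold, panel$isgs)
  with_seed(substream_seed(spec$seed, "qpcr"), {
    baseline <- stats::setNames(stats::runif(length(panel$isgs), 22, 28),
                                panel$isgs)
    hk_ct <- stats::setNames(c(spec$hk_ct_mean, spec$hk_ct_mean - 8),
                             panel$housekeeping)  # 18S is far more abundant
    samples <- c(sprintf("P%02d", seq_len(spec$n_patients)),
                 sprintf("C%02d", seq_len(spec$n_controls)))
    group <- rep(c("patient", "control"),
                 c(spec$n_patients, spec$n_controls))
    loading_sd <- if (spec$ct_noise_sd > 0) 0.3 else 0
    loading <- stats::rnorm(length(samples), 0, loading_sd)
    rows <- list()
    for (i in seq_along(samples)) {
      shift <- if (group[i] == "patient") log2(fold) else 0 * fold
      genes <- c(panel$isgs, panel$housekeeping)
      role <- rep(c("isg", "housekeeping"),
                  c(length(panel$isgs), length(panel$housekeeping)))
      mu <- c(baseline - shift, hk_ct) + loading[i]
      for (r in 1:2)
        rows[[length(rows) + 1]] <- data.frame(
          sample = samples[i], group = group[i], gene = genes, role = role,
          replicate = r,
          ct = mu + stats::rnorm(length(mu), 0, spec$ct_noise_sd),
          stringsAsFactors = FALSE)
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    structure(list(ct = ct,
                   truth = list(injected_fold = fold,
                                patients = samples[group == "patient"],
                                controls = samples[group == "control"])),
              class = "qpcr_sim")
  })
}

#' Simulate a NanoString run
#'
#' Counts are generated per probe around probe-specific baselines with
#' log-normal noise (`sdlog = ct_noise_sd * log(2)`, the Ct-scale noise
#' mapped to the log2 count scale), multiplied by a per-sample scale
#' distortion that also affects the calibrators (so positive-calibrator
#' normalization is non-trivial), plus an additive per-sample background
#' captured by the negative calibrators. Patients carry `injected_fold` on
#' the ISG probes only.
#'
#' @param spec An [expression_sim_spec()].
#' @param panel A [nanostring_panel()].
#' @param distortion_sdlog Log-scale SD of the per-sample multiplicative
#'   distortion (0 disables it).
#' @param background_mean Mean of the additive per-sample background counts
#'   (0 disables it).
#' @return A list of class `"nanostring_sim"`: `counts` (long table:
#'   `sample`, `group`, `probe`, `role`, `count`) and `truth`.
#' @export
simulate_nanostring <- function(spec, panel = nanostring_panel(),
                                distortion_sdlog = 0.3,
                                background_mean = 10) {
  stop_if_not(inherits(spec, "expression_sim_spec"),
              "spec must come from expression_sim_spec()")
  stop_if_not(distortion_sdlog >= 0 && background_mean >= 0,
              "distortion_sdlog and background_mean must be non-negative")
  fold <- expand_fold(spec$injected_fold, panel$probes)
  with_seed(substream_seed(spec$seed, "nanostring"), {
    base_isg <- stats::setNames(
      exp(stats::runif(length(panel$probes), log(200), log(5000))),
      panel$probes)
    base_ref <- stats::setNames(
      exp(stats::runif(3, log(1000), log(8000))), panel$reference_probes)
    pos_cal <- stats::setNames(c(32768, 8192, 2048, 512, 128, 32) * 4,
                               sprintf("POS_%s", LETTERS[1:6]))
    neg_cal <- stats::setNames(rep(0, 8), sprintf("NEG_%s", LETTERS[1:8]))
    samples <- c(sprintf("P%02d", seq_len(spec$n_patients)),
                 sprintf("C%02d", seq_len(spec$n_controls)))
    group <- rep(c("patient", "control"),
                 c(spec$n_patients, spec$n_controls))
    sdlog <- spec$ct_noise_sd * log(2)
    distort <- if (distortion_sdlog > 0)
      stats::rlnorm(length(samples), 0, distortion_sdlog) else
        rep(1, length(samples))
    bg <- if (background_mean > 0)
      stats::runif(length(samples), 0.5, 1.5) * background_mean else
        rep(0, length(samples))
    rows <- list()
    for (i in seq_along(samples)) {
      isg_mu <- base_isg * (if (group[i] == "patient") fold else 1)
      probes <- c(names(isg_mu), names(base_ref), names(pos_cal),
                  names(neg_cal))
      role <- rep(c("isg", "reference", "pos_cal", "neg_cal"),
                  c(length(isg_mu), 3L, 6L, 8L))
      mu <- c(isg_mu, base_ref, pos_cal, neg_cal)
      noise <- if (sdlog > 0)
        stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog) else rep(1, length(mu))
      count <- mu * noise * distort[i] + bg[i] * distort[i]
      rows[[length(rows) + 1]] <- data.frame(
        sample = samples[i], group = group[i], probe = probes, role = role,
        count = count, stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- NULL
    structure(list(counts = counts,
                   truth = list(injected_fold = fold,
                                patients = samples[group == "patient"],
                                controls = samples[group == "control"],
                                distortion = stats::setNames(distort,
                                                             samples))),
              class = "nanostring_sim")
  })
}

#' Specification of a simulated dual-luciferase plate series
#'
#' @param constructs Construct labels; must include exactly one wild type.
#' @param effect_multiplier Named per-construct fold-stimulated multiplier
#'   relative to wild type; the wild-type multiplier is 1 by definition
#'   (filled in or checked).
#' @param replicate_cv Coefficient of variation of the log-normal
#'   luminescence noise (>= 0).
#' @param n_experiments Number of independent experiments.
#' @param wildtype Wild-type label.
#' @param seed Integer seed.
#' @return A list of class `"plate_sim_spec"`.
#' @export
plate_sim_spec <- function(constructs = c("EV", "WT", "VAR"),
                           effect_multiplier = c(EV = 0.2, WT = 1,
                                                 VAR = 3),
                           replicate_cv = 0.1, n_experiments = 4,
                           wildtype = "WT", seed = 1) {
  stop_if_not(wildtype %in% constructs,
              "constructs must include the wild-type label '", wildtype, "'")
  stop_if_not(sum(constructs == wildtype) == 1,
              "exactly one wild-type construct")
  miss <- setdiff(constructs, names(effect_multiplier))
  if (identical(miss, wildtype))
    effect_multiplier[wildtype] <- 1
  else stop_if_not(length(miss) == 0,
                   "effect_multiplier missing for: ",
                   paste(miss, collapse = ", "))
  stop_if_not(isTRUE(all.equal(unname(effect_multiplier[wildtype]), 1)),
              "wild-type multiplier is 1 by definition")
  stop_if_not(all(effect_multiplier > 0), "multipliers must be positive")
  stop_if_not(replicate_cv >= 0, "replicate_cv must be non-negative")
  stop_if_not(n_experiments >= 1, "n_experiments must be at least 1")
  structure(list(constructs = constructs,
                 effect_multiplier = effect_multiplier[constructs],
                 replicate_cv = replicate_cv,
                 n_experiments = as.integer(n_experiments),
                 wildtype = wildtype, seed = as.integer(seed)),
            class = "plate_sim_spec")
}

#' Simulate a dual-luciferase well table
#'
#' Per experiment, a shared baseline unstimulated RLU and wild-type
#' stimulation fold are drawn; each construct's expected fold stimulated is
#' the wild-type fold times its planted multiplier. Wells carry Renilla
#' readings (with unit-mean log-normal noise at `replicate_cv`) and Firefly
#' readings equal to Renilla x true RLU x independent noise, in duplicate
#' for stimulated and unstimulated conditions.
#'
#' @param spec A [plate_sim_spec()].
#' @return A list of class `"plate_sim"`: `wells` (long table with
#'   `construct`, `tlr`, `stimulus`, `stimulated`, `experiment`,
#'   `replicate`, `firefly`, `renilla`) and `truth`.
#' @export
simulate_reporter_plate <- function(spec) {
  stop_if_not(inherits(spec, "plate_sim_spec"),
              "spec must come from plate_sim_spec()")
  with_seed(substream_seed(spec$seed, "reporter_plate"), {
    rows <- list()
    for (e in seq_len(spec$n_experiments)) {
      base_rlu <- exp(stats::rnorm(1, 0, 0.2))
      wt_fold <- 20 * exp(stats::rnorm(1, 0, 0.2))
      for (cst in spec$constructs) {
        truth_rlu <- c(unstim = base_rlu,
                       stim = base_rlu * wt_fold *
                         spec$effect_multiplier[[cst]])
        for (cond in names(truth_rlu)) for (r in 1:2) {
          renilla <- 1e5 * rlnoise(1, spec$replicate_cv)
          firefly <- renilla * truth_rlu[[cond]] *
            rlnoise(1, spec$replicate_cv)
          rows[[length(rows) + 1]] <- data.frame(
            construct = cst, tlr = "TLR7", stimulus = "R848",
            stimulated = cond == "stim", experiment = e, replicate = r,
            firefly = firefly, renilla = renilla,
            stringsAsFactors = FALSE)
        }
      }
    }
    wells <- do.call(rbind, rows)
    rownames(wells) <- NULL
    structure(list(wells = wells,
                   truth = list(effect_multiplier = spec$effect_multiplier,
                                wildtype = spec$wildtype)),
              class = "plate_sim")
  })
}

#' Simulate per-model ddG records
#'
#' Draws `n_models` ddG values per variant x complex from a normal
#' distribution with the planted per-variant mean and SD, mimicking the
#' spread over independently predicted structural models.
#'
#' @param truth `data.frame` with columns `variant`, `complex`, `mean`,
#'   `sd` (kcal/mol).
#' @param n_models Models per variant x complex (>= 1).
#' @param seed Integer seed.
#' @return A list of class `"ddg_sim"`: `records` (as consumed by
#'   [summarize_ddg()]) and `truth`.
#' @export
simulate_ddg <- function(truth, n_models = 5, seed = 1) {
  stop_if_not(all(c("variant", "complex", "mean", "sd") %in% names(truth)),
              "truth needs columns variant, complex, mean, sd")
  stop_if_not(n_models >= 1, "n_models must be at least 1")
  stop_if_not(all(truth$sd >= 0), "sd must be non-negative")
  with_seed(substream_seed(seed, "ddg"), {
    recs <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i)
      data.frame(variant = truth$variant[i], complex = truth$complex[i],
                 model_index = seq_len(n_models),
                 ddg = stats::rnorm(n_models, truth$mean[i], truth$sd[i]),
                 stringsAsFactors = FALSE)))
    rownames(recs) <- NULL
    structure(list(records = recs, truth = truth), class = "ddg_sim")
  })
}
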