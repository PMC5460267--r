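#' Configuration of the synthetic GWAS study
#'
#' Describes the simulated study design: two correlated quantitative base
#' traits (HDL-like and LDL-like) observed only through summary statistics
#' with sampling noise matching a large base GWAS, and an individual-level
#' binary target cohort whose liability shares a tunable fraction of causal
#' variants with the base traits. Genotypes have block-wise LD. Defaults
#' mirror the study design the pipeline targets: a very large base sample
#' (n = 188,577) so base effect estimates are precise, and a case fraction
#' near 0.31 (5,333 cases among 17,352 subjects), at a desk-scale SNP and
#' target-sample count.
#'
#' @param n_snps total SNP count.
#' @param n_blocks number of LD blocks (`<= n_snps`); SNPs are split evenly.
#' @param within_block_r latent exchangeable correlation within a block,
#'   in `[0, 1)`.
#' @param maf_range range the per-SNP allele-b frequency is drawn from,
#'   within (0, 0.5].
#' @param n_base effective base-GWAS sample size (drives the sampling
#'   standard error of the simulated betas).
#' @param n_target target cohort size.
#' @param case_fraction fraction of target samples ascertained as cases,
#'   in (0, 1).
#' @param h2_base variance of each base trait explained by its causal SNPs,
#'   in `[0, 1)`.
#' @param h2_liability heritability of the target liability, in `[0, 1)`.
#' @param shared_fraction fraction of target causal SNPs drawn from the
#'   base-causal set, in `[0, 1]`.
#' @param sign_mix probability that a causal SNP's HDL- and LDL-like
#'   effects have concordant sign.
#' @param n_causal number of causal SNPs per base trait (the target gets
#'   the same total count, split `shared_fraction` /
#'   `1 - shared_fraction`).
#' @param effect_dist distribution of causal standardized effects:
#'   `"gaussian"` (default, a polygenic architecture with many weak
#'   effects) or `"fixed"` (a spike architecture — equal magnitudes,
#'   random signs — which confines the base signal cleanly below a
#'   p-value threshold when `n_base` is chosen accordingly).
#' @param target_shared_group optionally restrict the target-shared causal
#'   SNPs to one beta-sign group (see [beta_sign_groups()]), judged on the
#'   true effect signs.
#' @param spacing_bp physical distance between adjacent SNPs.
#' @param seed master seed; each simulation stage uses a sub-seed derived
#'   from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 10000L, n_blocks = 100L,
                       within_block_r = 0.7, maf_range = c(0.05, 0.5),
                       n_base = 188577L, n_target = 4000L,
                       case_fraction = 0.31, h2_base = 0.3,
                       h2_liability = 0.3, shared_fraction = 0.3,
                       sign_mix = 0.5, n_causal = 200L,
                       effect_dist = c("gaussian", "fixed"),
                       target_shared_group = NULL, spacing_bp = 5000L,
                       seed = 1L) {
  effect_dist <- match.arg(effect_dist)
  cfg <- list(n_snps = as.integer(n_snps), n_blocks = as.integer(n_blocks),
              within_block_r = within_block_r,
              maf_range = as.numeric(maf_range),
              n_base = as.numeric(n_base), n_target = as.integer(n_target),
              case_fraction = case_fraction, h2_base = h2_base,
              h2_liability = h2_liability,
              shared_fraction = shared_fraction, sign_mix = sign_mix,
              n_causal = as.integer(n_causal),
              effect_dist = effect_dist,
              target_shared_group = target_shared_group,
              spacing_bp = as.integer(spacing_bp), seed = as.integer(seed))
  ok <- cfg$n_snps >= 1 && cfg$n_blocks >= 1 && cfg$n_blocks <= cfg$n_snps &&
    cfg$within_block_r >= 0 && cfg$within_block_r < 1 &&
    length(cfg$maf_range) == 2L && cfg$maf_range[1] > 0 &&
    cfg$maf_range[1] <= cfg$maf_range[2] && cfg$maf_range[2] <= 0.5 &&
    cfg$n_base >= 1 && cfg$n_target >= 2 &&
    cfg$case_fraction > 0 && cfg$case_fraction < 1 &&
    cfg$h2_base >= 0 && cfg$h2_base < 1 &&
    cfg$h2_liability >= 0 && cfg$h2_liability < 1 &&
    cfg$shared_fraction >= 0 && cfg$shared_fraction <= 1 &&
    cfg$sign_mix >= 0 && cfg$sign_mix <= 1 &&
    cfg$n_causal >= 0 && cfg$n_causal <= cfg$n_snps &&
    (is.null(cfg$target_shared_group) ||
       cfg$target_shared_group %in% beta_sign_groups())
  if (!ok) {
    prscan_abort("infeasible simulation configuration (see ?sim_config)",
                 "prscan_validation_error")
  }
  structure(cfg, class = "sim_config")
}

#' Block assignment of SNPs
#' @noRd
snp_blocks <- function(config) {
  sort(rep_len(seq_len(config$n_blocks), config$n_snps))
}

#' Simulate block-correlated genotype dosages
#'
#' Haplotypes are drawn from a block-structured latent Gaussian copula:
#' within each block the latent variables share an exchangeable correlation
#' `within_block_r`, blocks are independent, and an allele is present when
#' its latent variable falls below the allele-frequency quantile. The
#' dosage is the sum of two independent haplotypes, so empirical allele
#' frequencies match the drawn ones up to sampling error.
#'
#' @param config a [sim_config].
#' @return A [target_cohort] without phenotype; attribute `maf` carries the
#'   drawn allele-b frequencies. Bit-identical across runs for a fixed
#'   seed.
#' @export
simulate_ld_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    m <- config$n_snps
    n <- config$n_target
    maf <- runif(m, config$maf_range[1], config$maf_range[2])
    thresh <- qnorm(maf)
    blocks <- snp_blocks(config)
    r <- config$within_block_r
    draw_haplotype <- function() {
      Z <- matrix(rnorm(n * m), nrow = n)
      if (r > 0) {
        shared <- matrix(rnorm(n * config$n_blocks), nrow = n)
        Z <- sqrt(1 - r) * Z + sqrt(r) * shared[, blocks, drop = FALSE]
      }
      sweep(Z, 2L, thresh, "<") * 1L
    }
    dosages <- draw_haplotype() + draw_haplotype()
    snp_index <- data.frame(
      snp_id = sprintf("rs%06d", seq_len(m)),
      chrom = "1",
      pos = seq_len(m) * config$spacing_bp,
      allele_a = "A", allele_b = "G"
    )
    cohort <- target_cohort(
      sample_ids = sprintf("S%05d", seq_len(n)),
      snp_index = snp_index, dosages = dosages
    )
    attr(cohort, "maf") <- maf
    cohort
  })
}

#' Simulate summary statistics of the two correlated base traits
#'
#' Causal SNPs are confined to half of the LD blocks (so that architecture
#' specific to the target can live in the other half, keeping
#' `shared_fraction` an exact overlap control). Per-standardized-genotype
#' true effects are Gaussian, rescaled so the causal SNPs explain `h2_base`
#' of each trait; the LDL-like effect sign is concordant with the HDL-like
#' one with probability `sign_mix`. Observed effects add sampling noise
#' with `se = 1 / sqrt(n_base * 2 f (1 - f))` (per-allele scale) and
#' p-values come from the two-sided Wald statistic, floored at the smallest
#' positive double.
#'
#' @param config a [sim_config].
#' @param maf per-SNP allele-b frequencies, as attached to the cohort by
#'   [simulate_ld_genotypes()].
#' @return list with `hdl` and `ldl` ([summary_stats]) and `truth`
#'   (data.frame per causal SNP: `snp_id`, `block`, `maf`, `b_hdl_std`,
#'   `b_ldl_std`, true per-allele `beta_hdl`, `beta_ldl`).
#' @export
simulate_base_sumstats <- function(config, maf) {
  stopifnot(inherits(config, "sim_config"), length(maf) == config$n_snps)
  with_seed(derive_seed(config$seed, 2L), {
    m <- config$n_snps
    blocks <- snp_blocks(config)
    base_blocks <- seq_len(max(1L, floor(config$n_blocks / 2)))
    pool <- which(blocks %in% base_blocks)
    if (config$n_causal > length(pool)) {
      prscan_abort("n_causal exceeds the SNPs available in base blocks",
                   "prscan_validation_error")
    }
    causal <- sort(sample(pool, config$n_causal))

    scale_to_h2 <- function(b, h2) {
      ss <- sum(b^2)
      if (ss == 0 || h2 == 0) return(b * 0)
      b * sqrt(h2 / ss)
    }
    b_hdl <- numeric(m)
    b_ldl <- numeric(m)
    if (config$n_causal > 0L) {
      if (config$effect_dist == "fixed") {
        b_hdl[causal] <- sample(c(-1, 1), config$n_causal, replace = TRUE)
        mag_ldl <- rep(1, config$n_causal)
      } else {
        b_hdl[causal] <- rnorm(config$n_causal)
        mag_ldl <- abs(rnorm(config$n_causal))
      }
      concordant <- runif(config$n_causal) < config$sign_mix
      b_ldl[causal] <- mag_ldl * sign(b_hdl[causal]) *
        ifelse(concordant, 1, -1)
      b_hdl[causal] <- scale_to_h2(b_hdl[causal], config$h2_base)
      b_ldl[causal] <- scale_to_h2(b_ldl[causal], config$h2_base)
    }

    var_allele <- 2 * maf * (1 - maf)
    se <- 1 / sqrt(config$n_base * var_allele)
    to_sumstats <- function(b_std, trait) {
      beta_true <- b_std / sqrt(var_allele)
      beta_hat <- beta_true + rnorm(m, sd = se)
      p <- 2 * pnorm(-abs(beta_hat / se))
      p <- pmax(p, .Machine$double.xmin)
      summary_stats(data.frame(
        snp_id = sprintf("rs%06d", seq_len(m)), chrom = "1",
        pos = seq_len(m) * config$spacing_bp,
        effect_allele = "G", other_allele = "A",
        beta = beta_hat, se = se, p = p
      ), trait_name = trait)
    }
    hdl <- to_sumstats(b_hdl, "HDL")
    ldl <- to_sumstats(b_ldl, "LDL")
    truth <- data.frame(
      snp_id = sprintf("rs%06d", causal), block = blocks[causal],
      maf = maf[causal], b_hdl_std = b_hdl[causal],
      b_ldl_std = b_ldl[causal],
      beta_hdl = b_hdl[causal] / sqrt(var_allele[causal]),
      beta_ldl = b_ldl[causal] / sqrt(var_allele[causal])
    )
    list(hdl = hdl, ldl = ldl, truth = truth)
  })
}

#' Simulate the binary target phenotype on existing genotypes
#'
#' Liability-threshold disease model: the liability is a weighted sum of
#' standardized dosages plus Gaussian noise scaled so the genetic share of
#' the liability variance is `h2_liability`; the top `case_fraction`
#' quantile of the liability becomes the cases (so the case count is exact).
#' Target causal SNPs are `round(shared_fraction * n_causal)` SNPs reused
#' from the base-causal set — with effects proportional to the true base
#' effects, so base and target effects correlate at shared SNPs — plus
#' independent causal SNPs drawn from LD blocks that contain no base-causal
#' SNP.
#'
#' @param config a [sim_config].
#' @param truth the `truth` data.frame from [simulate_base_sumstats()].
#' @param cohort the phenotype-less [target_cohort] from
#'   [simulate_ld_genotypes()].
#' @return list with `target` (completed [target_cohort]) and
#'   `target_truth` (list: `shared_ids`, `independent_ids`, `gamma`
#'   data.frame, realized `h2`, `genetic_value`).
#' @export
simulate_target_phenotype <- function(config, truth, cohort) {
  stopifnot(inherits(config, "sim_config"), inherits(cohort,
                                                     "target_cohort"))
  with_seed(derive_seed(config$seed, 3L), {
    n <- nrow(cohort$dosages)
    n_shared <- round(config$shared_fraction * config$n_causal)
    n_indep <- config$n_causal - n_shared

    pool_shared <- truth
    if (!is.null(config$target_shared_group)) {
      want <- switch(config$target_shared_group,
                     "incHDL+incLDL" = truth$b_hdl_std > 0 & truth$b_ldl_std > 0,
                     "decHDL+decLDL" = truth$b_hdl_std < 0 & truth$b_ldl_std < 0,
                     "incHDL+decLDL" = truth$b_hdl_std > 0 & truth$b_ldl_std < 0,
                     "decHDL+incLDL" = truth$b_hdl_std < 0 & truth$b_ldl_std > 0)
      pool_shared <- truth[want, , drop = FALSE]
    }
    if (n_shared > nrow(pool_shared)) {
      prscan_abort(sprintf(
        "cannot draw %d shared causal SNPs from a pool of %d",
        n_shared, nrow(pool_shared)), "prscan_validation_error")
    }
    shared <- pool_shared[sample.int(nrow(pool_shared), n_shared), ,
                          drop = FALSE]
    gamma_shared <- if (is.null(config$target_shared_group)) {
      shared$b_hdl_std
    } else {
      (shared$b_hdl_std + shared$b_ldl_std) / 2
    }

    blocks <- snp_blocks(cohort_config_check(config, cohort))
    base_block_set <- unique(truth$block)
    free_pool <- which(!(blocks %in% base_block_set))
    if (n_indep > length(free_pool)) {
      prscan_abort("not enough SNPs outside base-causal blocks",
                   "prscan_validation_error")
    }
    indep <- sort(sample(free_pool, n_indep))
    gamma_scale <- if (n_shared > 0) sqrt(mean(gamma_shared^2)) else
      sqrt(config$h2_base / max(config$n_causal, 1L))
    gamma_indep <- rnorm(n_indep, sd = max(gamma_scale, 1e-8))

    causal_idx <- c(match(shared$snp_id, cohort$snp_index$snp_id), indep)
    gamma <- c(gamma_shared, gamma_indep)

    if (length(causal_idx) > 0L && config$h2_liability > 0) {
      Z <- impute_mean(cohort$dosages[, causal_idx, drop = FALSE])
      Z <- scale(Z)
      Z[, attr(Z, "scaled:scale") == 0] <- 0
      g <- as.vector(Z %*% gamma)
    } else {
      g <- numeric(n)
    }
    vg <- var(g)
    liability <- if (vg > 0 && config$h2_liability > 0) {
      g + rnorm(n, sd = sqrt(vg * (1 - config$h2_liability) /
                               config$h2_liability))
    } else {
      rnorm(n)
    }
    n_cases <- round(config$case_fraction * n)
    phenotype <- integer(n)
    phenotype[order(liability, decreasing = TRUE)[seq_len(n_cases)]] <- 1L

    target <- target_cohort(cohort$sample_ids, cohort$snp_index,
                            cohort$dosages, phenotype)
    attr(target, "maf") <- attr(cohort, "maf")
    realized_h2 <- if (var(liability) > 0) vg / var(liability) else 0
    list(target = target,
         target_truth = list(
           shared_ids = shared$snp_id,
           independent_ids = cohort$snp_index$snp_id[indep],
           gamma = data.frame(
             snp_id = cohort$snp_index$snp_id[causal_idx],
             gamma = gamma,
             shared = c(rep(TRUE, n_shared), rep(FALSE, n_indep))),
           h2_realized = realized_h2,
           genetic_value = g,
           liability = liability))
  })
}

# the phenotype step reuses the block layout; guard against a mismatched
# cohort being passed in
cohort_config_check <- function(config, cohort) {
  if (ncol(cohort$dosages) != config$n_snps) {
    prscan_abort("cohort SNP count does not match the configuration",
                 "prscan_validation_error")
  }
  config
}

#' Simulate a complete synthetic study
#'
#' Runs [simulate_ld_genotypes()], [simulate_base_sumstats()] and
#' [simulate_target_phenotype()] in order and bundles the results with the
#' ground truth, which is recorded exactly as simulated for
#' parameter-recovery tests.
#'
#' @param config a [sim_config].
#' @return list with `hdl`, `ldl` ([summary_stats]), `target`
#'   ([target_cohort]), and `truth` (list: `config`, `maf`, `base`
#'   data.frame, `target` list).
#' @export
simulate_study <- function(config = sim_config()) {
  cohort <- simulate_ld_genotypes(config)
  base <- simulate_base_sumstats(config, attr(cohort, "maf"))
  ph <- simulate_target_phenotype(config, base$truth, cohort)
  list(hdl = base$hdl, ldl = base$ldl, target = ph$target,
       truth = list(config = unclass(config), maf = attr(cohort, "maf"),
                    base = base$truth, target = ph$target_truth))
}

#' Serialize simulation ground truth beside the outputs
#'
#' @param truth the `truth` element of [simulate_study()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  truth$target$genetic_value <- NULL   # per-sample vectors stay in memory
  truth$target$liability <- NULL
  jsonlite::write_json(truth, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
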