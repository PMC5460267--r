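#' Match base summary statistics to target cohort SNPs
#'
#' SNPs are matched by `snp_id`, cross-checked on `chrom:pos`. The base
#' `beta` is re-expressed for the target's `allele_b` (the dosage-counted
#' allele): it is kept when the base effect allele equals `allele_b` and
#' negated when it equals `allele_a`. Strand-ambiguous (A/T, C/G) base SNPs
#' are dropped as palindromic, as are SNPs with irreconcilable alleles or no
#' match; every dropped category is counted.
#'
#' @param base a [summary_stats] object.
#' @param target a [target_cohort].
#' @return list with `matched` (data.frame `snp_id`, `chrom`, `pos`, `col`
#'   — dosage column index —, `beta`, `se`, `p`, `flipped`) and `counts`
#'   (named integer vector: `base`, `palindromic`, `unmatched`,
#'   `pos_mismatch`, `allele_mismatch`, `matched`).
#' @export
harmonize_alleles <- function(base, target) {
  stopifnot(inherits(base, "summary_stats"), inherits(target,
                                                      "target_cohort"))
  b <- as.data.frame(base)
  n_base <- nrow(b)
  pal <- paste0(pmin(b$effect_allele, b$other_allele),
                pmax(b$effect_allele, b$other_allele)) %in% c("AT", "CG")
  n_pal <- sum(pal)
  b <- b[!pal, , drop = FALSE]

  col <- match(b$snp_id, target$snp_index$snp_id)
  n_unmatched <- sum(is.na(col))
  keep <- !is.na(col)
  b <- b[keep, , drop = FALSE]
  col <- col[keep]

  idx <- target$snp_index[col, , drop = FALSE]
  pos_ok <- b$chrom == idx$chrom & b$pos == idx$pos
  n_pos_mismatch <- sum(!pos_ok)
  b <- b[pos_ok, , drop = FALSE]
  col <- col[pos_ok]
  idx <- idx[pos_ok, , drop = FALSE]

  same <- b$effect_allele == idx$allele_b & b$other_allele == idx$allele_a
  flip <- b$effect_allele == idx$allele_a & b$other_allele == idx$allele_b
  n_allele_mismatch <- sum(!(same | flip))
  keep <- same | flip
  b <- b[keep, , drop = FALSE]
  col <- col[keep]
  flip <- flip[keep]

  if (nrow(b) == 0L) {
    prscan_abort("no SNPs could be matched between base and target",
                 "prscan_pipeline_error")
  }
  matched <- data.frame(
    snp_id = b$snp_id, chrom = b$chrom, pos = b$pos, col = col,
    beta = ifelse(flip, -b$beta, b$beta), se = b$se, p = b$p,
    flipped = flip
  )
  rownames(matched) <- NULL
  list(matched = matched,
       counts = c(base = n_base, palindromic = n_pal,
                  unmatched = n_unmatched, pos_mismatch = n_pos_mismatch,
                  allele_mismatch = n_allele_mismatch,
                  matched = nrow(matched)))
}

#' Build an LD reference from target dosages
#'
#' Pairwise LD is quantified as the squared Pearson correlation of
#' mean-imputed dosages, evaluated lazily within a base-pair window (the
#' standard choice when individual-level target data exist). Monomorphic
#' SNPs get r-squared 0 against everything.
#'
#' @param target a [target_cohort].
#' @param window_bp window within which r-squared is defined (pairs farther
#'   apart are treated as unlinked by [clump()]).
#' @return An `ld_reference` object.
#' @export
ld_reference <- function(target, window_bp = 250000L) {
  stopifnot(inherits(target, "target_cohort"))
  X <- impute_mean(target$dosages)
  X <- scale(X, center = TRUE, scale = FALSE)
  norms <- sqrt(colSums(X^2))
  zero <- norms <= 0
  norms[zero] <- 1
  X <- sweep(X, 2L, norms, "/")    # unit-norm columns: crossprod = Pearson r
  X[, zero] <- 0
  structure(list(X = X, snp_id = target$snp_index$snp_id,
                 chrom = target$snp_index$chrom,
                 pos = target$snp_index$pos,
                 window_bp = as.integer(window_bp), r2 = NULL),
            class = "ld_reference")
}

#' Wrap an externally supplied r-squared matrix as an LD reference
#'
#' @param r2 symmetric SNP x SNP matrix with unit diagonal, values in
#'   `[0, 1]`, dimnames = SNP ids.
#' @param chrom,pos per-SNP coordinates aligned with `r2` rows.
#' @param window_bp window within which the matrix is trusted.
#' @return An `ld_reference` object.
#' @export
ld_reference_matrix <- function(r2, chrom, pos, window_bp = 250000L) {
  r2 <- as.matrix(r2)
  if (is.null(rownames(r2))) {
    prscan_abort("the r2 matrix needs SNP ids as dimnames",
                 "prscan_config_error")
  }
  if (any(r2 < 0 | r2 > 1) || any(abs(diag(r2) - 1) > 1e-12) ||
      !isSymmetric(unname(r2))) {
    prscan_abort("r2 must be symmetric with unit diagonal and values in [0,1]",
                 "prscan_validation_error")
  }
  structure(list(X = NULL, snp_id = rownames(r2), chrom = as.character(chrom),
                 pos = as.integer(pos), window_bp = as.integer(window_bp),
                 r2 = r2),
            class = "ld_reference")
}

#' r-squared between one SNP and a set of SNPs
#' @param ld an `ld_reference`; `i`, `js` integer indices into `ld$snp_id`.
#' @noRd
ld_r2_values <- function(ld, i, js) {
  if (!is.null(ld$r2)) {
    ld$r2[i, js]
  } else {
    as.vector(crossprod(ld$X[, i], ld$X[, js, drop = FALSE]))^2
  }
}

#' Mean-impute missing dosages per SNP
#' @noRd
impute_mean <- function(dosages) {
  if (!anyNA(dosages)) return(dosages)
  means <- colMeans(dosages, na.rm = TRUE)
  means[is.nan(means)] <- 0
  na_idx <- which(is.na(dosages), arr.ind = TRUE)
  dosages[na_idx] <- means[na_idx[, 2L]]
  dosages
}

#' Greedy LD clumping of matched SNPs
#'
#' Repeatedly takes the unclumped SNP with the smallest base p-value as an
#' index SNP and removes all unclumped SNPs on the same chromosome within
#' `window_bp` whose r-squared with it is at least `r2_cut`. Ties on p are
#' broken by position then SNP id, deterministically. Defaults follow the
#' cited scoring tool's conventions: 250 kb window, r-squared 0.1, all SNPs
#' eligible as indexes (`clump_p = 1`).
#'
#' @param matched the `matched` table from [harmonize_alleles()] (or any
#'   data.frame with `snp_id`, `chrom`, `pos`, `p`).
#' @param ld an [ld_reference] covering the matched SNPs.
#' @param r2_cut clumping r-squared threshold in `[0, 1]`.
#' @param window_bp clumping window in base pairs.
#' @param clump_p only SNPs with `p <= clump_p` may become index SNPs.
#' @return character vector of index SNP ids, sorted by ascending p.
#' @export
clump <- function(matched, ld, r2_cut = 0.1, window_bp = 250000L,
                  clump_p = 1.0) {
  if (!is.numeric(r2_cut) || r2_cut < 0 || r2_cut > 1) {
    prscan_abort("r2_cut must be in [0, 1]", "prscan_config_error")
  }
  ld_idx <- match(matched$snp_id, ld$snp_id)
  if (anyNA(ld_idx)) {
    prscan_abort("LD reference does not cover all matched SNPs",
                 "prscan_config_error")
  }
  ord <- order(matched$p, matched$pos, matched$snp_id)
  n <- nrow(matched)
  removed <- rep(FALSE, n)
  is_index <- rep(FALSE, n)
  for (k in ord) {
    if (removed[k] || is_index[k]) next
    if (matched$p[k] > clump_p) next
    is_index[k] <- TRUE
    near <- which(!removed & !is_index &
                    matched$chrom == matched$chrom[k] &
                    abs(matched$pos - matched$pos[k]) <= window_bp)
    if (length(near)) {
      r2 <- ld_r2_values(ld, ld_idx[k], ld_idx[near])
      removed[near[r2 >= r2_cut]] <- TRUE
    }
  }
  keep <- which(is_index)
  keep <- keep[order(matched$p[keep], matched$pos[keep],
                     matched$snp_id[keep])]
  matched$snp_id[keep]
}

#' Per-sample polygenic scores at one p-value threshold
#'
#' The score of sample i is the mean over the m selected SNPs of
#' `beta_j * dosage_ij`, where the selected SNPs are those with base
#' `p < p_T` (strict) among `index_snps`. Missing dosages are mean-imputed
#' per SNP here, at scoring time.
#'
#' @param matched the `matched` table from [harmonize_alleles()].
#' @param target a [target_cohort].
#' @param p_T base p-value threshold.
#' @param index_snps SNP ids retained by [clump()]; `NULL` uses all matched
#'   SNPs.
#' @return numeric per-sample score vector with attribute `n_snps`, or
#'   `NULL` (with a warning) when no SNP passes the threshold.
#' @export
compute_scores <- function(matched, target, p_T, index_snps = NULL) {
  sel <- matched$p < p_T
  if (!is.null(index_snps)) sel <- sel & matched$snp_id %in% index_snps
  m <- sum(sel)
  if (m == 0L) {
    warning(sprintf("no SNPs at threshold p_T = %g; threshold skipped", p_T),
            call. = FALSE)
    return(NULL)
  }
  D <- impute_mean(target$dosages[, matched$col[sel], drop = FALSE])
  scores <- as.vector(D %*% matched$beta[sel]) / m
  attr(scores, "n_snps") <- m
  scores
}

#' Test score-phenotype association by logistic regression
#'
#' The binary phenotype is regressed on the z-standardized score (plus any
#' covariates); `assoc_p` is the Wald p-value of the score term and the
#' model fit is Nagelkerke's pseudo R-squared against the covariate-only
#' null. Under (quasi-)perfect separation the Wald test degenerates, so the
#' result is flagged and the p-value falls back to the likelihood-ratio
#' test.
#'
#' @param scores finite numeric score vector.
#' @param phenotype binary vector aligned with `scores`.
#' @param covariates optional data.frame of numeric covariates.
#' @return list with `assoc_p`, `r2_nagelkerke`, `beta`, `se`, `method`
#'   (`"wald"` or `"lrt"`), `separation` (logical).
#' @export
associate <- function(scores, phenotype, covariates = NULL) {
  stopifnot(all(is.finite(scores)), length(scores) == length(phenotype))
  phenotype <- as.integer(phenotype)
  s <- sd(scores)
  if (s == 0) {
    return(list(assoc_p = 1, r2_nagelkerke = 0, beta = 0, se = NA_real_,
                method = "degenerate", separation = FALSE))
  }
  dat <- data.frame(y = phenotype, score = (scores - mean(scores)) / s)
  null_rhs <- "1"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(scores))
    names(covariates) <- make.names(names(covariates), unique = TRUE)
    dat <- cbind(dat, covariates)
    null_rhs <- paste(names(covariates), collapse = " + ")
  }
  full_fml <- as.formula(paste("y ~ score",
                               if (!is.null(covariates))
                                 paste("+", null_rhs) else ""))
  separation <- FALSE
  ctrl <- stats::glm.control(epsilon = 1e-12, maxit = 50)
  full <- withCallingHandlers(
    glm(full_fml, family = binomial(), data = dat, control = ctrl),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  null <- suppressWarnings(glm(as.formula(paste("y ~", null_rhs)),
                               family = binomial(), data = dat,
                               control = ctrl))
  if (!full$converged) separation <- TRUE
  sm <- summary(full)$coefficients
  beta <- sm["score", "Estimate"]
  se <- sm["score", "Std. Error"]
  if (separation) {
    lrt <- anova(null, full, test = "Chisq")
    assoc_p <- lrt$`Pr(>Chi)`[2L]
    method <- "lrt"
  } else {
    assoc_p <- sm["score", "Pr(>|z|)"]
    method <- "wald"
  }
  n <- length(phenotype)
  ll0 <- as.numeric(logLik(null))
  ll1 <- as.numeric(logLik(full))
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  r2_max <- 1 - exp(2 * ll0 / n)
  r2 <- if (r2_max > 0) max(0, min(1, cox_snell / r2_max)) else 0
  list(assoc_p = assoc_p, r2_nagelkerke = r2, beta = beta, se = se,
       method = method, separation = separation)
}

#' Default base p-value thresholds of the scan
#' @return the seven thresholds `0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5`.
#' @export
default_thresholds <- function() c(0.001, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Scan shared genetic etiology across p-value thresholds
#'
#' Runs the full clumping-and-thresholding scan: allele harmonization, one
#' LD clumping pass (clumping is threshold-independent), then per threshold
#' polygenic scoring and logistic association. The best threshold is the one
#' with the smallest association p-value (equivalently, in this model, the
#' largest Nagelkerke R-squared).
#'
#' @param base a [summary_stats] object (single or combined trait).
#' @param target a [target_cohort] with phenotype.
#' @param thresholds ascending base p-value thresholds; default the seven
#'   canonical values of [default_thresholds()].
#' @param clump_kb clumping window in kilobases (default 250).
#' @param clump_r2 clumping r-squared threshold (default 0.1).
#' @param clump_p index-SNP eligibility threshold (default 1).
#' @param covariates optional covariate data.frame (defaults to the
#'   cohort's own, if any).
#' @param ld optional [ld_reference]; computed from the target dosages when
#'   absent.
#' @param keep_scores retain the per-sample score vectors in the result.
#' @return A `prs_scan` object: `trait`, `table` (one row per threshold:
#'   `trait`, `threshold`, `n_snps_used`, `assoc_p`, `neg_log10_p`,
#'   `r2_nagelkerke`, `skipped`), `best_threshold`, `counts` from
#'   harmonization, `index_snps`, and optionally `scores`.
#' @export
scan_thresholds <- function(base, target, thresholds = default_thresholds(),
                            clump_kb = 250, clump_r2 = 0.1, clump_p = 1.0,
                            covariates = NULL, ld = NULL,
                            keep_scores = FALSE) {
  stopifnot(inherits(base, "summary_stats"), inherits(target,
                                                      "target_cohort"))
  if (is.null(target$phenotype)) {
    prscan_abort("target cohort has no phenotype", "prscan_pipeline_error")
  }
  thresholds <- sort(unique(as.numeric(thresholds)))
  covariates <- covariates %||% target$covariates
  h <- harmonize_alleles(base, target)
  window_bp <- as.integer(clump_kb * 1000)
  ld <- ld %||% ld_reference(target, window_bp = window_bp)
  index_snps <- clump(h$matched, ld, r2_cut = clump_r2,
                      window_bp = window_bp, clump_p = clump_p)
  score_list <- list()
  rows <- lapply(thresholds, function(pt) {
    sc <- withCallingHandlers(
      compute_scores(h$matched, target, pt, index_snps),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(sc)) {
      return(data.frame(trait = trait_name(base), threshold = pt,
                        n_snps_used = 0L, assoc_p = NA_real_,
                        neg_log10_p = NA_real_, r2_nagelkerke = NA_real_,
                        skipped = TRUE))
    }
    if (keep_scores) score_list[[as.character(pt)]] <<- sc
    a <- associate(sc, target$phenotype, covariates)
    data.frame(trait = trait_name(base), threshold = pt,
               n_snps_used = attr(sc, "n_snps"), assoc_p = a$assoc_p,
               neg_log10_p = -log10(a$assoc_p),
               r2_nagelkerke = a$r2_nagelkerke, skipped = FALSE)
  })
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  usable <- which(!table$skipped)
  best <- if (length(usable)) {
    table$threshold[usable[which.min(table$assoc_p[usable])]]
  } else {
    NA_real_
  }
  structure(list(trait = trait_name(base), table = table,
                 best_threshold = best, counts = h$counts,
                 index_snps = index_snps,
                 scores = if (keep_scores) score_list else NULL),
            class = "prs_scan")
}

#' @export
print.prs_scan <- function(x, ...) {
  cat(sprintf("<prs_scan> trait '%s': %d thresholds, best p_T = %s\n",
              x$trait, nrow(x$table), format(x$best_threshold)))
  print(x$table, digits = 4)
  invisible(x)
}
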