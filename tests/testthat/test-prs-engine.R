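test_that("allele harmonization flips, drops and counts correctly", {
  base <- summary_stats(data.frame(
    snp_id = c("rs001", "rs002", "rs003", "rs004", "rs005"),
    chrom = "1", pos = c(1000L, 2000L, 3000L, 4000L, 99L),
    effect_allele = c("G", "A", "A", "C", "G"),
    other_allele = c("A", "G", "T", "T", "A"),
    beta = c(0.5, 0.5, 0.5, 0.5, 0.5), se = 0.1, p = 0.01
  ), "base")
  dos <- matrix(1, nrow = 3, ncol = 5)
  target <- make_cohort(dos, phenotype = c(1L, 0L, 0L))
  # target alleles: a = A, b = G at pos 1000,2000,...; rs005 pos mismatch
  h <- harmonize_alleles(base, target)
  expect_equal(h$matched$snp_id, c("rs001", "rs002"))
  expect_equal(h$matched$beta, c(0.5, -0.5))   # rs002 effect allele is A
  expect_equal(unname(h$counts["palindromic"]), 1L)   # rs003 is A/T
  expect_equal(unname(h$counts["allele_mismatch"]), 1L)  # rs004 C/T
  expect_equal(unname(h$counts["pos_mismatch"]), 1L)  # rs005
  expect_equal(unname(h$counts["matched"]), 2L)

  # no matchable SNPs is a pipeline error
  at_only <- summary_stats(data.frame(
    snp_id = "rs001", chrom = "1", pos = 1000L, effect_allele = "A",
    other_allele = "T", beta = 1, se = 1, p = 0.5), "base")
  expect_error(harmonize_alleles(at_only, target),
               class = "prscan_pipeline_error")
})

test_that("clumping keeps the most significant SNP of a correlated pair", {
  pos <- c(1000L, 2000L)
  r2 <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("rs001", "rs002"),
                                                 c("rs001", "rs002")))
  ld <- ld_reference_matrix(r2, chrom = c("1", "1"), pos = pos)
  matched <- data.frame(snp_id = c("rs001", "rs002"), chrom = "1",
                        pos = pos, p = c(1e-8, 1e-4))
  expect_equal(clump(matched, ld, r2_cut = 0.1, window_bp = 250000L),
               "rs001")
  # uncorrelated SNPs all survive
  r2_0 <- diag(2)
  dimnames(r2_0) <- dimnames(r2)
  ld0 <- ld_reference_matrix(r2_0, chrom = c("1", "1"), pos = pos)
  expect_setequal(clump(matched, ld0, 0.1, 250000L),
                  c("rs001", "rs002"))
  # outside the window the pair is not clumped even at r2 = 1
  far <- data.frame(snp_id = c("rs001", "rs002"), chrom = "1",
                    pos = c(1000L, 400000L), p = c(1e-8, 1e-4))
  ldf <- ld_reference_matrix(r2, chrom = c("1", "1"), pos = far$pos)
  expect_setequal(clump(far, ldf, 0.1, 250000L), c("rs001", "rs002"))
})

test_that("clumping equals the straight-line greedy reference on LD fixtures", {
  set.seed(404)
  for (rep in 1:30) {
    m <- 30L
    pos <- sort(sample.int(500000L, m))
    # random block-ish correlation structure
    L <- matrix(rnorm(m * m, sd = 0.4), m)
    diag(L) <- 1
    S <- L %*% t(L)
    r2 <- abs(cov2cor(S))^2
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    ids <- sprintf("rs%03d", 1:m)
    dimnames(r2) <- list(ids, ids)
    p <- runif(m)^2
    matched <- data.frame(snp_id = ids, chrom = "1", pos = pos, p = p)
    window <- sample(c(50000L, 150000L, 250000L), 1)
    cut <- sample(c(0.1, 0.3, 0.6), 1)
    ld <- ld_reference_matrix(r2, chrom = rep("1", m), pos = pos,
                              window_bp = window)
    got <- clump(matched, ld, r2_cut = cut, window_bp = window)
    want <- oracle_clump(ids, pos, p, r2, window, cut)
    expect_identical(got, want)
    # invariant: no retained pair is linked within the window
    kept <- match(got, ids)
    for (i in kept) {
      for (j in kept) {
        if (i < j && abs(pos[i] - pos[j]) <= window) {
          expect_lt(r2[i, j], cut)
        }
      }
    }
  }
})

test_that("LD from dosages is the squared Pearson correlation, imputed", {
  set.seed(9)
  dos <- matrix(sample(0:2, 60, replace = TRUE), nrow = 20)
  dos[3, 1] <- NA
  cohort <- make_cohort(dos)
  ld <- ld_reference(cohort)
  imp <- dos
  imp[3, 1] <- mean(dos[, 1], na.rm = TRUE)
  want <- cor(imp)^2
  got <- outer(1:3, 1:3, Vectorize(function(i, j)
    prscan:::ld_r2_values(ld, i, j)))
  expect_equal(got, unname(want), tolerance = 1e-12)

  # monomorphic SNPs have r2 = 0 by convention
  dos2 <- cbind(rep(1, 20), dos[, 2])
  ld2 <- ld_reference(make_cohort(dos2))
  expect_equal(prscan:::ld_r2_values(ld2, 1, 2), 0)
})

test_that("polygenic scores are the mean of beta times dosage", {
  matched <- data.frame(snp_id = "rs001", chrom = "1", pos = 1000L,
                        col = 1L, beta = 0.5, se = 0.1, p = 1e-4)
  target <- make_cohort(matrix(c(0, 1, 2), ncol = 1))
  sc <- compute_scores(matched, target, p_T = 0.05)
  expect_equal(as.vector(sc), c(0, 0.5, 1.0))   # beta x dosage / m, m = 1
  expect_equal(attr(sc, "n_snps"), 1L)

  # zero betas give zero scores
  matched0 <- transform(matched, beta = 0)
  expect_equal(as.vector(compute_scores(matched0, target, 0.05)),
               c(0, 0, 0))

  # 5 SNPs x 4 samples vs the dense loop oracle
  set.seed(12)
  dos <- matrix(runif(20, 0, 2), nrow = 4)
  betas <- rnorm(5)
  m5 <- data.frame(snp_id = sprintf("rs%03d", 1:5), chrom = "1",
                   pos = 1:5 * 1000L, col = 1:5, beta = betas, se = 0.1,
                   p = 1e-4)
  got <- compute_scores(m5, make_cohort(dos), 0.05)
  expect_equal(as.vector(got), oracle_scores(betas, dos), tolerance = 1e-12)

  # missing dosages are mean-imputed per SNP at scoring time
  dosNA <- dos
  dosNA[2, 3] <- NA
  imp <- dosNA
  imp[2, 3] <- mean(dosNA[, 3], na.rm = TRUE)
  expect_equal(as.vector(compute_scores(m5, make_cohort(dosNA), 0.05)),
               oracle_scores(betas, imp), tolerance = 1e-12)

  # empty threshold is skipped with a warning
  expect_warning(out <- compute_scores(m5, make_cohort(dos), 1e-6),
                 "skipped")
  expect_null(out)
})

test_that("logistic association matches an IRLS oracle on a small fixture", {
  # hand-coded n = 20 fixture with one covariate
  score <- c(0.3, -1.2, 0.5, 2.1, -0.7, 1.4, 0.2, -0.3, 1.9, -1.5,
             0.8, -0.1, 1.1, -2.0, 0.6, 0.9, -0.4, 1.3, -0.9, 0.4)
  covar <- c(1.2, 0.1, -0.5, 0.7, 0.3, -1.1, 0.9, -0.2, 0.5, -0.8,
             1.4, 0.0, -0.3, 0.6, -1.2, 0.2, 0.8, -0.6, 1.0, -0.4)
  # outcome deliberately overlaps the score so the likelihood is bounded
  y <- c(1L, 0L, 0L, 1L, 1L, 1L, 0L, 0L, 1L, 0L,
         1L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L)
  res <- associate(score, y, covariates = data.frame(cv = covar))
  z <- (score - mean(score)) / sd(score)
  X <- cbind(1, z, covar)
  beta_oracle <- oracle_irls_logistic(X, y)
  expect_equal(res$beta, beta_oracle[2], tolerance = 1e-8)
  expect_equal(res$method, "wald")

  # Nagelkerke R2 from first principles on the same fixture
  ll1 <- sum(y * (X %*% beta_oracle) - log(1 + exp(X %*% beta_oracle)))
  b0 <- oracle_irls_logistic(cbind(1, covar), y)
  ll0 <- sum(y * (cbind(1, covar) %*% b0) -
               log(1 + exp(cbind(1, covar) %*% b0)))
  n <- 20
  want_r2 <- (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(res$r2_nagelkerke, want_r2, tolerance = 1e-8)
})

test_that("association p-values are calibrated under the null", {
  set.seed(77)
  n <- 2000L
  reps <- 1000L
  pheno <- rep(c(1L, 0L), c(600L, 1400L))
  rejections <- 0L
  for (r in seq_len(reps)) {
    sc <- rnorm(n)    # independent of the (fixed) phenotype
    if (associate(sc, pheno)$assoc_p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / reps
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gte(rate, 0.05 - ci_half - 1e-9)
  expect_lte(rate, 0.05 + ci_half + 1e-9)
})

test_that("perfect separation is flagged and handled by a likelihood-ratio test", {
  set.seed(3)
  sc <- rnorm(200)
  y <- as.integer(sc > median(sc))
  res <- associate(sc, y)
  expect_true(res$separation)
  expect_equal(res$method, "lrt")
  expect_lt(res$assoc_p, 1e-10)
  expect_gt(res$r2_nagelkerke, 0.9)   # near the maximum attainable fit
})

test_that("threshold scans nest SNP sets and respect invariances", {
  set.seed(55)
  cfg <- sim_config(n_snps = 400L, n_blocks = 20L, n_target = 400L,
                    n_causal = 30L, shared_fraction = 0.5, seed = 14)
  st <- simulate_study(cfg)
  scan <- scan_thresholds(st$hdl, st$target)
  expect_equal(scan$table$threshold, default_thresholds())
  expect_true(all(diff(scan$table$n_snps_used) >= 0))
  expect_equal(scan$best_threshold,
               scan$table$threshold[which.min(scan$table$assoc_p)])

  # score invariance under SNP reordering
  perm <- sample(ncol(st$target$dosages))
  tperm <- target_cohort(st$target$sample_ids,
                         st$target$snp_index[perm, ],
                         st$target$dosages[, perm],
                         st$target$phenotype)
  h1 <- harmonize_alleles(st$hdl, st$target)
  h2 <- harmonize_alleles(st$hdl, tperm)
  s1 <- compute_scores(h1$matched, st$target, 0.5)
  s2 <- compute_scores(h2$matched, tperm, 0.5)
  expect_equal(as.vector(s1), as.vector(s2), tolerance = 1e-12)

  # invariance under allele relabeling with beta sign flip
  flipped <- as.data.frame(st$hdl)
  flipped[, c("effect_allele", "other_allele")] <-
    flipped[, c("other_allele", "effect_allele")]
  flipped$beta <- -flipped$beta
  hf <- harmonize_alleles(summary_stats(flipped, "HDL"), st$target)
  expect_equal(hf$matched$beta, h1$matched$beta, tolerance = 1e-12)
})
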