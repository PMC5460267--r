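test_that("genotype simulation is deterministic and respects the MAF range", {
  cfg <- sim_config(n_snps = 200L, n_blocks = 10L, n_target = 500L,
                    n_causal = 20L, seed = 99)
  a <- simulate_ld_genotypes(cfg)
  b <- simulate_ld_genotypes(cfg)
  expect_identical(a$dosages, b$dosages)   # bit-identical under one seed
  expect_true(all(a$dosages %in% 0:2))
  emp_maf <- colMeans(a$dosages) / 2
  expect_true(all(emp_maf > 0.01 & emp_maf < 0.6))
  expect_equal(cor(emp_maf, attr(a, "maf")) > 0.9, TRUE)
  # different seed, different data
  c2 <- simulate_ld_genotypes(sim_config(n_snps = 200L, n_blocks = 10L,
                                         n_target = 500L, n_causal = 20L,
                                         seed = 100))
  expect_false(identical(a$dosages, c2$dosages))
  expect_error(sim_config(n_snps = 10, n_blocks = 20),
               class = "prscan_validation_error")
  expect_error(sim_config(maf_range = c(0.4, 0.2)),
               class = "prscan_validation_error")
})

test_that("block correlation calibrates with the latent copula parameter", {
  block_r2 <- function(r, seed) {
    cfg <- sim_config(n_snps = 60L, n_blocks = 6L, within_block_r = r,
                      n_target = 5000L, n_causal = 5L, seed = seed)
    dos <- simulate_ld_genotypes(cfg)$dosages
    blocks <- sort(rep_len(1:6, 60))
    r2 <- suppressWarnings(cor(dos))^2
    r2[is.na(r2)] <- 0
    within <- outer(blocks, blocks, "==") & upper.tri(r2)
    c(within = mean(r2[within]), cross = mean(r2[!within & upper.tri(r2)]))
  }
  r0 <- block_r2(0, 61)
  expect_lt(r0[["within"]], 0.01)    # independence at r = 0
  expect_lt(r0[["cross"]], 0.01)
  r9 <- block_r2(0.9, 62)
  # dichotomization attenuates the latent r = 0.9; the population value of
  # the mean within-block dosage r2 for this copula is about 0.32
  expect_gt(r9[["within"]], 0.25)
  expect_lt(r9[["within"]], 0.40)
  expect_lt(r9[["cross"]], 0.01)
  r5 <- block_r2(0.5, 63)
  expect_gt(r9[["within"]], r5[["within"]])  # monotone in the parameter
  expect_gt(r5[["within"]], r0[["within"]])
})

test_that("null base traits give uniform p-values; huge samples recover beta", {
  cfg0 <- sim_config(n_snps = 10000L, n_blocks = 100L, n_causal = 100L,
                     h2_base = 0, seed = 15)
  maf <- runif(10000, 0.05, 0.5)
  ss0 <- simulate_base_sumstats(cfg0, maf)
  ks <- suppressWarnings(ks.test(ss0$hdl$p, "punif"))
  expect_gt(ks$p.value, 0.01)

  # vanishing-noise limit: beta_hat approaches the true beta
  cfg_big <- sim_config(n_snps = 2000L, n_blocks = 20L, n_causal = 100L,
                        n_base = 1e7, h2_base = 0.5, seed = 16)
  maf2 <- runif(2000, 0.05, 0.5)
  sim <- simulate_base_sumstats(cfg_big, maf2)
  truth_beta <- setNames(sim$truth$beta_hdl, sim$truth$snp_id)
  est <- sim$hdl$beta[match(names(truth_beta), sim$hdl$snp_id)]
  rmse <- sqrt(mean((est - truth_beta)^2))
  expect_lt(rmse, 1e-3)
})

test_that("sign structure of the two traits follows sign_mix", {
  cfg <- sim_config(n_snps = 2000L, n_blocks = 20L, n_causal = 400L,
                    sign_mix = 1, seed = 17)
  maf <- runif(2000, 0.05, 0.5)
  sim <- simulate_base_sumstats(cfg, maf)
  expect_true(all(sign(sim$truth$b_hdl_std) == sign(sim$truth$b_ldl_std)))
  # observed betas land concordantly wherever the true effect is large
  # enough that sampling noise cannot flip its sign
  sp <- split_by_beta_sign(sim$hdl, sim$ldl)
  causal_groups <- c(sp$groups[["incHDL+incLDL"]]$snp_id,
                     sp$groups[["decHDL+decLDL"]]$snp_id)
  z_true <- with(sim$truth, pmin(abs(b_hdl_std), abs(b_ldl_std))) *
    sqrt(188577)   # standardized effect on the Wald z scale
  strong <- sim$truth$snp_id[z_true > 5]
  expect_gt(length(strong), 50)
  expect_true(all(strong %in% causal_groups))

  # sign_mix = 0.5 populates all four groups in their expected proportions
  cfg5 <- sim_config(n_snps = 2000L, n_blocks = 20L, n_causal = 400L,
                     sign_mix = 0.5, seed = 18)
  sim5 <- simulate_base_sumstats(cfg5, maf)
  tr <- sim5$truth
  counts <- c(sum(tr$b_hdl_std > 0 & tr$b_ldl_std > 0),
              sum(tr$b_hdl_std < 0 & tr$b_ldl_std < 0),
              sum(tr$b_hdl_std > 0 & tr$b_ldl_std < 0),
              sum(tr$b_hdl_std < 0 & tr$b_ldl_std > 0))
  gof <- chisq.test(counts, p = rep(0.25, 4))
  expect_gt(gof$p.value, 0.01)
})

test_that("the liability-threshold phenotype has exact case counts and h2", {
  cfg <- sim_config(n_snps = 500L, n_blocks = 25L, n_target = 3000L,
                    n_causal = 60L, case_fraction = 0.3,
                    h2_liability = 0.4, shared_fraction = 0.5, seed = 19)
  st <- simulate_study(cfg)
  expect_equal(sum(st$target$phenotype), round(0.3 * 3000))

  # regression of liability on the true genetic value: slope ~ 1, R2 ~ h2
  tt <- st$truth$target
  fit <- lm(tt$liability ~ tt$genetic_value)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
  expect_lt(abs(summary(fit)$r.squared - 0.4), 0.05)
  expect_lt(abs(tt$h2_realized - 0.4), 0.05)

  # shared causal SNPs come from the base-causal set; independent ones from
  # blocks without base signal
  expect_true(all(tt$shared_ids %in% st$truth$base$snp_id))
  blocks <- sort(rep_len(1:25, 500))
  base_blocks <- unique(st$truth$base$block)
  indep_idx <- match(tt$independent_ids, st$target$snp_index$snp_id)
  expect_false(any(blocks[indep_idx] %in% base_blocks))

  # restricting the shared group keeps only concordant-positive causal SNPs
  cfgg <- sim_config(n_snps = 500L, n_blocks = 25L, n_target = 1000L,
                     n_causal = 80L, sign_mix = 0.5, shared_fraction = 0.2,
                     target_shared_group = "incHDL+incLDL", seed = 20)
  stg <- simulate_study(cfgg)
  tb <- stg$truth$base
  shared <- tb[tb$snp_id %in% stg$truth$target$shared_ids, ]
  expect_true(all(shared$b_hdl_std > 0 & shared$b_ldl_std > 0))
})

test_that("the full simulated study is reproducible under one seed", {
  cfg <- sim_config(n_snps = 300L, n_blocks = 15L, n_target = 300L,
                    n_causal = 30L, seed = 77)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$target$dosages, s2$target$dosages)
  expect_identical(s1$target$phenotype, s2$target$phenotype)
  expect_equal(as.data.frame(s1$hdl), as.data.frame(s2$hdl))
  expect_equal(s1$truth$base, s2$truth$base)
})
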