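test_that("scenarios validate their rates and pleiotropy settings", {
  expect_error(mr_scenario(palindrome_rate = 1.2), "palindrome_rate")
  expect_error(mr_scenario(pleiotropy_mode = "balanced",
                           pleiotropy_mean = 0.1), "Balanced")
  expect_error(mr_scenario(ld_blocks = data.frame(size = 40, r2 = 0.9),
                           n_snps = 30), "more variants")
  expect_s3_class(mr_scenario(seed = 1), "mr_scenario")
})

test_that("the generator is deterministic and the truth record reproduces the draws", {
  sc <- mr_scenario(n_snps = 20, theta = 0.3, seed = 99)
  a <- simulate_mr_pair(sc)
  b <- simulate_mr_pair(sc)
  expect_identical(as.data.frame(a$exposure), as.data.frame(b$exposure))
  expect_identical(as.data.frame(a$outcome), as.data.frame(b$outcome))
  # Truth record: emitted true outcome effects obey Gamma = theta*gamma + alpha.
  expect_equal(a$truth$snps$Gamma,
               0.3 * a$truth$snps$gamma + a$truth$snps$alpha)
  expect_equal(a$truth$divisor,
               (470 / 216569) * (1 - 470 / 216569))
})

test_that("generated SEs are positive and shrink like 1/sqrt(n)", {
  small <- simulate_mr_pair(mr_scenario(n_snps = 50, n_exposure = 1000,
                                        seed = 4))
  big <- simulate_mr_pair(mr_scenario(n_snps = 50, n_exposure = 100000,
                                      seed = 4))
  expect_true(all(small$exposure$se > 0))
  # Same seed, same EAFs: the SE ratio is exactly sqrt(n_big/n_small).
  expect_equal(small$exposure$se / big$exposure$se,
               rep(sqrt(100), 50))
})

test_that("binary outcomes are emitted on the linear scale and convert back to log odds", {
  pair <- simulate_mr_pair(mr_scenario(n_snps = 10, theta = 0.5, seed = 8))
  expect_identical(attr(pair$outcome, "scale"), "linear-boltlmm")
  conv <- convert_boltlmm_to_logor(pair$outcome)
  mu <- 470 / 216569
  expect_equal(conv$beta * mu * (1 - mu), pair$outcome$beta)
  # Recovered SEs match the generator's log-odds SE model.
  eaf <- pair$outcome$eaf
  expect_equal(conv$se, 1 / sqrt(2 * eaf * (1 - eaf) * 216569))
})

test_that("palindrome exclusions land in the binomial band of the configured rate", {
  pair <- simulate_mr_pair(mr_scenario(n_snps = 100, palindrome_rate = 0.2,
                                       seed = 13))
  h <- harmonize_pair(pair)
  excl <- harmonization_exclusions(h)
  n_pal <- sum(excl$reason == "palindromic")
  band <- qbinom(c(0.025, 0.975), 100, 0.2)
  expect_gte(n_pal, band[1])
  expect_lte(n_pal, band[2])
  expect_equal(n_pal, sum(pair$truth$snps$palindromic))
})

test_that("full strand flipping leaves the harmonized set identical", {
  base <- simulate_mr_pair(mr_scenario(n_snps = 40, theta = 0.2, seed = 17))
  flip <- simulate_mr_pair(mr_scenario(n_snps = 40, theta = 0.2, seed = 17,
                                       strand_flip_rate = 1))
  hb <- harmonize_pair(base)
  hf <- harmonize_pair(flip)
  expect_equal(tidy(hb)[, c("variant_id", "gamma", "Gamma", "se_Gamma")],
               tidy(hf)[, c("variant_id", "gamma", "Gamma", "se_Gamma")])
  # Allele swapping is likewise undone by harmonization.
  swap <- simulate_mr_pair(mr_scenario(n_snps = 40, theta = 0.2, seed = 17,
                                       allele_swap_rate = 0.5))
  hs <- harmonize_pair(swap)
  expect_equal(tidy(hb)$Gamma, tidy(hs)$Gamma)
})

test_that("LD blocks are emitted as a symmetric reference that clumping consumes", {
  pair <- simulate_mr_pair(mr_scenario(
    n_snps = 12, seed = 23,
    ld_blocks = data.frame(size = c(4, 3), r2 = c(0.8, 0.95))
  ))
  expect_s3_class(pair$ld, "ld_reference")
  ids <- pair$exposure$variant_id
  expect_equal(ld_r2(pair$ld, ids[1], ids[2]), 0.8)
  expect_equal(ld_r2(pair$ld, ids[2], ids[1]), 0.8)
  expect_equal(ld_r2(pair$ld, ids[5], ids[6]), 0.95)
  expect_equal(ld_r2(pair$ld, ids[1], ids[9]), 0)
  kept <- clump_variants(pair$exposure, 1, pair$ld)
  # One survivor per block plus all singletons.
  expect_equal(nrow(kept), 2 + 5)
})

test_that("a null pair leaves zero inside the IVW interval", {
  pair <- simulate_mr_pair(mr_scenario(n_snps = 50, theta = 0, seed = 31))
  fit <- mr_ivw(harmonize_pair(pair))
  expect_lte(fit$ci_low, 0)
  expect_gte(fit$ci_high, 0)
})

test_that("the panel generator mirrors the bidirectional study shape", {
  panel <- simulate_mr_panel(factor_count = 3, n_snps_per_factor = 12,
                             active_factor = 2, n_disease_snps = 8,
                             seed = 55)
  expect_named(panel$factors, sprintf("factor_%02d", 1:3))
  expect_identical(attr(panel$crp, "scale"), "natural-log")
  expect_identical(attr(panel$pct, "scale"), "natural-log")
  expect_identical(attr(panel$disease, "scale"), "linear-boltlmm")
  expect_equal(panel$truth$divisor,
               (470 / 216569) * (1 - 470 / 216569), tolerance = 1e-12)
  expect_equal(sum(panel$truth$traits$theta_forward != 0), 1)
  expect_equal(panel$truth$traits$theta_forward[2], log(1.42))
  # Disease dataset carries outcome rows for every factor instrument and
  # its own instruments; factor datasets carry the disease instruments.
  f1 <- panel$factors$factor_01
  expect_true(all(panel$truth$disease_instruments %in% f1$variant_id))
  expect_true(all(setdiff(f1$variant_id, panel$truth$disease_instruments)
                  %in% panel$disease$variant_id))
  # Single-factor reduction still produces a complete set.
  single <- simulate_mr_panel(factor_count = 1, n_snps_per_factor = 6,
                              active_factor = 0, n_disease_snps = 6,
                              seed = 7)
  expect_named(single$factors, "factor_01")
  expect_true(all(single$truth$traits$theta_forward == 0))
})
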