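test_that("p-threshold rule: strict with >= 3 genome-wide variants, relaxed otherwise", {
  gs <- make_sumstats(5, p_value = 1e-9)
  expect_equal(choose_p_threshold(gs)$threshold, 5e-8)
  expect_equal(choose_p_threshold(gs)$rule, "genome-wide")

  mixed <- gwas_sumstats(
    dplyr::mutate(make_summary_tbl(12),
                  p_value = c(rep(1e-9, 2), rep(1e-6, 10))),
    "t"
  )
  thr <- choose_p_threshold(mixed)
  expect_equal(thr$threshold, 1e-5)
  expect_equal(thr$rule, "relaxed")
  expect_equal(thr$n_gs, 2)

  none <- make_sumstats(3, p_value = 1e-3)
  expect_equal(choose_p_threshold(none)$threshold, 1e-5)
  expect_equal(
    nrow(clump_variants(none, choose_p_threshold(none)$threshold,
                        pre_clumped = TRUE)),
    0
  )
})

test_that("greedy clumping keeps the best variant per LD block within the window", {
  tbl <- make_summary_tbl(3)
  tbl$p_value <- c(1e-9, 1e-8, 1e-7)
  no_ld <- ld_reference(tibble::tibble(variant_a = character(),
                                       variant_b = character(),
                                       r2 = numeric()))
  expect_equal(nrow(clump_variants(tbl, 1e-5, no_ld)), 3)

  block <- ld_reference(tibble::tibble(
    variant_a = c("rs1", "rs1", "rs2"),
    variant_b = c("rs2", "rs3", "rs3"),
    r2 = 0.5
  ))
  kept <- clump_variants(tbl, 1e-5, block)
  expect_equal(kept$variant_id, "rs1") # best p wins, the rest are clumped
  removed <- attr(kept, "removed")
  expect_setequal(removed$variant_id, c("rs2", "rs3"))
  expect_true(all(removed$reason == "clumped"))

  far <- tbl[1:2, ]
  far$position <- c(1L, 20000001L) # 20 Mb apart
  pair_ld <- ld_reference(tibble::tibble(variant_a = "rs1",
                                         variant_b = "rs2", r2 = 0.5))
  expect_equal(nrow(clump_variants(far, 1e-5, pair_ld,
                                   clump_window_bp = 1e7)), 2)
  expect_error(clump_variants(tbl, 1e-5, ld = NULL), "LD reference")
})

test_that("clumping output is order-invariant and pairwise independent", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 12
    tbl <- make_summary_tbl(n)
    tbl$p_value <- runif(n, 1e-12, 1e-6)
    tbl$position <- sample.int(5e6, n)
    combo <- t(utils::combn(n, 2))
    pairs <- tibble::tibble(
      variant_a = tbl$variant_id[combo[, 1]],
      variant_b = tbl$variant_id[combo[, 2]],
      r2 = sample(c(0, 0.3), nrow(combo), replace = TRUE)
    )
    ld <- ld_reference(pairs)
    kept <- clump_variants(tbl, 1e-5, ld, clump_r2 = 0.1)
    shuffled <- clump_variants(tbl[sample.int(n), ], 1e-5, ld,
                               clump_r2 = 0.1)
    expect_equal(kept$variant_id, shuffled$variant_id)
    # Exhaustive pairwise check of the independence rule.
    if (nrow(kept) > 1) {
      idx <- t(utils::combn(nrow(kept), 2))
      r2 <- ld_r2(ld, kept$variant_id[idx[, 1]], kept$variant_id[idx[, 2]])
      dist <- abs(kept$position[idx[, 1]] - kept$position[idx[, 2]])
      expect_true(all(r2 < 0.1 | dist > 1e7))
    }
  }
})

test_that("explained variance follows 2*EAF*(1-EAF)*beta^2", {
  expect_equal(compute_r_squared(0.5, 0.1), 0.005)
  expect_equal(compute_r_squared(0.5, 0), 0)
  expect_equal(compute_r_squared(0.1, 0.2), 0.0072)
  expect_error(compute_r_squared(0, 0.1), "eaf")
  expect_warning(r2 <- compute_r_squared(0.5, 2), "clipped")
  expect_lt(r2, 1)
})

test_that("F statistic follows R^2(N-2)/(1-R^2) and is monotone", {
  expect_equal(compute_f_statistic(0, 100), 0)
  expect_equal(compute_f_statistic(0.005, 1000), 0.005 * 998 / 0.995)
  expect_equal(compute_f_statistic(0.005, 1000), 5.0151, tolerance = 1e-4)
  expect_equal(compute_f_statistic(0.01, 8293), 83.747, tolerance = 1e-4)
  expect_error(compute_f_statistic(0.01, 2), "exceed 2")
  r2_grid <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(compute_f_statistic(r2_grid, 1000)) > 0))
  n_grid <- c(10, 100, 1000, 1e5)
  expect_true(all(diff(compute_f_statistic(0.01, n_grid)) > 0))
})

test_that("the weak-instrument filter excludes F < 10 and keeps the boundary", {
  tbl <- make_summary_tbl(3)
  tbl$f_statistic <- c(9.99, 10, 25)
  kept <- filter_weak_instruments(tbl)
  expect_setequal(kept$variant_id, c("rs2", "rs3"))
  expect_equal(attr(kept, "removed")$reason, "weak")
  empty <- filter_weak_instruments(tbl[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("confounder screens apply 0.05 / testable-count and log untestable variants", {
  instruments <- make_summary_tbl(10)
  bmi_tbl <- make_summary_tbl(10)
  bmi_tbl$p_value <- rep(0.5, 10)
  bmi_tbl$p_value[1] <- 0.001 # below 0.05/10 = 0.005
  bmi_tbl$p_value[2] <- 0.01  # above threshold: retained
  bmi <- gwas_sumstats(bmi_tbl, "BMI")
  out <- screen_instruments(instruments, list(BMI = bmi))
  expect_setequal(attr(out, "removed")$variant_id, "rs1")
  expect_equal(attr(out, "removed")$reason, "confounder:BMI")
  expect_true("rs2" %in% out$variant_id)

  partial <- gwas_sumstats(bmi_tbl[1:4, ], "BMI")
  out2 <- screen_instruments(instruments, list(BMI = partial))
  notes <- attr(out2, "notes")
  expect_setequal(notes$variant_id, sprintf("rs%d", 5:10))
  expect_true(all(sprintf("rs%d", 5:10) %in% out2$variant_id))

  outc <- gwas_sumstats(dplyr::mutate(bmi_tbl, p_value = 1e-6), "disease")
  out3 <- screen_instruments(instruments, list(outcome = outc))
  expect_equal(unique(attr(out3, "removed")$reason), "outcome-associated")
  expect_equal(nrow(out3), 0)
})

test_that("proxy search takes the highest r2 above the cutoff, ties broken by outcome p", {
  outcome_tbl <- make_summary_tbl(4)
  outcome_tbl$variant_id <- c("px1", "px2", "px3", "px4")
  outcome_tbl$p_value <- c(0.3, 0.01, 0.5, 0.5)
  outcome <- gwas_sumstats(outcome_tbl, "disease")
  ld <- ld_reference(tibble::tibble(
    variant_a = c("rsA", "rsA", "rsB", "rsC", "rsC"),
    variant_b = c("px1", "px2", "px3", "px1", "px2"),
    r2 = c(0.95, 0.95, 0.85, 0.92, 0.99)
  ))
  prox <- find_proxies(c("rsA", "rsB", "rsC"), ld, outcome)
  expect_equal(prox$proxy_id[prox$variant_id == "rsA"], "px2") # p tie-break
  expect_equal(prox$proxy_id[prox$variant_id == "rsC"], "px2") # max r2
  expect_equal(attr(prox, "unproxied"), "rsB") # best is 0.85 <= 0.9
})
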