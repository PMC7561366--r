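test_that("descriptives report n, mean, and sample SD", {
  d <- descriptives(c(1, 2, 3))
  expect_equal(d, list(n = 3L, mean = 2, sd = 1))
  expect_equal(descriptives(rep(5, 10))$sd, 0)
  expect_error(descriptives(c(1)), "at least 2")
  # missing values are dropped
  expect_equal(descriptives(c(1, NA, 2, 3, Inf))$n, 3L)
})

test_that("pooled t matches a hand recomputation and the stats route", {
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    tt <- pooled_t_test(a, b)
    # independent brute-force recomputation of every formula
    n1 <- length(a); n2 <- length(b)
    sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
    t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    d_hand <- (mean(a) - mean(b)) /
      sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2))
    expect_equal(tt$t, t_hand, tolerance = 1e-10)
    expect_equal(tt$cohen_d, d_hand, tolerance = 1e-10)
    expect_equal(tt$df, n1 + n2 - 2)
    # cross-check t and p against the independent implementation
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tt$p_two_tailed, ref$p.value, tolerance = 1e-10)
  }
  ident <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_two_tailed, 1)
  expect_equal(ident$cohen_d, 0)
  expect_error(pooled_t_test(c(1, 1), c(2, 2)), "degenerate")
})

test_that("summary t-test equals the raw-data test on matching summaries", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(15, 0.4)
    s <- summary_t_test(descriptives(a), descriptives(b))
    r <- pooled_t_test(a, b)
    expect_equal(s$t, r$t, tolerance = 1e-10)
    expect_equal(s$p_two_tailed, r$p_two_tailed, tolerance = 1e-10)
    expect_equal(s$cohen_d, r$cohen_d, tolerance = 1e-10)
  }
  expect_equal(summary_t_test(list(n = 10, mean = 3, sd = 1),
                              list(n = 12, mean = 3, sd = 2))$t, 0)
})

test_that("published-group summaries reproduce the printed t and d", {
  tt <- summary_t_test(list(n = 52, mean = 421.36, sd = 53.41),
                       list(n = 47, mean = 342.36, sd = 72.47))
  expect_equal(tt$df, 97)
  expect_equal(round(tt$t, 2), 6.21)
  expect_equal(round(tt$cohen_d, 2), 1.26)
  expect_lt(tt$p_two_tailed, 0.001)
})

test_that("pearson matches cor.test, is symmetric and affine-invariant", {
  set.seed(15)
  x <- rnorm(40); y <- 0.5 * x + rnorm(40)
  r <- pearson(x, y)
  ref <- cor.test(x, y)
  expect_equal(r$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(r$p_two_tailed, ref$p.value, tolerance = 1e-12)
  expect_equal(pearson(y, x)$r, r$r, tolerance = 1e-12)
  expect_equal(pearson(3 * x + 7, y)$r, r$r, tolerance = 1e-12)

  expect_equal(pearson(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson(c(-1, 0, 1), c(1, 0, 1))$r, 0, tolerance = 1e-12)
  # pairwise deletion
  expect_equal(pearson(c(x, NA), c(y, 5))$n, 40L)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("correlation recovers the generator correlation", {
  sim <- synth_cohort(cohort_spec(n_participants = 10000L,
                                  corr = corr_with(rho = 0.5), seed = 99))
  r <- pearson(sim$participants$f0_hz, sim$participants$dwell_index)
  expect_lt(abs(r$r - 0.5), 0.03)
})

test_that("KS diagnostic separates normal from uniform samples", {
  p_norm <- vapply(1:50, function(i) {
    set.seed(100 + i)
    ks_normality(rnorm(300))$p
  }, numeric(1))
  expect_gte(mean(p_norm > 0.05), 0.9)
  p_unif <- vapply(1:50, function(i) {
    set.seed(200 + i)
    ks_normality(runif(500))$p
  }, numeric(1))
  expect_gte(mean(p_unif < 0.05), 0.9)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(c(1, 2)), "at least 5")
})

test_that("correlation table has the cohort x subset x cell structure", {
  sim_t <- synth_cohort(cohort_spec(n_participants = 500L,
                                    corr = corr_with(rho = 0.3),
                                    bout_start_fraction = 1, seed = 31))
  sim_c <- synth_cohort(cape_town_spec(n_participants = 500L, seed = 32))
  records <- rbind(sim_t$participants, sim_c$participants)
  tab <- run_correlation_table(records)
  expect_equal(nrow(tab), 16L)
  expect_setequal(unique(tab$subset), c("all", "bout_start",
                                        "ssri_excluded"))
  # only the planted F0 x disengagement cell is large in the Tampere cohort
  tam <- tab[tab$cohort == "tampere" & tab$subset == "all", ]
  planted <- tam$feature == "F0" & tam$outcome == "disengagement"
  expect_gt(abs(tam$r[planted]), 0.2)
  expect_true(all(abs(tam$r[!planted]) < 0.2))
  # bout-start filter is idempotent when every flag is TRUE
  tam_all <- tab[tab$cohort == "tampere" & tab$subset == "all", c("r", "n")]
  tam_sub <- tab[tab$cohort == "tampere" & tab$subset == "bout_start",
                 c("r", "n")]
  expect_equal(tam_all, tam_sub, ignore_attr = TRUE)
  # the SSRI filter reduces the Cape Town n
  ct <- tab[tab$cohort == "cape_town", ]
  expect_lt(ct$n[ct$subset == "ssri_excluded"][1],
            ct$n[ct$subset == "all"][1])

  # a 2-participant cohort is entirely not computable
  tiny <- synth_cohort(cohort_spec(n_participants = 2L, seed = 33))
  tab2 <- run_correlation_table(tiny$participants)
  expect_true(all(!tab2$computable[tab2$cohort == "tampere"]))
})

test_that("simulated cohorts recover the generator parameters within 3 SE", {
  spec <- cohort_spec(n_participants = 1000L, seed = 44)
  d <- synth_cohort(spec)$participants
  for (v in c("f0_hz", "f0var_hz", "orienting_latency_ms")) {
    se <- spec$sds[v] / sqrt(1000)
    expect_lt(abs(mean(d[[v]]) - spec$means[v]), 3 * se)
    sd_se <- spec$sds[v] / sqrt(2 * 999)
    expect_lt(abs(sd(d[[v]]) - spec$sds[v]), 3 * sd_se)
  }
})
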