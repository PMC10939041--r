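test_that("lattice zone graphs have the expected counts and degrees", {
  g <- make_lattice_zones(2L, 2L)
  expect_length(g$zones, 4L)
  expect_equal(nrow(g$edges), 4L)
  g8 <- make_lattice_zones(8L, 8L)
  expect_length(g8$zones, 64L)
  expect_equal(nrow(g8$edges), 112L)        # 2 * 8 * 7
  deg <- zone_degree(g8)
  expect_equal(sort(unique(deg)), c(2L, 3L, 4L))
  expect_equal(sum(deg == 2L), 4L)          # corners
})

test_that("iGMRF fields are centred, seeded, and match the pseudo-inverse
           pairwise variances", {
  g <- make_lattice_zones(2L, 3L)
  f1 <- sample_igmrf(g, tau2 = 0.5, seed = 3L)
  f2 <- sample_igmrf(g, tau2 = 0.5, seed = 3L)
  expect_identical(f1, f2)
  expect_lt(abs(sum(f1)), 1e-10)

  # Monte-Carlo Var(b_i - b_j) for an adjacent pair against the analytic
  # value from the Laplacian pseudo-inverse
  K <- mrf_penalty(g)
  Kp <- MASS::ginv(K)
  i <- 1L; j <- 2L
  v_analytic <- 0.5 * (Kp[i, i] + Kp[j, j] - 2 * Kp[i, j])
  draws <- vapply(seq_len(4000L), function(s) {
    f <- sample_igmrf(g, tau2 = 0.5, seed = 10000L + s)
    f[i] - f[j]
  }, numeric(1L))
  expect_equal(stats::var(draws), v_analytic, tolerance = 0.06)
})

test_that("panel generation is a pure function of its seed and honours
           the level bands", {
  tr <- synthetic_truth(seed = 2L)
  a <- gen_panel(tr, n_households = 200L, waves = 3L, seed = 9L)
  b <- gen_panel(tr, n_households = 200L, waves = 3L, seed = 9L)
  expect_identical(a$data, b$data)
  expect_equal(nrow(a$data), 600L)
  expect_equal(sort(unique(a$data$wave)), c(2012L, 2014L, 2016L))
  # FCS values always re-categorize to the drawn level
  expect_equal(categorize_fcs(a$data$fcs, ordinal_coding()), a$data$level)
  # truth fields are centred
  expect_lt(abs(sum(tr$f_str)), 1e-9)
  expect_lt(abs(sum(tr$f_unstr)), 1e-9)
})

test_that("with all effects zero the margins follow the probit bands of
           the thresholds", {
  tr <- synthetic_truth(tau2_str = 1e-12, tau2_unstr = 1e-12,
                        gamma = c(urban = 0, shock = 0),
                        smooth_fns = list(), offset = 0, seed = 1L)
  tr$f_str[] <- 0; tr$f_unstr[] <- 0
  gp <- gen_panel(tr, n_households = 3835L, waves = 3L, seed = 1L)
  pr <- tabulate(gp$data$level + 1L, 3L) / nrow(gp$data)
  th <- tr$thresholds
  expected <- c(pnorm(th[1L]), pnorm(th[2L]) - pnorm(th[1L]),
                1 - pnorm(th[2L]))
  expect_true(all(abs(pr - expected) < 0.015))
})

test_that("the calibrated default generator reproduces the study margins
           at the ensemble level", {
  pooled <- c(0, 0, 0)
  for (sd in 1:4) {
    tr <- synthetic_truth(seed = sd)
    gp <- gen_panel(tr, n_households = 3835L, waves = 3L, seed = sd)
    pooled <- pooled + tabulate(gp$data$level + 1L, 3L)
  }
  pct <- 100 * pooled / sum(pooled)
  target <- c(47.9, 27.1, 25)   # ascending coding: secure, vulnerable, insecure
  expect_true(all(abs(pct - target) < 3))
  expect_lt(abs(pct[3L] - 25), 2)      # insecure margin, pooled
})

test_that("MCAR masking feeds the imputation path", {
  tr <- synthetic_truth(seed = 3L)
  gp <- gen_panel(tr, n_households = 300L, waves = 3L, seed = 3L,
                  p_missing = 0.05)
  expect_gt(sum(is.na(gp$data$fcs)), 0L)
  imp <- impute_longitudinal(gp$data)
  expect_false(anyNA(imp$coping))
  expect_false(anyNA(imp$fcs))
})
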