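test_that("FCS levels use half-open bands with inclusive upper bounds", {
  cd <- ordinal_coding()   # insecurity-ascending: 2 = insecure
  expect_equal(categorize_fcs(c(35.5, 49, 49.01, 0), cd), c(2L, 1L, 0L, 2L))
  cd2 <- ordinal_coding(direction = "insecurity-descending")
  expect_equal(categorize_fcs(c(35.5, 49, 49.01), cd2), c(0L, 1L, 2L))
  expect_error(categorize_fcs(-1, cd), ">= 0")
  expect_error(ordinal_coding(cuts = c(49, 35.5)), "cuts")
})

test_that("categorization is monotone in the score", {
  cd <- ordinal_coding()
  x <- sort(runif(200, 0, 80))
  lv <- categorize_fcs(x, cd)
  expect_true(all(diff(lv) <= 0))   # insecurity never increases with FCS
})

test_that("longitudinal imputation fills household means and drops
           single-wave households", {
  d <- tibble::tibble(
    household_id = c("H1", "H1", "H1", "H2", "H3", "H3"),
    zone = "A",
    wave = c(2012L, 2014L, 2016L, 2012L, 2012L, 2014L),
    fcs = c(40, NA, 50, 33, NA, 20),
    x = c(NA, NA, NA, 1, 2, NA),
    f = c("a", NA, "a", "b", NA, "c"))
  out <- impute_longitudinal(d)
  expect_false("H2" %in% out$household_id)     # observed once only
  expect_equal(out$fcs[out$household_id == "H1"], c(40, 45, 50))
  # all waves missing for H1's x -> global mean of remaining records
  expect_equal(out$x[out$household_id == "H1"], rep(mean(c(2)), 3L),
               tolerance = 1e-12)
  # categorical: household mode then global mode
  expect_equal(out$f[out$household_id == "H1"], rep("a", 3L))
  expect_false(anyNA(out))
})

test_that("imputation is the identity on complete data and never alters
           observed values", {
  d <- toy_panel()
  expect_equal(impute_longitudinal(d), d)
  d2 <- d
  d2$fcs[2L] <- NA
  out <- impute_longitudinal(d2)
  expect_equal(out$fcs[-2L], d$fcs[-2L])
})

test_that("cross tabulations give row percentages summing to 100", {
  d <- tibble::tibble(level = c(2L, 2L, 0L, 1L),
                      urban = c("y", "y", "n", "n"))
  ct <- cross_tab(d, "urban")
  yrow <- ct[ct$category == "y", ]
  expect_equal(yrow$pct_insecure, 100)
  expect_equal(yrow$pct_secure + yrow$pct_vulnerable, 0)
  nrow_ <- ct[ct$category == "n", ]
  expect_equal(c(nrow_$pct_secure, nrow_$pct_vulnerable, nrow_$pct_insecure),
               c(50, 50, 0))
  sums <- rowSums(as.matrix(ct[, c("pct_secure", "pct_vulnerable",
                                   "pct_insecure")]))
  expect_true(all(abs(sums - 100) < 0.05))
  # single-category factor equals the marginal distribution
  d$one <- "all"
  expect_equal(unlist(cross_tab(d, "one")[, 3:5], use.names = FALSE),
               unlist(cross_tab(d)[, 3:5], use.names = FALSE))
})

test_that("zone aggregates flag zones without records", {
  g <- path_graph(3L)
  d <- tibble::tibble(zone = c("A", "A", "A", "B"),
                      level = c(2L, 2L, 0L, 1L),
                      fcs = c(10, 20, 60, 42))
  agg <- zone_aggregate(d, "insecure-proportion", graph = g)
  expect_equal(agg$value[agg$zone == "A"], 2 / 3)
  expect_true(agg$no_data[agg$zone == "C"])
  expect_true(is.na(agg$value[agg$zone == "C"]))
  m <- zone_aggregate(tibble::tibble(zone = "A", fcs = c(35.5, 49),
                                     level = c(2L, 1L)),
                      "mean-fcs")
  expect_equal(m$value, 42.25)
})
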