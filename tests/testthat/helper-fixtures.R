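# small graphs and data generators shared across tests

path_graph <- function(n = 3L) {
  lab <- LETTERS[seq_len(n)]
  zone_graph(lab, cbind(lab[-n], lab[-1L]))
}

# square lattice with an isolated extra zone appended
graph_with_island <- function() {
  g <- make_lattice_zones(2L, 2L)
  zone_graph(c(g$zones, "ISL"), g$edges)
}

# tiny complete panel for prep/fit plumbing tests
toy_panel <- function() {
  tibble::tibble(
    household_id = rep(c("H1", "H2", "H3"), each = 2L),
    zone = rep(c("A", "B", "A"), each = 2L),
    wave = rep(c(2012L, 2014L), times = 3L),
    fcs = c(40, 50, 30, 20, 60, 70),
    level = c(1L, 0L, 2L, 2L, 0L, 0L),
    urban = c(1L, 1L, 0L, 0L, 1L, 1L))
}

# small ordinal probit sample with two linear covariates and known truth
sim_linear_ordinal <- function(n = 60L, seed = 7L,
                               beta = c(0.8, -0.5),
                               thresholds = c(-0.5, 0.6)) {
  withr::with_seed(seed, {
    x1 <- stats::rnorm(n)
    x2 <- stats::rbinom(n, 1L, 0.5)
    eta <- beta[1L] * x1 + beta[2L] * x2
    P <- category_probs(eta, thresholds, "probit")
    u <- stats::runif(n)
    y <- (u > P[, 1L]) + (u > P[, 1L] + P[, 2L])
    tibble::tibble(level = as.integer(y), x1 = x1, x2 = x2)
  })
}

# direct numerical maximum-likelihood oracle for the no-smooth model
ml_oracle <- function(d, link = "probit") {
  y <- d$level
  X <- as.matrix(d[, c("x1", "x2")])
  nll <- function(p) {
    th <- c(p[1L], p[1L] + exp(p[2L]))
    -ordinal_loglik(y, as.numeric(X %*% p[3:4]), th, link)$loglik
  }
  o <- stats::optim(c(-0.5, 0, 0, 0), nll, method = "BFGS",
                    control = list(maxit = 2000L, reltol = 1e-14))
  c(o$par[1L], o$par[1L] + exp(o$par[2L]), o$par[3L], o$par[4L])
}

# brute-force O(n^2) Moran's I oracle
moran_brute <- function(v, W) {
  n <- length(v)
  z <- v - mean(v)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- num + W[i, j] * z[i] * z[j]
  }
  (n / sum(W)) * num / sum(z^2)
}
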