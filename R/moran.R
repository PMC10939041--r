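#' Global Moran's I with analytic and permutation inference
#'
#' Computes `I = (n/S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) /
#' sum_i (x_i - xbar)^2` over zone values, with binary contiguity weights
#' from the zone graph (default) or row-standardized weights.  Zones with
#' missing values are dropped and the weight matrix re-subset before
#' anything is computed.  Inference: the normal approximation under the
#' randomization assumption, and a two-sided permutation test
#' `p = (1 + #{|I_perm| >= |I_obs|}) / (n_perm + 1)`.
#'
#' @param values named numeric vector (names = zones) or data frame with
#'   columns `zone`, `value` (e.g. from [zone_aggregate()]).
#' @param graph a [zone_graph()].
#' @param style `"binary"` (default) or `"row-standardized"` weights.
#' @param n_perm number of label permutations (default 9999).
#' @param seed integer seed for the permutation draw.
#' @return one-row tibble: `statistic`, `expectation`, `variance`,
#'   `p.analytic`, `p.perm`, `n_zones`, `s0`, `style`.
#' @export
morans_i <- function(values, graph, style = c("binary", "row-standardized"),
                     n_perm = 9999L, seed = NULL) {
  style <- match.arg(style)
  stopifnot(inherits(graph, "zone_graph"))
  if (is.data.frame(values)) {
    values <- stats::setNames(values$value, values$zone)
  }
  v <- values[graph$zones[graph$zones %in% names(values)]]
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 3L) stop("need at least 3 zones with data")
  W <- adjacency_matrix(graph)[names(v), names(v), drop = FALSE]
  if (style == "row-standardized") {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  S0 <- sum(W)
  if (S0 <= 0) stop("weight matrix has no links among zones with data")
  z <- v - mean(v)
  m2 <- sum(z^2)
  if (m2 < 1e-14) stop("constant surface: zero variance in values")
  I_of <- function(zz) (n / S0) * as.numeric(t(zz) %*% W %*% zz) / sum(zz^2)
  I_obs <- I_of(z)

  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / m2^2
  num <- n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
    b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)
  VI <- num / ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  zstat <- (I_obs - EI) / sqrt(VI)
  p_an <- 2 * stats::pnorm(-abs(zstat))

  p_perm <- NA_real_
  if (n_perm > 0L) {
    rng <- local_rng(seed)
    on.exit(rng(), add = TRUE)
    cnt <- 0L
    for (m in seq_len(n_perm)) {
      zp <- z[sample.int(n)]
      if (abs(I_of(zp)) >= abs(I_obs) - 1e-12) cnt <- cnt + 1L
    }
    p_perm <- (1 + cnt) / (n_perm + 1)
  }
  tibble::tibble(statistic = I_obs, expectation = EI, variance = VI,
                 z = zstat, p.analytic = p_an, p.perm = p_perm,
                 n_zones = n, s0 = S0, style = style)
}

# set the RNG locally; returns a restore function
local_rng <- function(seed) {
  if (is.null(seed)) return(function() invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}
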