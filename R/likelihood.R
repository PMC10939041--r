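link_funs <- function(link = c("probit", "logit")) {
  link <- match.arg(link)
  if (link == "probit") {
    list(name = "probit", F = stats::pnorm, f = stats::dnorm,
         Fc = function(x) stats::pnorm(x, lower.tail = FALSE),
         q = stats::qnorm)
  } else {
    list(name = "logit", F = stats::plogis, f = stats::dlogis,
         Fc = function(x) stats::plogis(x, lower.tail = FALSE),
         q = stats::qlogis)
  }
}

# stable F(hi) - F(lo): switch to complementary CDFs deep in the right tail
cdf_band <- function(lo, hi, lk) {
  use_c <- (lo + hi) > 0
  out <- numeric(length(lo))
  out[!use_c] <- lk$F(hi[!use_c]) - lk$F(lo[!use_c])
  out[use_c] <- lk$Fc(lo[use_c]) - lk$Fc(hi[use_c])
  pmax(out, 0)
}

#' Category probabilities of the cumulative threshold model
#'
#' For ordered thresholds `theta` (length R-1) and linear predictor values
#' `eta`, returns the matrix of category probabilities
#' `pi_r = F(theta_{r+1} - eta) - F(theta_r - eta)` with `F` the standard
#' normal (probit) or standard logistic (logit) CDF and `theta_0 = -Inf`,
#' `theta_R = Inf`.  Rows sum to one.
#'
#' @param eta numeric vector of predictor values (finite).
#' @param thresholds strictly increasing numeric vector (length R-1).
#' @param link `"probit"` or `"logit"`.
#' @return numeric matrix, `length(eta)` x R.
#' @export
category_probs <- function(eta, thresholds, link = c("probit", "logit")) {
  lk <- link_funs(link)
  if (!all(is.finite(eta))) stop("`eta` must be finite")
  th <- as.numeric(thresholds)
  if (any(diff(th) <= 0)) stop("thresholds must be strictly increasing")
  R <- length(th) + 1L
  n <- length(eta)
  P <- matrix(0, n, R)
  U <- outer(eta, th, function(e, t) t - e)   # n x (R-1)
  P[, 1L] <- lk$F(U[, 1L])
  P[, R] <- lk$Fc(U[, R - 1L])
  if (R > 2L) {
    for (r in 2:(R - 1L)) P[, r] <- cdf_band(U[, r - 1L], U[, r], lk)
  }
  P
}

#' Ordinal log-likelihood and deviance
#'
#' Multinomial log-likelihood of levels under the cumulative threshold
#' model, evaluated through numerically stable CDF differences.  The
#' deviance is `-2 * loglik`; the (constant) saturated multinomial term is
#' omitted.
#'
#' @param level integer vector of levels coded `0 .. R-1`.
#' @param eta numeric predictor vector, same length.
#' @param thresholds strictly increasing numeric vector (length R-1).
#' @param link `"probit"` or `"logit"`.
#' @return list with `loglik` and `deviance`.
#' @export
ordinal_loglik <- function(level, eta, thresholds, link = c("probit", "logit")) {
  R <- length(thresholds) + 1L
  if (!all(level %in% 0:(R - 1L))) stop("levels must be coded 0..", R - 1L)
  P <- category_probs(eta, thresholds, link)
  ll <- sum(log(pmax(P[cbind(seq_along(level), level + 1L)], 1e-300)))
  list(loglik = ll, deviance = -2 * ll)
}

# score and expected Fisher information of the ordinal likelihood at
# (theta, eta); eta enters through the stacked design X (score/info for the
# coefficient part are returned in design space)
ordinal_score_info <- function(y, eta, theta, lk, X) {
  n <- length(y); Rm1 <- length(theta); R <- Rm1 + 1L
  U <- outer(eta, theta, function(e, t) t - e)
  Ftab <- cbind(0, lk$F(U), 1)
  ftab <- cbind(0, lk$f(U), 0)
  piM <- Ftab[, 2:(R + 1L), drop = FALSE] - Ftab[, 1:R, drop = FALSE]
  # recompute interior bands stably
  if (R > 2L) {
    for (r in 2:(R - 1L)) piM[, r] <- cdf_band(U[, r - 1L], U[, r], lk)
  }
  piC <- pmax(piM, 1e-12)
  bM <- -(ftab[, 2:(R + 1L), drop = FALSE] - ftab[, 1:R, drop = FALSE])
  iy <- cbind(seq_len(n), y + 1L)
  pi_obs <- piC[iy]
  robs <- bM[iy] / pi_obs
  w <- rowSums(bM^2 / piC)
  ll <- sum(log(pmax(piM[iy], 1e-300)))

  fI <- ftab[, 2:R, drop = FALSE]               # n x (R-1): f_{ir}
  s_theta <- numeric(Rm1)
  Cmat <- matrix(0, n, Rm1)
  Itt <- matrix(0, Rm1, Rm1)
  for (r in seq_len(Rm1)) {
    s_theta[r] <- sum(fI[, r] * ((y == r - 1L) - (y == r)) / pi_obs)
    Cmat[, r] <- fI[, r] * (bM[, r] / piC[, r] - bM[, r + 1L] / piC[, r + 1L])
    Itt[r, r] <- sum(fI[, r]^2 * (1 / piC[, r] + 1 / piC[, r + 1L]))
    if (r < Rm1) {
      Itt[r, r + 1L] <- Itt[r + 1L, r] <- -sum(fI[, r] * fI[, r + 1L] /
                                                 piC[, r + 1L])
    }
  }
  s_coef <- as.numeric(Matrix::crossprod(X, robs))
  Itc <- t(as.matrix(Matrix::crossprod(X, Cmat)))       # (R-1) x p
  Icc <- as.matrix(Matrix::crossprod(sqrt(w) * X))
  list(ll = ll, s_theta = s_theta, s_coef = s_coef,
       Itt = Itt, Itc = Itc, Icc = Icc)
}
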