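#' Fit a cumulative-link geo-additive (STAR) model
#'
#' Fits the ordinal threshold model `P(Y <= r) = F(theta_r - eta)` with a
#' structured additive predictor combining linear terms, P-spline smooths,
#' Markov-random-field or tensor-product structured spatial effects, and
#' i.i.d. Gaussian zone effects.  Coefficients are estimated by penalized
#' Fisher scoring at fixed smoothing variances; the variances `tau^2` are
#' updated by Fellner-Schall-type restricted-maximum-likelihood steps
#' (empirical Bayes).  Terms whose variance falls to `stop_tau2` or below
#' are frozen to their penalty nullspace: a second-order P-spline degrades
#' to a linear effect, spatial and i.i.d. blocks to zero.
#'
#' Formula specials:
#' \describe{
#'   \item{`s(x, n_knots = 20, degree = 3, order = 2)`}{P-spline smooth.}
#'   \item{`mrf(zone)`}{structured spatial effect with graph-Laplacian
#'     penalty (needs `graph`); island zones are excluded from the block
#'     and served by the unstructured term only.}
#'   \item{`tp(zone, n_knots = 8, degree = 3)`}{tensor-product P-spline of
#'     the zone centroid coordinates (needs centroids on `graph`), with
#'     first-order marginal penalties.}
#'   \item{`re(zone)`}{i.i.d. Gaussian zone effect.}
#' }
#' All smooth/spatial terms carry absorbed sum-to-zero constraints (over
#' observations for `s()`, over zones otherwise); there is no free
#' intercept - the thresholds absorb it.  Thresholds are kept ordered via
#' `theta_r = theta_1 + sum(exp(delta))`.
#'
#' @param data data frame, one row per record; the outcome must be coded
#'   `0 .. R-1` under the insecurity-ascending convention (see
#'   [ordinal_coding()]).
#' @param formula model formula, e.g.
#'   `level ~ urban + shock + s(coping) + mrf(zone) + re(zone)`.
#' @param graph [zone_graph()] for `mrf`/`tp`/`re` terms.
#' @param link `"probit"` (default) or `"logit"`.
#' @param stop_tau2 small-variance stopping threshold (natural penalty
#'   scale); default `1e-5`.
#' @param max_iter maximum outer (variance-update) iterations.
#' @param tol relative penalized-deviance convergence tolerance.
#' @param tau2_tol relative `tau^2` convergence tolerance.
#' @param tau2_init initial variance for penalized terms (scaled-penalty
#'   space).
#' @param verbose print per-iteration progress.
#' @return an object of class `ordstar_fit`; see [tidy.ordstar_fit()],
#'   [glance.ordstar_fit()], [smooth_curve()], [zone_effects()],
#'   [variance_partition()].
#' @export
ordstar <- function(data, formula, graph = NULL,
                    link = c("probit", "logit"),
                    stop_tau2 = 1e-5, max_iter = 200L,
                    tol = 1e-7, tau2_tol = 1e-4,
                    tau2_init = 1, verbose = FALSE) {
  link <- match.arg(link)
  lk <- link_funs(link)
  data <- tibble::as_tibble(data)
  pf <- parse_ordstar_formula(formula)
  y <- data[[pf$outcome]]
  if (anyNA(y)) stop("outcome contains missing values; impute first")
  y <- as.integer(y)
  R <- max(y) + 1L
  if (R < 2L) stop("outcome needs at least 2 categories")
  cnt <- tabulate(y + 1L, nbins = R)
  if (any(cnt == 0L)) {
    stop("empty outcome category (separation): level ",
         paste(which(cnt == 0L) - 1L, collapse = ", "))
  }
  n <- length(y)

  blocks <- build_blocks(data, pf, graph)
  st <- assemble_blocks(blocks)

  # threshold initialization from marginal cumulative proportions
  pcum <- cumsum(cnt)[seq_len(R - 1L)] / n
  theta0 <- lk$q(pcum)
  psi <- c(theta0[1L], if (R > 2L) log(diff(theta0)))
  b <- numeric(ncol(st$X))

  tau2 <- vapply(blocks, function(bl) {
    if (bl$penalized) tau2_init else Inf
  }, numeric(1L))
  names(tau2) <- vapply(blocks, `[[`, "", "name")

  pd_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  stall <- 0L
  repeat {
    it <- it + 1L
    Pm <- penalty_matrix(blocks, st, tau2)
    inner <- inner_scoring(y, psi, b, st$X, Pm, lk, R,
                           max_steps = if (it == 1L) 50L else 25L,
                           tol = tol)
    psi <- inner$psi; b <- inner$b
    pd_trace <- c(pd_trace, inner$pd)

    # effective df at current estimates
    ed <- edf_state(y, psi, b, st$X, Pm, lk, R)
    ed_term <- edf_by_block(ed$diag, st$cols)

    froze <- FALSE
    max_rel_dtau <- 0
    for (j in seq_along(blocks)) {
      bl <- blocks[[j]]
      if (!bl$penalized || bl$stopped) next
      idx <- st$cols[[j]]
      bKb <- as.numeric(t(b[idx]) %*% bl$K %*% b[idx])
      denom <- ed_term[j] - bl$null_dim
      t_new <- if (denom > 1e-6 && is.finite(bKb)) bKb / denom else tau2[j] / 10
      t_new <- min(max(t_new, 1e-12), 1e10)
      if (t_new * bl$scale <= stop_tau2) {
        blocks[[j]] <- freeze_block(blocks[[j]], b[idx])
        blocks[[j]]$tau2_at_stop <- t_new
        tau2[j] <- t_new
        froze <- TRUE
      } else {
        max_rel_dtau <- max(max_rel_dtau,
                            abs(t_new - tau2[j]) / (tau2[j] + 1e-8))
        tau2[j] <- t_new
      }
    }
    if (froze) {
      # re-assemble with frozen blocks; map coefficients into the new space
      bnew <- list()
      for (j in seq_along(blocks)) {
        idx <- st$cols[[j]]
        bj <- b[idx]
        prj <- blocks[[j]]$freeze_proj
        bnew[[j]] <- if (is.null(prj)) bj else as.numeric(prj %*% bj)
        blocks[[j]]$freeze_proj <- NULL
      }
      st <- assemble_blocks(blocks)
      b <- unlist(bnew)
      if (length(b) != ncol(st$X)) stop("internal: coefficient remap failed")
    }
    if (verbose) {
      message(sprintf("iter %3d  pen.dev %.6f  max rel dtau %.2e%s",
                      it, inner$pd, max_rel_dtau,
                      if (froze) "  [term frozen]" else ""))
    }
    npd <- length(pd_trace)
    dev_ok <- npd >= 2L &&
      abs(pd_trace[npd] - pd_trace[npd - 1L]) <
        tol * (abs(pd_trace[npd]) + 0.1)
    if (!froze && dev_ok && max_rel_dtau < tau2_tol) { converged <- TRUE; break }
    if (it >= max_iter) break
    # Fellner-Schall updates that keep crawling (e.g. a variance drifting
    # slowly to the boundary) are resolved by maximizing the profile
    # Laplace-approximate REML criterion for each still-moving term
    stall <- if (!froze && max_rel_dtau > tau2_tol) stall + 1L else 0L
    if (stall >= 12L) {
      for (j in st$pen_idx) {
        tau2[j] <- profile_tau2(j, tau2, y, psi, b, st, blocks, lk, R, tol)
      }
      stall <- 0L
    }
  }

  # final state: one clean inner solve, covariance, edf, gcv
  Pm <- penalty_matrix(blocks, st, tau2)
  inner <- inner_scoring(y, psi, b, st$X, Pm, lk, R, max_steps = 25L, tol = tol)
  psi <- inner$psi; b <- inner$b
  fin <- final_state(y, psi, b, st, blocks, tau2, Pm, lk, R)

  q_par <- if (st$has_par) length(st$cols[[1L]]) else 0L
  edf_total <- sum(fin$edf_term[st$pen_idx]) +
    sum(vapply(blocks[st$stop_idx], function(bl) bl$null_dim_frozen, numeric(1L))) +
    q_par + (R - 1L)
  dev <- -2 * fin$ll
  gcv <- n * dev / (n - edf_total)^2

  theta <- psi_to_theta(psi, R)
  sm <- smooth_summary(blocks, st, tau2, fin, stop_tau2)

  structure(list(
    formula = formula, link = link, n = n, n_cat = R,
    thresholds = theta, psi = psi, coef = stats::setNames(b, st$colnames),
    blocks = blocks, cols = st$cols, colnames = st$colnames,
    has_par = st$has_par,
    vcov = fin$vcov_nat,       # (R-1 + p) x (R-1 + p), natural theta scale
    tau2 = tau2,
    param_table = param_table(theta, b, st, fin, R),
    smooth_table = sm,
    loglik = fin$ll, deviance = dev, edf_total = edf_total, gcv = gcv,
    edf_term = fin$edf_term,
    converged = converged, iterations = it, pd_trace = pd_trace,
    graph = attr(blocks, "graph"),
    zone_counts = attr(blocks, "zone_counts"),
    coding_direction = "insecurity-ascending",
    stop_tau2 = stop_tau2
  ), class = "ordstar_fit")
}

# ---- formula parsing ------------------------------------------------------

parse_ordstar_formula <- function(formula) {
  if (length(formula) != 3L) stop("formula needs an outcome on the left")
  outcome <- deparse(formula[[2L]])
  tl <- attr(stats::terms(formula), "term.labels")
  specials <- list()
  parametric <- character(0)
  cap <- function(x, ...) list(var = deparse(substitute(x)), ...)
  env <- list2env(list(s = cap, mrf = cap, tp = cap, re = cap))
  for (lab in tl) {
    type <- sub("\\(.*$", "", lab)
    if (type %in% c("s", "mrf", "tp", "re") && grepl("^\\w+\\(", lab)) {
      spec <- eval(parse(text = lab)[[1L]], envir = env)
      spec$type <- type
      spec$label <- lab
      specials[[length(specials) + 1L]] <- spec
    } else {
      parametric <- c(parametric, lab)
    }
  }
  if (sum(vapply(specials, function(s) s$type == "mrf", logical(1L))) > 1L ||
      sum(vapply(specials, function(s) s$type == "tp", logical(1L))) > 1L) {
    stop("at most one mrf() and one tp() term are allowed")
  }
  list(outcome = outcome, parametric = parametric, specials = specials)
}

# ---- block construction ---------------------------------------------------

build_blocks <- function(data, pf, graph) {
  blocks <- list()
  zone_counts <- NULL
  if (length(pf$parametric)) {
    fpar <- stats::reformulate(pf$parametric, intercept = TRUE)
    Xp <- stats::model.matrix(fpar, data = data)[, -1L, drop = FALSE]
    blocks[[length(blocks) + 1L]] <-
      new_term_block("parametric", "parametric", Xp, K = NULL)
  }
  for (sp in pf$specials) {
    if (sp$type == "s") {
      x <- data[[sp$var]]
      if (is.null(x)) stop("variable '", sp$var, "' not found")
      bd <- bspline_design(x,
                           n_knots = sp$n_knots %||% 20L,
                           degree = sp$degree %||% 3L)
      K <- diff_penalty(ncol(bd$B), order = sp$order %||% 2L)
      bl <- new_term_block(sp$label, "pspline", bd$B, K,
                           meta = list(var = sp$var, knots = bd$knots,
                                       xrange = bd$xrange,
                                       degree = bd$degree,
                                       order = sp$order %||% 2L,
                                       x_obs = x))
      bl <- scale_penalty(absorb_constraint(bl))
      blocks[[length(blocks) + 1L]] <- bl
    } else {
      if (is.null(graph)) stop("spatial term '", sp$label, "' needs `graph`")
      zlab <- as.character(data[[sp$var]])
      if (anyNA(match(zlab, graph$zones))) {
        stop("record zone(s) not present in graph")
      }
      if (is.null(zone_counts)) {
        zone_counts <- table(factor(zlab, levels = graph$zones))
      }
      if (sp$type == "mrf") {
        deg <- zone_degree(graph)
        keep <- graph$zones[deg > 0L]
        islands <- graph$zones[deg == 0L]
        if (length(keep) < 2L) stop("MRF term needs a graph with edges")
        j <- match(zlab, keep)
        ok <- !is.na(j)
        X <- Matrix::sparseMatrix(i = which(ok), j = j[ok], x = 1,
                                  dims = c(length(zlab), length(keep)),
                                  dimnames = list(NULL, keep))
        K <- mrf_penalty(graph)[keep, keep, drop = FALSE]
        bl <- new_term_block(sp$label, "mrf", X, K,
                             meta = list(var = sp$var, zones = keep,
                                         islands = islands))
        bl <- scale_penalty(absorb_constraint(bl, cvec = rep(1, length(keep))))
        blocks[[length(blocks) + 1L]] <- bl
      } else if (sp$type == "re") {
        ib <- iid_block(zlab, graph)
        bl <- new_term_block(sp$label, "iid", ib$X, ib$K,
                             meta = list(var = sp$var, zones = graph$zones))
        bl <- scale_penalty(absorb_constraint(bl,
                                              cvec = rep(1, length(graph$zones))))
        blocks[[length(blocks) + 1L]] <- bl
      } else { # tp
        if (is.null(graph$centroids)) {
          stop("tp() needs centroids on the zone graph")
        }
        td <- tensor_design(graph$centroids$lon, graph$centroids$lat,
                            n_knots = sp$n_knots %||% 8L,
                            degree = sp$degree %||% 3L)
        j <- match(zlab, graph$zones)
        X <- td$B[j, , drop = FALSE]
        bl <- new_term_block(sp$label, "tensor", X, td$K,
                             meta = list(var = sp$var, zones = graph$zones,
                                         B_zone = td$B, p = td$p, q = td$q))
        bl <- scale_penalty(absorb_constraint(bl, cvec = colSums(td$B)))
        blocks[[length(blocks) + 1L]] <- bl
      }
    }
  }
  if (!length(blocks)) stop("model has no terms")
  attr(blocks, "graph") <- graph
  attr(blocks, "zone_counts") <- zone_counts
  blocks
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assemble_blocks <- function(blocks) {
  ps <- vapply(blocks, function(bl) ncol(bl$X), integer(1L))
  ends <- cumsum(ps)
  cols <- lapply(seq_along(blocks), function(j) {
    if (ps[j] == 0L) integer(0) else (ends[j] - ps[j] + 1L):ends[j]
  })
  X <- do.call(cbind, lapply(blocks, `[[`, "X"))
  cn <- unlist(lapply(seq_along(blocks), function(j) {
    if (ps[j] == 0L) return(character(0))
    nm <- colnames(blocks[[j]]$X)
    if (is.null(nm)) nm <- paste0(blocks[[j]]$name, ".", seq_len(ps[j]))
    if (blocks[[j]]$name != "parametric" && ps[j] > 0L) {
      nm <- paste0(blocks[[j]]$name, ".", seq_len(ps[j]))
    }
    nm
  }))
  pen_idx <- which(vapply(blocks, function(bl) bl$penalized && !bl$stopped,
                          logical(1L)))
  stop_idx <- which(vapply(blocks, `[[`, logical(1L), "stopped"))
  list(X = X, cols = cols, colnames = cn,
       has_par = blocks[[1L]]$name == "parametric",
       pen_idx = pen_idx, stop_idx = stop_idx)
}

penalty_matrix <- function(blocks, st, tau2) {
  p <- ncol(st$X)
  Pm <- matrix(0, p, p)
  for (j in seq_along(blocks)) {
    bl <- blocks[[j]]
    if (bl$penalized && !bl$stopped && length(st$cols[[j]])) {
      Pm[st$cols[[j]], st$cols[[j]]] <- bl$K / tau2[j]
    }
  }
  Pm
}

freeze_block <- function(bl, b_cur) {
  bl$stopped <- TRUE
  bl$null_dim_frozen <- bl$null_dim
  if (bl$null_dim > 0L) {
    eg <- eigen(bl$K, symmetric = TRUE)
    N <- eg$vectors[, ncol(bl$K) - seq_len(bl$null_dim) + 1L, drop = FALSE]
    bl$X <- bl$X %*% N
    bl$map <- bl$map %*% N
    bl$freeze_proj <- t(N)
    bl$K <- NULL
    bl$penalized <- FALSE
    bl$null_dim <- 0L
  } else {
    bl$X <- bl$X[, integer(0), drop = FALSE]
    bl$map <- bl$map[, integer(0), drop = FALSE]
    bl$freeze_proj <- matrix(0, 0L, length(b_cur))
    bl$K <- NULL
    bl$penalized <- FALSE
  }
  bl
}

# ---- scoring machinery ----------------------------------------------------

psi_to_theta <- function(psi, R) {
  if (R == 2L) return(psi[1L])
  cumsum(c(psi[1L], exp(psi[2:(R - 1L)])))
}

theta_jacobian <- function(psi, R) {
  # J[r, s] = d theta_r / d psi_s ; lower-triangular pattern
  J <- matrix(0, R - 1L, R - 1L)
  J[, 1L] <- 1
  if (R > 2L) {
    for (s in 2:(R - 1L)) J[s:(R - 1L), s] <- exp(psi[s])
  }
  J
}

pen_dev <- function(y, psi, b, X, Pm, lk, R) {
  theta <- psi_to_theta(psi, R)
  eta <- as.numeric(X %*% b)
  P <- category_probs(eta, theta, lk$name)
  ll <- sum(log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-300)))
  -2 * ll + as.numeric(t(b) %*% Pm %*% b)
}

inner_scoring <- function(y, psi, b, X, Pm, lk, R, max_steps = 25L,
                          tol = 1e-7) {
  pd <- pen_dev(y, psi, b, X, Pm, lk, R)
  M_last <- NULL
  for (step in seq_len(max_steps)) {
    theta <- psi_to_theta(psi, R)
    eta <- as.numeric(X %*% b)
    si <- ordinal_score_info(y, eta, theta, lk, X)
    J <- theta_jacobian(psi, R)
    s_full <- c(t(J) %*% si$s_theta, si$s_coef - Pm %*% b)
    Att <- t(J) %*% si$Itt %*% J
    Atc <- t(J) %*% si$Itc
    M_last <- rbind(cbind(Att, Atc), cbind(t(Atc), si$Icc))
    A <- M_last
    ic <- (R - 1L) + seq_len(ncol(X))
    A[ic, ic] <- A[ic, ic] + Pm
    delta <- solve_psd(A, s_full)
    # step halving on the penalized deviance
    fac <- 1
    for (h in seq_len(30L)) {
      psi_n <- psi + fac * delta[seq_len(R - 1L)]
      b_n <- b + fac * delta[-seq_len(R - 1L)]
      pd_n <- pen_dev(y, psi_n, b_n, X, Pm, lk, R)
      if (is.finite(pd_n) && pd_n <= pd + 1e-10) break
      fac <- fac / 2
    }
    if (!is.finite(pd_n) || pd_n > pd + 1e-10) break  # no improving step
    psi <- psi_n; b <- b_n
    improved <- pd - pd_n
    pd <- pd_n
    if (improved < tol * (abs(pd) + 0.1)) break
  }
  list(psi = psi, b = b, pd = pd, M = M_last)
}

solve_psd <- function(A, rhs) {
  out <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(out)) {
    out <- solve(A + diag(1e-8 * max(diag(A)), nrow(A)), rhs)
  }
  out
}

# Laplace-approximate restricted likelihood at fixed variances (additive
# constants dropped); used as the stall fallback for variance updates
reml_criterion <- function(y, psi, b, st, blocks, tau2, lk, R, tol) {
  Pm <- penalty_matrix(blocks, st, tau2)
  inner <- inner_scoring(y, psi, b, st$X, Pm, lk, R, max_steps = 8L,
                         tol = tol * 10)
  psi <- inner$psi; b <- inner$b
  theta <- psi_to_theta(psi, R)
  eta <- as.numeric(st$X %*% b)
  ll <- ordinal_loglik(y, eta, theta, lk$name)$loglik
  p <- ncol(st$X)
  A <- inner$M
  ic <- (R - 1L) + seq_len(p)
  A[ic, ic] <- A[ic, ic] + Pm
  ld <- as.numeric(Matrix::determinant(Matrix::Matrix(A), logarithm = TRUE)$modulus)
  pen <- as.numeric(t(b) %*% Pm %*% b)
  logtau_term <- 0
  for (j in st$pen_idx) {
    pj <- length(st$cols[[j]])
    logtau_term <- logtau_term +
      (pj - blocks[[j]]$null_dim) * log(tau2[j])
  }
  ll - 0.5 * pen - 0.5 * ld - 0.5 * logtau_term
}

profile_tau2 <- function(j, tau2, y, psi, b, st, blocks, lk, R, tol) {
  f <- function(lt) {
    t2 <- tau2; t2[j] <- exp(lt)
    reml_criterion(y, psi, b, st, blocks, t2, lk, R, tol)
  }
  grid <- seq(log(1e-9), log(tau2[j]) + 2, length.out = 9L)
  vals <- vapply(grid, f, numeric(1L))
  k <- which.max(vals)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  if (lo == hi) return(exp(grid[k]))
  exp(stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 0.05)$maximum)
}

edf_from_M <- function(M, Pm, R, p) {
  Pfull <- matrix(0, nrow(M), ncol(M))
  ic <- (R - 1L) + seq_len(p)
  Pfull[ic, ic] <- Pm
  H <- tryCatch(solve(M + Pfull, M), error = function(e) {
    solve(M + Pfull + diag(1e-8 * max(diag(M)), nrow(M)), M)
  })
  diag(H)[ic]
}

# effective df per term: block trace of (Fisher + penalty)^{-1} Fisher
edf_state <- function(y, psi, b, X, Pm, lk, R) {
  theta <- psi_to_theta(psi, R)
  eta <- as.numeric(X %*% b)
  si <- ordinal_score_info(y, eta, theta, lk, X)
  J <- theta_jacobian(psi, R)
  Att <- t(J) %*% si$Itt %*% J
  Atc <- t(J) %*% si$Itc
  M <- rbind(cbind(Att, Atc), cbind(t(Atc), si$Icc))
  p <- ncol(X)
  Pfull <- matrix(0, nrow(M), ncol(M))
  Pfull[(R - 1L) + seq_len(p), (R - 1L) + seq_len(p)] <- Pm
  H <- tryCatch(solve(M + Pfull, M), error = function(e) {
    solve(M + Pfull + diag(1e-8 * max(diag(M)), nrow(M)), M)
  })
  dg <- diag(H)[(R - 1L) + seq_len(p)]
  list(diag = dg, M = M, Pfull = Pfull)
}

# wrapper giving per-block traces (needs the column map)
edf_by_block <- function(dg, cols) {
  vapply(cols, function(ix) if (length(ix)) sum(dg[ix]) else 0, numeric(1L))
}

final_state <- function(y, psi, b, st, blocks, tau2, Pm, lk, R) {
  theta <- psi_to_theta(psi, R)
  eta <- as.numeric(st$X %*% b)
  si <- ordinal_score_info(y, eta, theta, lk, st$X)
  J <- theta_jacobian(psi, R)
  Att <- t(J) %*% si$Itt %*% J
  Atc <- t(J) %*% si$Itc
  M <- rbind(cbind(Att, Atc), cbind(t(Atc), si$Icc))
  p <- ncol(st$X)
  Pfull <- matrix(0, nrow(M), ncol(M))
  Pfull[(R - 1L) + seq_len(p), (R - 1L) + seq_len(p)] <- Pm
  A <- M + Pfull
  V <- tryCatch(solve(A), error = function(e) {
    solve(A + diag(1e-8 * max(diag(A)), nrow(A)))
  })
  H <- V %*% M
  dg <- diag(H)[(R - 1L) + seq_len(p)]
  edf_term <- edf_by_block(dg, st$cols)
  # delta-method covariance on the natural threshold scale
  Jfull <- diag(nrow(A))
  Jfull[seq_len(R - 1L), seq_len(R - 1L)] <- J
  vcov_nat <- Jfull %*% V %*% t(Jfull)
  ll <- ordinal_loglik(y, eta, theta, lk$name)$loglik
  list(ll = ll, vcov_nat = vcov_nat, edf_term = edf_term, H_diag = dg)
}

param_table <- function(theta, b, st, fin, R) {
  est <- theta
  nm <- paste0("theta_", seq_len(R - 1L))
  idx <- seq_len(R - 1L)
  if (st$has_par && length(st$cols[[1L]])) {
    est <- c(est, b[st$cols[[1L]]])
    nm <- c(nm, st$colnames[st$cols[[1L]]])
    idx <- c(idx, (R - 1L) + st$cols[[1L]])
  }
  se <- sqrt(pmax(diag(fin$vcov_nat)[idx], 0))
  z <- unname(est / se)
  tibble::tibble(term = nm, estimate = unname(est), std.error = unname(se),
                 statistic = z, p.value = 2 * stats::pnorm(-abs(z)))
}

smooth_summary <- function(blocks, st, tau2, fin, stop_tau2) {
  rows <- list()
  for (j in seq_along(blocks)) {
    bl <- blocks[[j]]
    if (bl$name == "parametric") next
    stopped <- bl$stopped
    t2s <- if (stopped) bl$tau2_at_stop %||% 0 else tau2[j]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      term = bl$name, kind = bl$kind,
      variance = t2s * bl$scale,           # natural penalty scale
      smooth_par = if (t2s > 0) 1 / t2s else Inf,  # scaled-penalty lambda
      df = if (stopped) bl$null_dim_frozen + 0 else fin$edf_term[j],
      stopped = as.integer(stopped)
    )
  }
  dplyr::bind_rows(rows)
}

#' Effective degrees of freedom of a fitted model
#'
#' Per-term block traces of `(Fisher + penalty)^{-1} Fisher`, plus the
#' parametric and threshold counts; `total` matches the edf used in the
#' model's GCV.
#'
#' @param fit an `ordstar_fit`.
#' @return tibble with one row per term and an attribute `total`.
#' @export
effective_df <- function(fit) {
  stopifnot(inherits(fit, "ordstar_fit"))
  out <- tibble::tibble(
    term = vapply(fit$blocks, `[[`, "", "name"),
    kind = vapply(fit$blocks, `[[`, "", "kind"),
    edf = ifelse(vapply(fit$blocks, `[[`, logical(1L), "stopped"),
                 vapply(fit$blocks, function(b) b$null_dim_frozen + 0,
                        numeric(1L)),
                 fit$edf_term)
  )
  attr(out, "total") <- fit$edf_total
  out
}

#' Generalized cross-validation score
#'
#' `GCV = n * deviance / (n - edf_total)^2`; smaller is better.  Comparable
#' only across models fitted to the same records under the same outcome
#' coding.
#'
#' @param fit an `ordstar_fit`.
#' @return scalar.
#' @export
gcv <- function(fit) {
  stopifnot(inherits(fit, "ordstar_fit"))
  if (fit$edf_total >= fit$n) stop("effective df exceeds the sample size")
  fit$gcv
}
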