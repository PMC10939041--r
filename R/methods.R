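#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.ordstar_fit <- function(x, ...) {
  cat("<ordstar_fit> cumulative-", x$link, " structured additive model\n",
      sep = "")
  cat("  n = ", x$n, ", categories = ", x$n_cat,
      " (", x$coding_direction, ")\n", sep = "")
  cat("  thresholds: ", paste(sprintf("%.4f", x$thresholds), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  deviance %.4f  edf %.2f  GCV %.4f  (%s, %d iterations)\n",
              x$deviance, x$edf_total, x$gcv,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Tidy a fitted ordinal STAR model
#'
#' `effects = "parametric"` (default) gives the threshold and linear
#' coefficients with standard errors, z statistics and two-sided normal
#' p-values (standard errors from the Bayesian covariance
#' `(Fisher + penalty)^{-1}`).  `effects = "smooths"` gives one row per
#' smooth/spatial term: variance (natural penalty scale), smoothing
#' parameter `lambda = 1/tau^2` (scaled-penalty space), effective df, and
#' the small-variance stop flag.
#'
#' @param x an `ordstar_fit`.
#' @param effects `"parametric"` or `"smooths"`.
#' @param ... unused.
#' @method tidy ordstar_fit
#' @export
tidy.ordstar_fit <- function(x, effects = c("parametric", "smooths"), ...) {
  effects <- match.arg(effects)
  if (effects == "parametric") x$param_table else x$smooth_table
}

#' One-row model summary
#'
#' @param x an `ordstar_fit`.
#' @param ... unused.
#' @method glance ordstar_fit
#' @export
glance.ordstar_fit <- function(x, ...) {
  tibble::tibble(n = x$n, link = x$link, logLik = x$loglik,
                 deviance = x$deviance, edf = x$edf_total, gcv = x$gcv,
                 converged = x$converged, iterations = x$iterations)
}

find_block <- function(fit, term, kinds = NULL) {
  nms <- vapply(fit$blocks, `[[`, "", "name")
  knd <- vapply(fit$blocks, `[[`, "", "kind")
  j <- which(nms == term)
  if (!length(j)) {
    # allow bare variable name for s(var) etc.
    vars <- vapply(fit$blocks, function(b) b$meta$var %||% "", "")
    j <- which(vars == term & (is.null(kinds) | knd %in% (kinds %||% knd)))
  }
  if (!is.null(kinds)) j <- j[knd[j] %in% kinds]
  if (length(j) != 1L) stop("cannot identify term '", term, "'")
  j
}

block_coef <- function(fit, j) fit$coef[fit$cols[[j]]]

block_vcov <- function(fit, j, k = j) {
  off <- fit$n_cat - 1L
  fit$vcov[off + fit$cols[[j]], off + fit$cols[[k]], drop = FALSE]
}

#' Evaluate a fitted smooth with pointwise 95% band
#'
#' Evaluates a P-spline term (possibly frozen to its linear nullspace by the
#' stop rule) on a grid inside the observed covariate range; extrapolation
#' is refused.  Bands are `estimate +/- z * SE` with SE from the Bayesian
#' coefficient covariance.  The fitted curve is centred by construction
#' (sum-to-zero over the observed covariate values).
#'
#' @param fit an `ordstar_fit`.
#' @param term term label (`"s(coping)"`) or bare variable name.
#' @param grid evaluation points; default an equally spaced grid of
#'   `n_grid` points over the observed range.
#' @param n_grid grid size.
#' @param level band coverage (default 0.95).
#' @return tibble with columns `term`, `x`, `estimate`, `lower`, `upper`.
#' @export
smooth_curve <- function(fit, term, grid = NULL, n_grid = 100L,
                         level = 0.95) {
  stopifnot(inherits(fit, "ordstar_fit"))
  j <- find_block(fit, term, kinds = "pspline")
  bl <- fit$blocks[[j]]
  m <- bl$meta
  if (is.null(grid)) grid <- seq(m$xrange[1L], m$xrange[2L],
                                 length.out = n_grid)
  if (any(grid < m$xrange[1L] | grid > m$xrange[2L])) {
    stop("grid outside the observed range; extrapolation is refused")
  }
  Bg <- splines::splineDesign(m$knots, grid, ord = m$degree + 1L,
                              outer.ok = TRUE)
  Mmap <- as.matrix(Bg %*% bl$map)
  est <- as.numeric(Mmap %*% block_coef(fit, j))
  V <- block_vcov(fit, j)
  se <- sqrt(pmax(rowSums((Mmap %*% V) * Mmap), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(term = bl$name, x = grid, estimate = est,
                 lower = est - zq * se, upper = est + zq * se)
}

zone_block_values <- function(fit, j) {
  bl <- fit$blocks[[j]]
  if (bl$kind == "tensor") {
    Zm <- as.matrix(bl$meta$B_zone %*% bl$map)
    zones <- bl$meta$zones
  } else {
    Zm <- as.matrix(bl$map)
    zones <- bl$meta$zones
  }
  if (ncol(Zm) == 0L) {
    return(list(zones = zones, est = rep(0, length(zones)),
                var = rep(0, length(zones)), Zm = Zm))
  }
  est <- as.numeric(Zm %*% block_coef(fit, j))
  V <- block_vcov(fit, j)
  list(zones = zones, est = est,
       var = pmax(rowSums((Zm %*% V) * Zm), 0), Zm = Zm)
}

#' Per-zone spatial effects with hot/cold-spot classification
#'
#' Posterior-mode structured (MRF or tensor) and unstructured (i.i.d.) zone
#' effects, their sum, a 95% band for the sum, and a classification under
#' the insecurity-ascending coding: `hot` if the band lies above zero
#' (significantly higher food insecurity), `cold` if below, else `neutral`.
#' Island zones carry no structured effect (they are excluded from the MRF
#' block); zones without records are flagged `no_data`.
#'
#' @param fit an `ordstar_fit` containing at least one spatial term.
#' @param level band coverage.
#' @return tibble with columns `zone`, `structured`, `unstructured`,
#'   `total`, `lower`, `upper`, `class`, `n_records`, `no_data`.
#' @export
zone_effects <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ordstar_fit"))
  kinds <- vapply(fit$blocks, `[[`, "", "kind")
  js <- which(kinds %in% c("mrf", "tensor"))[1L]
  ju <- which(kinds == "iid")[1L]
  if (is.na(js) && is.na(ju)) stop("model has no spatial terms")
  zones <- fit$graph$zones
  n <- length(zones)
  str_e <- str_v <- uns_e <- uns_v <- rep(0, n)
  cov_su <- rep(0, n)
  if (!is.na(js)) {
    zb <- zone_block_values(fit, js)
    idx <- match(zb$zones, zones)
    str_e[idx] <- zb$est; str_v[idx] <- zb$var
  }
  if (!is.na(ju)) {
    zb_u <- zone_block_values(fit, ju)
    idx_u <- match(zb_u$zones, zones)
    uns_e[idx_u] <- zb_u$est; uns_v[idx_u] <- zb_u$var
    if (!is.na(js) && ncol(zb$Zm) && ncol(zb_u$Zm)) {
      Vsu <- block_vcov(fit, js, ju)
      cv <- rowSums((zb$Zm %*% Vsu) * zb_u$Zm[match(zb$zones, zb_u$zones), ,
                                              drop = FALSE])
      cov_su[match(zb$zones, zones)] <- cv
    }
  }
  tot <- str_e + uns_e
  se <- sqrt(pmax(str_v + uns_v + 2 * cov_su, 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  lo <- tot - zq * se; hi <- tot + zq * se
  cls <- ifelse(lo > 0, "hot", ifelse(hi < 0, "cold", "neutral"))
  nr <- if (!is.null(fit$zone_counts)) {
    as.integer(fit$zone_counts[zones])
  } else NA_integer_
  tibble::tibble(zone = zones, structured = str_e, unstructured = uns_e,
                 total = tot, lower = lo, upper = hi, class = cls,
                 n_records = nr, no_data = !is.na(nr) & nr == 0L)
}

#' Structured share of the spatial variation
#'
#' `100 * tau2_str / (tau2_str + tau2_unstr)`, the percentage of the total
#' zone-level variation explained by the spatially structured effect, on
#' the natural (unscaled-penalty) variance scale.
#'
#' @param x an `ordstar_fit`, or a length-2 numeric
#'   `c(tau2_structured, tau2_unstructured)`.
#' @param digits decimals for the returned percentage (default 2).
#' @param ... unused.
#' @return scalar percentage (`NA` with a warning if both variances are
#'   stopped/zero).
#' @export
variance_partition <- function(x, digits = 2L, ...) {
  UseMethod("variance_partition")
}

#' @export
variance_partition.numeric <- function(x, digits = 2L, ...) {
  stopifnot(length(x) == 2L, all(x >= 0))
  if (sum(x) == 0) {
    warning("both variances are zero; partition undefined")
    return(NA_real_)
  }
  round_half_up(100 * x[1L] / sum(x), digits)
}

#' @export
variance_partition.ordstar_fit <- function(x, digits = 2L, ...) {
  sm <- x$smooth_table
  str_row <- sm[sm$kind %in% c("mrf", "tensor"), , drop = FALSE]
  uns_row <- sm[sm$kind == "iid", , drop = FALSE]
  if (!nrow(str_row) || !nrow(uns_row)) {
    stop("need both a structured and an unstructured spatial term")
  }
  v <- c(ifelse(str_row$stopped[1L] == 1L, 0, str_row$variance[1L]),
         ifelse(uns_row$stopped[1L] == 1L, 0, uns_row$variance[1L]))
  variance_partition(v, digits = digits)
}

#' Plot fitted smooth terms
#'
#' One ribbon panel per P-spline term.
#'
#' @param object an `ordstar_fit`.
#' @param terms optional character vector of term labels to include.
#' @param ... passed to [smooth_curve()].
#' @method autoplot ordstar_fit
#' @export
autoplot.ordstar_fit <- function(object, terms = NULL, ...) {
  kinds <- vapply(object$blocks, `[[`, "", "kind")
  labs <- vapply(object$blocks, `[[`, "", "name")[kinds == "pspline"]
  if (!is.null(terms)) labs <- intersect(labs, terms)
  if (!length(labs)) stop("no P-spline terms to plot")
  cur <- dplyr::bind_rows(lapply(labs, function(tm) {
    smooth_curve(object, tm, ...)
  }))
  ggplot2::ggplot(cur, ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "partial effect (latent scale)")
}

#' Map zone effects on centroid coordinates
#'
#' Tile map of a zone-effect column using the graph centroids; a fallback
#' for quick inspection when no polygon shapes are at hand.
#'
#' @param fit an `ordstar_fit` whose graph carries centroids.
#' @param what column of [zone_effects()] to map.
#' @export
plot_zone_effects <- function(fit, what = c("total", "structured",
                                            "unstructured", "class")) {
  what <- match.arg(what)
  if (is.null(fit$graph$centroids)) stop("graph has no centroids")
  ze <- dplyr::left_join(zone_effects(fit), fit$graph$centroids, by = "zone")
  ggplot2::ggplot(ze, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = what)
}

#' @importFrom rlang .data
NULL
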