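#' B-spline design matrix on equally spaced knots
#'
#' Builds a clamped B-spline basis of the given degree on `n_knots` equally
#' spaced knots spanning `[min(x), max(x)]` (boundary knots replicated to
#' full multiplicity), giving `n_knots - 1 + degree` basis functions (22 for
#' the defaults).  Rows form a partition of unity on the knot range.
#'
#' @param x numeric vector with `min(x) < max(x)`.
#' @param n_knots number of equally spaced knots (>= 4 for cubic work; >= 2
#'   generally).
#' @param degree polynomial degree (3 = cubic).
#' @param xrange optional length-2 range overriding `range(x)` (used when
#'   evaluating a stored basis on a new grid).
#' @return list with `B` (n x p matrix), `knots` (augmented knot vector),
#'   `xrange`, `n_knots`, `degree`.
#' @export
bspline_design <- function(x, n_knots = 20L, degree = 3L, xrange = NULL) {
  if (!all(is.finite(x))) stop("`x` must be finite")
  if (is.null(xrange)) xrange <- range(x)
  if (xrange[1L] >= xrange[2L]) {
    stop("`x` is constant; model this variable parametrically instead")
  }
  if (n_knots < 2L) stop("need at least 2 knots")
  if (any(x < xrange[1L] | x > xrange[2L])) {
    stop("`x` outside the basis range; extrapolation is refused")
  }
  kn <- seq(xrange[1L], xrange[2L], length.out = n_knots)
  aug <- c(rep(xrange[1L], degree), kn, rep(xrange[2L], degree))
  B <- splines::splineDesign(aug, x, ord = degree + 1L, outer.ok = TRUE)
  list(B = B, knots = aug, xrange = xrange, n_knots = n_knots, degree = degree)
}

#' Random-walk difference penalty
#'
#' `K = t(D) %*% D` with `D` the order-th difference operator on `p`
#' coefficients; symmetric PSD of rank `p - order` (its nullspace holds the
#' polynomials of degree `< order`).
#'
#' @param p number of coefficients.
#' @param order difference order, 1 or 2.
#' @export
diff_penalty <- function(p, order = 2L) {
  stopifnot(order %in% c(1L, 2L), p > order)
  D <- diff(diag(p), differences = order)
  crossprod(D)
}

#' Markov random field penalty (graph Laplacian)
#'
#' `K[i,i] = degree(i)`, `K[i,j] = -1` iff zones i and j are neighbours,
#' else 0; rank is `N - #components`.  Island zones yield zero rows, which
#' the fitter removes from the MRF block.
#'
#' @param g a [zone_graph()].
#' @export
mrf_penalty <- function(g) {
  A <- adjacency_matrix(g)
  diag(rowSums(A)) - A
}

row_tensor <- function(A, B) {
  # row-wise Kronecker: n x (pA*pB), column (i-1)*pB + j  = A[,i]*B[,j]
  stopifnot(nrow(A) == nrow(B))
  out <- matrix(0, nrow(A), ncol(A) * ncol(B))
  for (i in seq_len(ncol(A))) {
    out[, (i - 1L) * ncol(B) + seq_len(ncol(B))] <- A[, i] * B
  }
  out
}

#' Tensor-product P-spline design and penalty for coordinates
#'
#' Marginal B-spline bases in longitude and latitude (each standardized to
#' `[0, 1]` before knot placement) combined by the row-wise tensor product;
#' the penalty is the Kronecker sum `K_lon %x% I + I %x% K_lat` with
#' first-order difference marginals (a two-dimensional first-order random
#' walk), whose nullspace on a connected grid is the constant surface.
#'
#' @param lon,lat numeric coordinate vectors (one entry per evaluation
#'   point, typically zone centroids).
#' @param n_knots knots per margin.
#' @param degree marginal spline degree.
#' @param order marginal difference-penalty order (default 1).
#' @return list with `B`, `K`, marginal sizes `p`, `q`, and the marginal
#'   basis metadata.
#' @export
tensor_design <- function(lon, lat, n_knots = 8L, degree = 3L, order = 1L) {
  if (length(unique(lon)) < 2L || length(unique(lat)) < 2L) {
    stop("centroids are degenerate (collinear on one axis)")
  }
  s1 <- (lon - min(lon)) / diff(range(lon))
  s2 <- (lat - min(lat)) / diff(range(lat))
  b1 <- bspline_design(s1, n_knots = n_knots, degree = degree,
                       xrange = c(0, 1))
  b2 <- bspline_design(s2, n_knots = n_knots, degree = degree,
                       xrange = c(0, 1))
  p <- ncol(b1$B); q <- ncol(b2$B)
  K <- diff_penalty(p, order) %x% diag(q) + diag(p) %x% diff_penalty(q, order)
  list(B = row_tensor(b1$B, b2$B), K = K, p = p, q = q,
       basis_lon = b1, basis_lat = b2)
}

#' Incidence design for i.i.d. zone random effects
#'
#' One column per zone of the graph (record x zone 0/1 incidence); penalty
#' is the identity (full rank).  Zones without records keep their column:
#' their effect is shrunk to zero by the penalty alone.
#'
#' @param zone character vector of record zone labels.
#' @param g a [zone_graph()].
#' @return list with `X` (sparse incidence) and `K` (identity).
#' @export
iid_block <- function(zone, g) {
  stopifnot(inherits(g, "zone_graph"))
  j <- match(as.character(zone), g$zones)
  if (anyNA(j)) stop("record zone(s) not in graph")
  X <- Matrix::sparseMatrix(i = seq_along(j), j = j, x = 1,
                            dims = c(length(j), length(g$zones)),
                            dimnames = list(NULL, g$zones))
  list(X = X, K = diag(length(g$zones)))
}

# -- term blocks ------------------------------------------------------------

new_term_block <- function(name, kind, X, K, meta = list()) {
  X <- methods::as(methods::as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  structure(list(name = name, kind = kind, X = X, K = K,
                 map = diag(ncol(X)),   # full-basis -> current columns
                 scale = 1, null_dim = penalty_nulldim(K),
                 penalized = !is.null(K) && any(K != 0),
                 constrained = FALSE, stopped = FALSE, meta = meta),
            class = "term_block")
}

penalty_nulldim <- function(K, tol = 1e-8) {
  if (is.null(K) || all(K == 0)) return(if (is.null(K)) 0L else ncol(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  sum(ev < tol * max(ev))
}

#' Absorb a sum-to-zero identifiability constraint into a term block
#'
#' Reparameterizes the block so its fitted contribution sums to zero -- over
#' observations for covariate smooths, over zones for spatial and i.i.d.
#' blocks (pass the zone-level constraint vector via `cvec`).  The design
#' loses one column; the penalty is congruently transformed.  For a
#' second-order P-spline the linear trend remains in the block's penalty
#' nullspace and is tracked through `null_dim`.
#'
#' @param block a term block as built by [new_term_block()] (internal) or the
#'   lists returned by the basis constructors wrapped in one.
#' @param cvec constraint vector in coefficient space; default
#'   `colSums(X)` (sum-to-zero over observations).
#' @return the constrained block (idempotent: constrained input is returned
#'   unchanged).
#' @export
absorb_constraint <- function(block, cvec = NULL) {
  stopifnot(inherits(block, "term_block"))
  if (block$constrained) return(block)
  if (is.null(cvec)) cvec <- Matrix::colSums(block$X)
  cvec <- as.numeric(cvec)
  nv <- sqrt(sum(cvec^2))
  if (nv < 1e-12) stop("degenerate constraint vector")
  Tm <- qr.Q(qr(matrix(cvec / nv, ncol = 1L)), complete = TRUE)[, -1L,
                                                               drop = FALSE]
  block$X <- block$X %*% Tm
  if (!is.null(block$K)) {
    K <- t(Tm) %*% block$K %*% Tm
    block$K <- (K + t(K)) / 2
  }
  block$map <- block$map %*% Tm
  block$null_dim <- penalty_nulldim(block$K)
  block$constrained <- TRUE
  block
}

scale_penalty <- function(block) {
  # unit spectral radius so tau^2 values are numerically comparable; the
  # recorded factor converts back to the natural (unscaled-penalty) scale
  if (!block$penalized || block$scale != 1) return(block)
  s <- max(eigen(block$K, symmetric = TRUE, only.values = TRUE)$values)
  if (s <= 0) stop("penalty for term '", block$name, "' is null")
  block$K <- block$K / s
  block$scale <- s
  block
}
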