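#' Construct a zone contiguity graph
#'
#' A `zone_graph` holds an ordered set of zone labels, an undirected edge set
#' (no self-edges, stored as unordered pairs), and optionally zone centroid
#' coordinates.  The zone order is fixed at construction and defines the row
#' order of every matrix derived from the graph (adjacency, Markov random
#' field penalty, spatial weights).
#'
#' @param zones character vector of unique zone labels; the order is kept.
#' @param edges two-column matrix or data frame of zone labels (one edge per
#'   row), or `NULL` for an edgeless graph.
#' @param centroids optional data frame with columns `zone`, `lon`, `lat`.
#' @return an object of class `zone_graph`.
#' @export
zone_graph <- function(zones, edges = NULL, centroids = NULL) {
  zones <- as.character(zones)
  if (anyDuplicated(zones)) stop("zone labels must be unique")
  if (length(zones) < 1L) stop("need at least one zone")
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2L) stop("`edges` must have two columns")
    storage.mode(em) <- "character"
    bad <- setdiff(c(em), zones)
    if (length(bad)) {
      stop("edge endpoint(s) not in zone set: ", paste(bad, collapse = ", "))
    }
    if (any(em[, 1L] == em[, 2L])) stop("self-edges are not allowed")
    # canonical unordered pairs, deduplicated, in zone order
    i <- match(em[, 1L], zones)
    j <- match(em[, 2L], zones)
    a <- pmin(i, j); b <- pmax(i, j)
    keep <- !duplicated(cbind(a, b))
    o <- order(a[keep], b[keep])
    em <- cbind(zones[a[keep][o]], zones[b[keep][o]])
  }
  if (!is.null(centroids)) {
    centroids <- tibble::as_tibble(centroids)
    if (!all(c("zone", "lon", "lat") %in% names(centroids))) {
      stop("`centroids` needs columns zone, lon, lat")
    }
    centroids$zone <- as.character(centroids$zone)
    if (!setequal(centroids$zone, zones)) {
      stop("centroid zones must match the graph's zone set")
    }
    centroids <- centroids[match(zones, centroids$zone),
                           c("zone", "lon", "lat")]
    if (!all(is.finite(centroids$lon)) || !all(is.finite(centroids$lat))) {
      stop("centroid coordinates must be finite")
    }
  }
  structure(list(zones = zones, edges = em, centroids = centroids),
            class = "zone_graph")
}

#' @export
print.zone_graph <- function(x, ...) {
  cat("<zone_graph> ", length(x$zones), " zones, ", nrow(x$edges), " edges",
      if (!is.null(x$centroids)) ", with centroids", "\n", sep = "")
  invisible(x)
}

#' Number of zones and edge table
#'
#' @param g a [zone_graph()].
#' @return `graph_edges()` returns a tibble with columns `from`, `to`.
#' @export
graph_edges <- function(g) {
  stopifnot(inherits(g, "zone_graph"))
  tibble::tibble(from = g$edges[, 1L], to = g$edges[, 2L])
}

#' Binary adjacency matrix of a zone graph
#'
#' Symmetric with zero diagonal; row/column order is the graph's zone order.
#'
#' @param g a [zone_graph()].
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "zone_graph"))
  n <- length(g$zones)
  A <- matrix(0, n, n, dimnames = list(g$zones, g$zones))
  if (nrow(g$edges)) {
    i <- match(g$edges[, 1L], g$zones)
    j <- match(g$edges[, 2L], g$zones)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Zone degrees
#' @param g a [zone_graph()].
#' @return named integer vector in zone order.
#' @export
zone_degree <- function(g) {
  stopifnot(inherits(g, "zone_graph"))
  d <- stats::setNames(integer(length(g$zones)), g$zones)
  if (nrow(g$edges)) {
    t1 <- table(factor(g$edges[, 1L], levels = g$zones))
    t2 <- table(factor(g$edges[, 2L], levels = g$zones))
    d <- stats::setNames(as.integer(t1 + t2), g$zones)
  }
  d
}

#' Read a plain-text zone contiguity file
#'
#' Reads the whitespace-separated `.gra` dialect written by [write_gra()]:
#' the first token is the number of zones N, followed by N records of
#' `label  neighbour-count  neighbour-references`.  By default neighbour
#' references are zone *labels*; with `positions = TRUE` they are 1-based
#' positions in file order (the strict BayesX convention).
#'
#' Neighbour lists must be symmetric: if A lists B, B must list A.
#'
#' @param path file path.
#' @param positions logical; interpret neighbour references as 1-based
#'   positions instead of labels.
#' @return a [zone_graph()].
#' @export
read_gra <- function(path, positions = FALSE) {
  tok <- scan(path, what = "character", quiet = TRUE)
  if (!length(tok)) stop("empty graph file: ", path)
  n <- suppressWarnings(as.integer(tok[1L]))
  if (is.na(n) || n < 1L) stop("malformed zone-count line in ", path)
  k <- 2L
  labs <- character(n)
  nb <- vector("list", n)
  for (z in seq_len(n)) {
    if (k > length(tok)) stop("truncated graph file at zone ", z)
    labs[z] <- tok[k]
    cnt <- suppressWarnings(as.integer(tok[k + 1L]))
    if (is.na(cnt) || cnt < 0L) {
      stop("malformed neighbour count for zone '", labs[z], "'")
    }
    if (k + 1L + cnt > length(tok)) {
      stop("truncated neighbour list for zone '", labs[z], "'")
    }
    nb[[z]] <- tok[(k + 2L):(k + 1L + cnt)][seq_len(cnt)]
    k <- k + 2L + cnt
  }
  if (anyDuplicated(labs)) stop("duplicate zone labels in ", path)
  # resolve references
  idx <- lapply(seq_len(n), function(z) {
    r <- nb[[z]]
    if (!length(r)) return(integer())
    if (positions) {
      i <- suppressWarnings(as.integer(r))
      if (any(is.na(i)) || any(i < 1L) || any(i > n)) {
        stop("neighbour index out of range for zone '", labs[z], "'")
      }
    } else {
      i <- match(r, labs)
      if (anyNA(i)) {
        stop("unknown neighbour label(s) for zone '", labs[z], "': ",
             paste(r[is.na(i)], collapse = ", "))
      }
    }
    unique(i)
  })
  for (z in seq_len(n)) {
    if (z %in% idx[[z]]) stop("zone '", labs[z], "' lists itself as neighbour")
    for (j in idx[[z]]) {
      if (!(z %in% idx[[j]])) {
        stop("asymmetric neighbour lists: zone '", labs[z],
             "' lists '", labs[j], "' but not vice versa")
      }
    }
  }
  ed <- do.call(rbind, lapply(seq_len(n), function(z) {
    j <- idx[[z]][idx[[z]] > z]
    if (length(j)) cbind(labs[z], labs[j]) else NULL
  }))
  zone_graph(labs, ed)
}

#' Write a zone contiguity file
#'
#' Inverse of [read_gra()]: the round trip preserves zone order and the edge
#' set exactly.
#'
#' @param g a [zone_graph()].
#' @param path file path.
#' @param positions write neighbour references as 1-based positions
#'   (strict BayesX style) instead of labels.
#' @return `path`, invisibly.
#' @export
write_gra <- function(g, path, positions = FALSE) {
  stopifnot(inherits(g, "zone_graph"))
  A <- adjacency_matrix(g)
  lines <- as.character(length(g$zones))
  for (z in seq_along(g$zones)) {
    j <- which(A[z, ] == 1)
    refs <- if (positions) as.character(j) else g$zones[j]
    lines <- c(lines,
               paste(c(g$zones[z], length(j), refs), collapse = " "))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read zone centroids from CSV
#'
#' Expects a header `zone,lon,lat` with longitude and latitude in degrees.
#'
#' @param path CSV file path.
#' @return tibble with columns `zone`, `lon`, `lat`.
#' @export
read_centroids <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("zone", "lon", "lat") %in% names(x))) {
    stop("centroid CSV needs header zone,lon,lat")
  }
  tibble::as_tibble(x)[, c("zone", "lon", "lat")]
}

#' k-nearest-neighbour zone graph from centroids
#'
#' Links every zone to its `k` nearest zones by Euclidean distance on raw
#' (lon, lat), then symmetrizes by union: i-j is an edge if j is among i's k
#' nearest or vice versa, so degrees may exceed `k`.  Distance ties are
#' broken by ascending zone order.  No great-circle correction is applied;
#' the coordinates are used as given.
#'
#' @param centroids data frame with columns `zone`, `lon`, `lat`.
#' @param k number of nearest neighbours per zone (`1 <= k < n`).
#' @return a [zone_graph()] carrying the centroids.
#' @export
knn_graph <- function(centroids, k = 4L) {
  centroids <- tibble::as_tibble(centroids)
  stopifnot(all(c("zone", "lon", "lat") %in% names(centroids)))
  n <- nrow(centroids)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of zones")
  xy <- as.matrix(centroids[, c("lon", "lat")])
  if (!all(is.finite(xy))) stop("coordinates must be finite")
  D <- as.matrix(stats::dist(xy))
  ed <- NULL
  for (i in seq_len(n)) {
    # ties broken by ascending zone order: order() is stable on the index
    o <- order(D[i, -i], seq_len(n)[-i])[seq_len(k)]
    j <- seq_len(n)[-i][o]
    ed <- rbind(ed, cbind(centroids$zone[i], centroids$zone[j]))
  }
  zone_graph(centroids$zone, ed, centroids = centroids)
}

#' Structural report on a zone graph
#'
#' Lists connected components, island zones (degree 0), and the degree
#' distribution; purely diagnostic, never errors.
#'
#' @param g a [zone_graph()].
#' @return a list with elements `n_components`, `component` (named membership
#'   vector), `islands` (character vector), and `degrees` (tibble).
#' @export
validate_graph <- function(g) {
  stopifnot(inherits(g, "zone_graph"))
  ig <- igraph::graph_from_data_frame(
    d = as.data.frame(g$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = g$zones, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(ig)
  deg <- zone_degree(g)
  list(
    n_components = comp$no,
    component = stats::setNames(as.integer(comp$membership[g$zones]), g$zones),
    islands = g$zones[deg == 0L],
    degrees = tibble::tibble(zone = g$zones, degree = as.integer(deg))
  )
}
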