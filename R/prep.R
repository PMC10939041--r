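#' Ordinal coding of food consumption scores
#'
#' Defines how a continuous food consumption score (FCS) is cut into the
#' three ordered food-security states and how those states map onto the
#' integer codes 0, 1, 2.  The package's canonical direction is
#' *insecurity-ascending*: 0 = secure, 1 = vulnerable, 2 = insecure, so that
#' positive linear effects in the model increase the probability of higher
#' food-insecurity levels.  The descending direction (0 = insecure) is
#' available for interoperability; the direction in force is recorded in
#' every derived output.
#'
#' @param cuts length-2 numeric, the FCS cut-points `(c1, c2)` with
#'   `c1 < c2`; default `c(35.5, 49)`.
#' @param direction `"insecurity-ascending"` (default) or
#'   `"insecurity-descending"`.
#' @return an object of class `ordinal_coding`.
#' @export
ordinal_coding <- function(cuts = c(35.5, 49),
                           direction = c("insecurity-ascending",
                                         "insecurity-descending")) {
  direction <- match.arg(direction)
  cuts <- as.numeric(cuts)
  if (length(cuts) != 2L || !all(is.finite(cuts)) || cuts[1L] >= cuts[2L]) {
    stop("`cuts` must be two finite numbers with cuts[1] < cuts[2]")
  }
  labels <- if (direction == "insecurity-ascending") {
    c("secure", "vulnerable", "insecure")  # codes 0,1,2
  } else {
    c("insecure", "vulnerable", "secure")
  }
  structure(list(cuts = cuts, direction = direction, labels = labels),
            class = "ordinal_coding")
}

#' @export
print.ordinal_coding <- function(x, ...) {
  cat("<ordinal_coding> cuts ", x$cuts[1L], "/", x$cuts[2L], ", ",
      x$direction, " (0=", x$labels[1L], ", 1=", x$labels[2L],
      ", 2=", x$labels[3L], ")\n", sep = "")
  invisible(x)
}

#' Categorize food consumption scores into ordinal levels
#'
#' Bands are half-open with inclusive upper bound: `fcs <= c1` is insecure,
#' `c1 < fcs <= c2` vulnerable, `fcs > c2` secure.  The state is then mapped
#' to \{0, 1, 2\} by the coding direction.
#'
#' @param fcs numeric vector of scores (must be finite and `>= 0`).
#' @param coding an [ordinal_coding()].
#' @return integer vector of levels in \{0, 1, 2\} (`NA` stays `NA`).
#' @export
categorize_fcs <- function(fcs, coding = ordinal_coding()) {
  stopifnot(inherits(coding, "ordinal_coding"))
  ok <- is.na(fcs) | (is.finite(fcs) & fcs >= 0)
  if (!all(ok)) stop("`fcs` values must be finite and >= 0")
  state <- ifelse(fcs <= coding$cuts[1L], "insecure",
                  ifelse(fcs <= coding$cuts[2L], "vulnerable", "secure"))
  out <- match(state, coding$labels) - 1L
  out[is.na(fcs)] <- NA_integer_
  out
}

#' Level labels for a coding
#' @param coding an [ordinal_coding()].
#' @return character vector of length 3, labels for codes 0,1,2.
#' @export
level_labels <- function(coding = ordinal_coding()) coding$labels

mode_value <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA)
  tb <- table(x)
  names(tb)[which.max(tb)]
}

#' Longitudinal mean imputation of a household panel
#'
#' Applies the panel cleaning rule used throughout the package: households
#' observed in a single wave are dropped; missing continuous values are
#' replaced by that household's across-wave mean, and - for covariates only -
#' by the overall variable mean when a household has no observed wave at all.
#' The outcome (`fcs`) is never imputed across households: households with
#' `fcs` missing in every wave are dropped.  Missing categorical values take
#' the household mode, then the global mode.  Non-missing values are never
#' altered.
#'
#' @param data data frame with one row per (household, wave).
#' @param id,wave column names of the household identifier and wave.
#' @param outcome name of the outcome score column (household-mean imputation
#'   only), or `NULL`.
#' @param continuous character vector of continuous covariate columns;
#'   defaults to all numeric columns except `id`, `wave`, `outcome`, `level`.
#' @param categorical character vector of categorical columns; defaults to
#'   all character/factor columns except `id` and `zone`.
#' @return tibble with the same columns, no missing values in the imputed
#'   variables.
#' @export
impute_longitudinal <- function(data, id = "household_id", wave = "wave",
                                outcome = "fcs",
                                continuous = NULL, categorical = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot(id %in% names(data), wave %in% names(data))
  # drop single-wave households
  nw <- table(data[[id]])
  keep <- names(nw)[nw >= 2L]
  data <- data[data[[id]] %in% keep, , drop = FALSE]

  if (is.null(continuous)) {
    num <- names(data)[vapply(data, is.numeric, logical(1L))]
    continuous <- setdiff(num, c(id, wave, outcome, "level"))
  }
  if (is.null(categorical)) {
    chr <- names(data)[vapply(data, function(x) is.character(x) || is.factor(x),
                              logical(1L))]
    categorical <- setdiff(chr, c(id, "zone"))
  }
  hh <- data[[id]]
  impute_num <- function(x, global_fallback) {
    if (!anyNA(x)) return(x)
    m <- tapply(x, hh, mean, na.rm = TRUE)[as.character(hh)]
    x[is.na(x)] <- m[is.na(x)]
    if (global_fallback && anyNA(x)) {
      g <- mean(x, na.rm = TRUE)
      if (is.nan(g)) stop("variable missing for all records")
      x[is.na(x)] <- g
    }
    unname(x)
  }
  for (v in continuous) data[[v]] <- impute_num(data[[v]], TRUE)
  if (!is.null(outcome) && outcome %in% names(data)) {
    data[[outcome]] <- impute_num(data[[outcome]], FALSE)
    if (anyNA(data[[outcome]])) {
      bad <- unique(hh[is.na(data[[outcome]])])
      message("dropping ", length(bad),
              " household(s) with no observed outcome in any wave")
      data <- data[!(data[[id]] %in% bad), , drop = FALSE]
      hh <- data[[id]]
    }
  }
  for (v in categorical) {
    x <- as.character(data[[v]])
    if (anyNA(x)) {
      hm <- tapply(x, hh, mode_value)[as.character(hh)]
      x[is.na(x)] <- hm[is.na(x)]
      if (anyNA(x)) {
        g <- mode_value(x)
        if (is.na(g)) stop("variable missing for all records")
        x[is.na(x)] <- g
      }
    }
    data[[v]] <- unname(x)
  }
  data
}

#' Cross-tabulate a factor against the ordinal levels
#'
#' Row percentages per factor category over the three levels; each row sums
#' to 100 up to rounding.  Empty categories are kept as zero rows and
#' flagged.
#'
#' @param data data frame with a `level` column coded 0/1/2.
#' @param factor name of the factor column, or `NULL` for the marginal
#'   distribution (single row labelled `"(all)"`).
#' @param coding the [ordinal_coding()] naming the levels.
#' @param digits round percentages to this many decimals (half-up); `NULL`
#'   (default) leaves them unrounded.
#' @return tibble: one row per category with columns `category`, `n`, one
#'   percentage column per level label, and `empty`.
#' @export
cross_tab <- function(data, factor = NULL, coding = ordinal_coding(),
                      digits = NULL) {
  data <- tibble::as_tibble(data)
  stopifnot("level" %in% names(data))
  lv <- data$level
  if (!all(lv %in% 0:2)) stop("`level` must be coded 0, 1, 2")
  cat_col <- if (is.null(factor)) rep("(all)", nrow(data)) else {
    stopifnot(factor %in% names(data))
    as.character(data[[factor]])
  }
  cats <- unique(cat_col)
  rows <- lapply(cats, function(cc) {
    sel <- cat_col == cc
    n <- sum(sel)
    pct <- if (n == 0L) rep(0, 3L) else
      100 * tabulate(lv[sel] + 1L, nbins = 3L) / n
    if (!is.null(digits)) pct <- round_half_up(pct, digits)
    out <- tibble::tibble(category = cc, n = n)
    out[paste0("pct_", coding$labels)] <- as.list(pct)
    out$empty <- n == 0L
    out
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "direction") <- coding$direction
  out
}

round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Zone-level aggregates of a panel
#'
#' One value per zone; zones of the companion graph with no records are kept
#' with `value = NA` and `no_data = TRUE` so that downstream consumers
#' (Moran's I, choropleth export) can exclude or hatch them.
#'
#' @param data data frame with columns `zone` and, as required, `fcs` or
#'   `level`.
#' @param statistic one of `"insecure-proportion"`, `"mean-fcs"`,
#'   `"modal-level"`.
#' @param graph optional [zone_graph()] supplying the full zone set/order.
#' @param coding the [ordinal_coding()] (identifies the "insecure" code).
#' @return tibble with columns `zone`, `value`, `n`, `no_data`.
#' @export
zone_aggregate <- function(data,
                           statistic = c("insecure-proportion", "mean-fcs",
                                         "modal-level"),
                           graph = NULL, coding = ordinal_coding()) {
  statistic <- match.arg(statistic)
  data <- tibble::as_tibble(data)
  stopifnot("zone" %in% names(data))
  zones <- if (is.null(graph)) unique(as.character(data$zone)) else graph$zones
  insec_code <- match("insecure", coding$labels) - 1L
  val <- vapply(zones, function(z) {
    d <- data[as.character(data$zone) == z, , drop = FALSE]
    if (nrow(d) == 0L) return(NA_real_)
    switch(statistic,
      "insecure-proportion" = mean(d$level == insec_code),
      "mean-fcs" = mean(d$fcs),
      "modal-level" = as.numeric(mode_value(d$level)))
  }, numeric(1L))
  n <- vapply(zones, function(z) sum(as.character(data$zone) == z), integer(1L))
  tibble::tibble(zone = zones, value = unname(val), n = unname(n),
                 no_data = n == 0L)
}
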