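#' Analysis configuration
#'
#' Assembles and validates the configuration driving [run_analysis()].
#' Configurations can also be read from a flat `key: value` YAML file with
#' [read_config()]; list-valued keys use YAML sequences.
#'
#' @param data path to the panel CSV (or a data frame).
#' @param graph path to a `.gra` contiguity file (or a [zone_graph()]).
#' @param centroids optional centroid CSV path (or data frame); required
#'   for tensor-product variants.
#' @param outdir output directory.
#' @param cuts,direction ordinal coding (see [ordinal_coding()]).
#' @param link `"probit"` or `"logit"`.
#' @param parametric character vector of linear-term columns.
#' @param smooths character vector of continuous covariates given P-spline
#'   smooths.
#' @param variants model variants to fit and compare: subset of
#'   `"additive"`, `"mrf"`, `"tensor-8"`, `"tensor-20"`.
#' @param moran_variable zone aggregate for Moran's I
#'   (`"insecure-proportion"` or `"mean-fcs"`).
#' @param moran_style weight style for Moran's I.
#' @param n_perm Moran permutation count.
#' @param stop_tau2,max_iter fitting controls (see [ordstar()]).
#' @param seed master seed; Moran permutations use `seed + 1`.
#' @return a list of class `ordstar_config`.
#' @export
analysis_config <- function(data, graph, centroids = NULL, outdir = ".",
                            cuts = c(35.5, 49),
                            direction = "insecurity-ascending",
                            link = "probit",
                            parametric = c("urban", "shock"),
                            smooths = c("coping", "age"),
                            variants = c("additive", "mrf"),
                            moran_variable = "insecure-proportion",
                            moran_style = "binary",
                            n_perm = 999L,
                            stop_tau2 = 1e-5, max_iter = 200L,
                            seed = 1L) {
  bad <- setdiff(variants, c("additive", "mrf", "tensor-8", "tensor-20"))
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  structure(
    list(data = data, graph = graph, centroids = centroids, outdir = outdir,
         cuts = cuts, direction = direction, link = link,
         parametric = parametric, smooths = smooths, variants = variants,
         moran_variable = moran_variable, moran_style = moran_style,
         n_perm = n_perm, stop_tau2 = stop_tau2, max_iter = max_iter,
         seed = seed),
    class = "ordstar_config")
}

#' Read an analysis configuration file
#'
#' @param path YAML (flat `key: value`) configuration file.
#' @return an `ordstar_config`.
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

variant_formula <- function(cfg, variant) {
  rhs <- c(cfg$parametric, sprintf("s(%s)", cfg$smooths))
  rhs <- c(rhs, switch(variant,
    "additive" = character(0),
    "mrf" = c("mrf(zone)", "re(zone)"),
    "tensor-8" = c("tp(zone, n_knots = 8)", "re(zone)"),
    "tensor-20" = c("tp(zone, n_knots = 20)", "re(zone)")))
  stats::as.formula(paste("level ~", paste(rhs, collapse = " + ")))
}

#' Run the full zone-level food-insecurity analysis
#'
#' Orchestrates the package's workflow end-to-end: load (or accept) the
#' panel, graph and centroids; code levels from FCS where absent; apply
#' longitudinal mean imputation; write descriptive cross-tabulations; test
#' zone aggregates for spatial autocorrelation (Moran's I); fit the
#' requested model variants; compare them by GCV (ties broken toward fewer
#' effective df); and export coefficient, smooth-term, zone-effect and
#' smooth-curve tables plus a plain-text summary.  Every number in the
#' bundle is computed by the corresponding package function; the runner
#' only collects and writes.
#'
#' @param cfg an [analysis_config()].
#' @return invisibly, a list with the prepared data, cross-tabs, Moran
#'   tibble, fitted models, comparison table, and (if spatial terms are
#'   present in the winner) the variance partition and zone effects.
#' @export
run_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "ordstar_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  coding <- ordinal_coding(cfg$cuts, cfg$direction)

  g <- if (inherits(cfg$graph, "zone_graph")) cfg$graph else read_gra(cfg$graph)
  if (!is.null(cfg$centroids) && is.null(g$centroids)) {
    cen <- if (is.data.frame(cfg$centroids)) cfg$centroids else
      read_centroids(cfg$centroids)
    g <- zone_graph(g$zones, g$edges, centroids = cen)
  }
  d <- if (is.data.frame(cfg$data)) tibble::as_tibble(cfg$data) else
    tibble::as_tibble(utils::read.csv(cfg$data, stringsAsFactors = FALSE,
                                      na.strings = c("", "NA")))
  d <- impute_longitudinal(d)
  if (!("level" %in% names(d))) d$level <- categorize_fcs(d$fcs, coding)

  log_lines <- c(
    paste0("ordinal coding: cuts ", paste(coding$cuts, collapse = "/"),
           ", ", coding$direction),
    "knot convention: k knots = k equally spaced knots spanning [min, max]",
    paste0("moran weights: ", cfg$moran_style),
    paste0("link: ", cfg$link),
    paste0("seed: ", cfg$seed, " (moran permutations use seed + 1)"))

  # descriptives
  tabs <- lapply(c(list(NULL), as.list(cfg$parametric)), function(f) {
    cross_tab(d, f, coding, digits = 1L)
  })
  names(tabs) <- c("(marginal)", cfg$parametric)
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]],
                     file.path(cfg$outdir, paste0("crosstab_",
                                                  gsub("[^a-z0-9]", "", nm),
                                                  ".csv")),
                     row.names = FALSE)
  }

  # Moran's I on the zone aggregate
  agg <- zone_aggregate(d, cfg$moran_variable, graph = g, coding = coding)
  mi <- morans_i(agg[!agg$no_data, c("zone", "value")], g,
                 style = cfg$moran_style, n_perm = cfg$n_perm,
                 seed = cfg$seed + 1L)
  utils::write.csv(mi, file.path(cfg$outdir, "morans_i.csv"),
                   row.names = FALSE)

  # model variants
  fits <- list()
  for (v in cfg$variants) {
    fits[[v]] <- ordstar(d, variant_formula(cfg, v), graph = g,
                         link = cfg$link, stop_tau2 = cfg$stop_tau2,
                         max_iter = cfg$max_iter)
    utils::write.csv(tidy(fits[[v]]),
                     file.path(cfg$outdir, paste0("coef_", v, ".csv")),
                     row.names = FALSE)
    utils::write.csv(tidy(fits[[v]], "smooths"),
                     file.path(cfg$outdir, paste0("smooths_", v, ".csv")),
                     row.names = FALSE)
    for (sv in cfg$smooths) {
      utils::write.csv(smooth_curve(fits[[v]], sv),
                       file.path(cfg$outdir,
                                 paste0("curve_", v, "_", sv, ".csv")),
                       row.names = FALSE)
    }
    if (v != "additive") {
      utils::write.csv(zone_effects(fits[[v]]),
                       file.path(cfg$outdir, paste0("zones_", v, ".csv")),
                       row.names = FALSE)
    }
  }

  comparison <- dplyr::bind_rows(lapply(names(fits), function(v) {
    tibble::tibble(variant = v, gcv = gcv(fits[[v]]),
                   edf = fits[[v]]$edf_total,
                   deviance = fits[[v]]$deviance,
                   converged = fits[[v]]$converged)
  }))
  # argmin with tie-break toward fewer effective df
  o <- order(round(comparison$gcv / 1e-8) * 1e-8, comparison$edf)
  comparison$best <- seq_len(nrow(comparison)) == o[1L]
  best <- comparison$variant[comparison$best]
  utils::write.csv(comparison, file.path(cfg$outdir, "comparison.csv"),
                   row.names = FALSE)

  vp <- NULL; ze <- NULL
  if (best != "additive") {
    vp <- variance_partition(fits[[best]])
    ze <- zone_effects(fits[[best]])
  }

  summary_lines <- c(
    "ordinal geo-additive analysis summary", "",
    log_lines, "",
    sprintf("records: %d   zones: %d", nrow(d), length(g$zones)),
    sprintf("moran's I: %.4f (E[I] %.4f, analytic p %.4g, perm p %.4g)",
            mi$statistic, mi$expectation, mi$p.analytic, mi$p.perm), "",
    "model comparison (GCV; smaller is better):",
    utils::capture.output(as.data.frame(comparison)), "",
    sprintf("selected variant: %s", best),
    if (!is.null(vp)) {
      sprintf("structured share of spatial variation: %.2f%%", vp)
    })
  writeLines(summary_lines, file.path(cfg$outdir, "summary.txt"))

  invisible(list(data = d, graph = g, crosstabs = tabs, moran = mi,
                 fits = fits, comparison = comparison, best = best,
                 variance_partition = vp, zone_effects = ze,
                 log = log_lines))
}

#' Simulate a full synthetic study to disk
#'
#' Writes the generated panel CSV, the `.gra` contiguity file, the centroid
#' CSV and a JSON truth sidecar (fields, effects, thresholds, offset) into
#' `outdir`; reproducible from `(truth arguments, n_households, waves,
#' seed)`.
#'
#' @param outdir output directory.
#' @param n_households,waves,seed,p_missing passed to [gen_panel()].
#' @param ... passed to [synthetic_truth()] (the field-drawing seed
#'   defaults to `seed`).
#' @return invisibly, the [gen_panel()] result.
#' @export
simulate_study <- function(outdir, n_households = 3835L, waves = 3L,
                           seed = 1L, p_missing = 0, ...) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  args <- list(...)
  if (is.null(args$seed)) args$seed <- seed
  truth <- do.call(synthetic_truth, args)
  gp <- gen_panel(truth, n_households = n_households, waves = waves,
                  seed = seed, p_missing = p_missing)
  utils::write.csv(gp$data, file.path(outdir, "panel.csv"), row.names = FALSE)
  write_gra(truth$graph, file.path(outdir, "zones.gra"))
  utils::write.csv(truth$graph$centroids, file.path(outdir, "centroids.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(f_str = as.list(truth$f_str), f_unstr = as.list(truth$f_unstr),
         gamma = as.list(truth$gamma), thresholds = truth$thresholds,
         link = truth$link, offset = truth$offset,
         tau2_str = truth$tau2_str, tau2_unstr = truth$tau2_unstr,
         prevalence = as.list(truth$prevalence),
         n_households = n_households, waves = waves, seed = seed),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(gp)
}
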