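# Orchestration: run every analysis stage on a dataset and emit a report.

#' Analysis configuration
#'
#' @param roles named character vector mapping cell_id to "smooth" or
#'   "parasol". Hotspot clustering runs on smooth-role cells; overlap
#'   analysis tests smooth synapses against parasol fields.
#' @param seed master integer seed; every stochastic stage draws from a
#'   stream derived from it and the stage name, so adding a stage never
#'   perturbs another stage's draws.
#' @param lambda density-map smoothing penalty (default 1).
#' @param bin_size_synapse,bin_size_dendrite optional bin sizes in um;
#'   derived from each cell's field diameter when NULL.
#' @param k_min,k_max mixture component range (k_min >= 2).
#' @param n_restarts EM restarts per K.
#' @param outlier_threshold Mahalanobis SD bound (default 3).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(roles, seed, lambda = 1,
                            bin_size_synapse = NULL,
                            bin_size_dendrite = NULL,
                            k_min = 2, k_max = 10, n_restarts = 10,
                            outlier_threshold = 3) {
  if (k_min < 2) stop("k_min must be >= 2")
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(names(roles)) || any(!roles %in% c("smooth", "parasol")))
    stop("roles must be a named vector of 'smooth'/'parasol'")
  structure(list(roles = roles, seed = as.integer(seed), lambda = lambda,
                 bin_size_synapse = bin_size_synapse,
                 bin_size_dendrite = bin_size_dendrite,
                 k_min = k_min, k_max = k_max, n_restarts = n_restarts,
                 outlier_threshold = outlier_threshold),
            class = "analysis_config")
}

# per-stage seed derived from the master seed and the stage name
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 131 + sum(utf8ToInt(stage))) %%
               2147483647)
}

#' Run the full analysis pipeline on a dataset
#'
#' Stages run in fixed order: morphometry, synapse proportions, density
#' maps, hotspot clustering (smooth-role cells), run/partner statistics,
#' and overlap analysis. A failed stage is recorded under `errors` and the
#' remaining stages still run. Deterministic given the config seed.
#'
#' @param dataset a `scene_dataset`.
#' @param config an [analysis_config()].
#' @return A `pipeline_report` list; see [write_report()].
#' @export
run_pipeline <- function(dataset, config) {
  validate_dataset(dataset)
  ids <- names(config$roles)
  missing_ids <- setdiff(ids, dataset$cells$cell_id)
  if (length(missing_ids))
    stop("roles name unknown cells: ", paste(missing_ids, collapse = ", "))
  report <- list(provenance = list(seed = config$seed,
                                   roles = as.list(config$roles),
                                   lambda = config$lambda,
                                   k_range = c(config$k_min, config$k_max),
                                   n_restarts = config$n_restarts,
                                   outlier_threshold =
                                     config$outlier_threshold,
                                   package_version =
                                     as.character(utils::packageVersion(
                                       "hotspotter"))),
                 errors = list())
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) report[[name]] <<- res
  }

  run_stage("morphometry", function() {
    out <- list()
    for (cid in ids) {
      rec <- get_reconstruction(dataset, cid)
      hull <- dendritic_field_hull(rec)
      dend <- rec$nodes[rec$nodes$tag == "dendrite", ]
      dp <- depth_profile(dend, dataset$ipl)
      out[[cid]] <- list(role = unname(config$roles[[cid]]),
                         hull_area = hull$area,
                         field_diameter = hull$equivalent_diameter,
                         centroid = hull$centroid,
                         soma_diameter = soma_diameter(rec),
                         mean_depth = dp$mean_depth,
                         mode_depth = dp$mode_depth)
    }
    out
  })

  run_stage("synapse_proportions", function() {
    out <- list()
    for (cid in ids) {
      syn <- subset_synapses(dataset, cid)
      n_ama <- sum(syn$kind == "conventional")
      n_bip <- sum(syn$kind == "ribbon")
      cls <- if (n_bip > 0)
        classification_rate(syn) else
          list(n_classified = 0L, n_total = 0L, percent = NA_real_)
      out[[cid]] <- list(n_total = nrow(syn), n_amacrine = n_ama,
                         n_bipolar = n_bip,
                         amacrine_fraction =
                           if (nrow(syn)) n_ama / nrow(syn) else NA_real_,
                         classification = cls)
    }
    out
  })

  run_stage("density", function() {
    out <- list()
    for (cid in ids) {
      rec <- get_reconstruction(dataset, cid)
      hull <- dendritic_field_hull(rec)
      bs_syn <- config$bin_size_synapse %||%
        default_bin_size("synapse", hull$equivalent_diameter)
      bs_dend <- config$bin_size_dendrite %||%
        default_bin_size("dendrite", hull$equivalent_diameter)
      rib <- subset_synapses(dataset, cid, kind = "ribbon")
      dend <- rec$nodes[rec$nodes$tag == "dendrite", ]
      maps <- list()
      if (nrow(rib))
        maps$synapses <- density_map(cbind(rib$x_um, rib$y_um), bs_syn,
                                     lambda = config$lambda)
      maps$dendrites <- density_map(cbind(dend$x_um, dend$y_um), bs_dend,
                                    lambda = config$lambda)
      out[[cid]] <- maps
    }
    out
  })

  smooth_ids <- ids[config$roles[ids] == "smooth"]
  if (!length(smooth_ids)) {
    report$errors[["clustering"]] <-
      "skipped: no smooth-role cell in config"
  } else {
    run_stage("clustering", function() {
      out <- list()
      for (cid in smooth_ids) {
        rib <- subset_synapses(dataset, cid, kind = "ribbon")
        pts <- cbind(rib$x_um, rib$y_um)
        sel <- select_components(pts, k_min = config$k_min,
                                 k_max = config$k_max,
                                 n_restarts = config$n_restarts,
                                 seed = stage_seed(config$seed,
                                                   "clustering"))
        outl <- flag_outliers(pts, sel$model,
                              threshold = config$outlier_threshold)
        comp <- cluster_composition(rib, sel$model, outl)
        out[[cid]] <- list(
          selected_K = sel$model$K,
          ch_by_k = sel$ch_by_k,
          low_contrast = sel$low_contrast,
          components = lapply(seq_len(sel$model$K), function(k) list(
            weight = sel$model$weights[k],
            mean = sel$model$means[k, ],
            sd = sqrt(diag(sel$model$covariances[[k]])))),
          assignments = sel$model$assignments,
          outliers = rib$synapse_id[outl],
          composition = comp)
      }
      out
    })
  }

  run_stage("run_statistics", function() {
    out <- list()
    for (cid in ids) {
      rec <- get_reconstruction(dataset, cid)
      syn <- subset_synapses(dataset, cid)
      if (!nrow(syn)) { out[[cid]] <- NULL; next }
      runs <- find_amacrine_runs(rec, syn)
      p <- amacrine_probability(syn)
      max_run <- if (nrow(runs)) max(runs$run_length) else 0L
      out[[cid]] <- list(
        amacrine_probability = p,
        n_runs_ge_5 = sum(runs$run_length >= 5),
        max_run = max_run,
        max_run_null_probability = run_probability(p, max_run))
    }
    out
  })

  run_stage("partner_profiles", function() {
    out <- list()
    for (cid in ids) {
      rib <- subset_synapses(dataset, cid, kind = "ribbon")
      if (!nrow(rib)) next
      pp <- partner_profile(rib)
      out[[cid]] <- list(n_partners = pp$n_partners,
                         mean_synapses_per_partner =
                           pp$mean_synapses_per_partner,
                         totals_by_type = as.list(pp$totals_by_type),
                         per_partner = pp$per_partner)
    }
    out
  })

  parasol_ids <- ids[config$roles[ids] == "parasol"]
  if (length(smooth_ids) && length(parasol_ids)) {
    run_stage("overlap", function() {
      out <- list()
      test <- subset_synapses(dataset, smooth_ids[1], kind = "ribbon")
      for (pid in parasol_ids) {
        rep_i <- overlap_analysis(test, get_reconstruction(dataset, pid),
                                  subset_synapses(dataset, pid,
                                                  kind = "ribbon"))
        out[[pid]] <- list(
          n_member = rep_i$n_member, n_total = rep_i$n_total,
          mean_distance_to_center =
            if (length(rep_i$distances)) mean(rep_i$distances) else
              NA_real_,
          shared_partners_by_type =
            if (is.null(rep_i$shared_partners)) NULL else
              as.list(table(rep_i$shared_partners$pre_type)))
      }
      out
    })
  }
  class(report) <- "pipeline_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group summary of a per-report metric
#'
#' Arithmetic mean, sample SD (n - 1 denominator) and n, the `mean +- sd`
#' reporting style of the study. A single value yields sd 0 with
#' `sd_defined = FALSE`.
#'
#' @param x numeric vector, or a list of `pipeline_report`s.
#' @param metric when `x` is a list of reports: a dot-separated path into
#'   each report (e.g. `"morphometry.smooth_1.field_diameter"`).
#' @return list with `mean`, `sd`, `n`, `sd_defined`.
#' @export
summarize_group <- function(x, metric = NULL) {
  if (!is.numeric(x)) {
    if (is.null(metric)) stop("metric required for a list of reports")
    path <- strsplit(metric, ".", fixed = TRUE)[[1]]
    x <- vapply(x, function(r) {
      for (p in path) {
        r <- r[[p]]
        if (is.null(r)) stop("metric absent: ", metric)
      }
      if (!is.numeric(r) || length(r) != 1)
        stop("metric is not a numeric scalar: ", metric)
      r
    }, numeric(1))
  }
  if (!length(x)) stop("no values")
  n <- length(x)
  list(mean = mean(x), sd = if (n > 1) stats::sd(x) else 0,
       n = n, sd_defined = n > 1)
}

#' Write a pipeline report to disk
#'
#' `report.json` holds every scalar result; density maps go under `maps/`
#' as delimited text and per-partner tables under `tables/` as CSV. The
#' JSON contains no timestamps, so reruns under the same seed are
#' byte-identical.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maps <- report$density
  if (!is.null(maps)) {
    mdir <- file.path(dir, "maps")
    if (!dir.exists(mdir)) dir.create(mdir)
    for (cid in names(maps))
      for (what in names(maps[[cid]]))
        write_density_map(maps[[cid]][[what]],
                          file.path(mdir, paste0(cid, "_", what, ".txt")))
    report$density <- lapply(maps, function(m)
      lapply(m, function(mm) list(bins = dim(mm$values),
                                  bin_size = mm$bin_size,
                                  lambda = mm$lambda,
                                  n_points = mm$n_points)))
  }
  pp <- report$partner_profiles
  if (!is.null(pp)) {
    tdir <- file.path(dir, "tables")
    if (!dir.exists(tdir)) dir.create(tdir)
    for (cid in names(pp)) {
      utils::write.csv(pp[[cid]]$per_partner,
                       file.path(tdir, paste0(cid, "_partners.csv")),
                       row.names = FALSE)
      report$partner_profiles[[cid]]$per_partner <- NULL
    }
  }
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", force = TRUE)
  invisible(dir)
}
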