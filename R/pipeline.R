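#' Default pipeline configuration
#'
#' One nested, JSON-serializable list drives the whole analysis. Every
#' analysis constant (5 CV folds, 2000 trees, `mtry = 2`, 3000 reference
#' points, 3 PCs, 3 nearest sites, masking threshold 3, 999 permutations,
#' the 0.30 percent accumulation threshold) appears here as a default rather
#' than as a hard-coded literal, and every stage's seed is explicit.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; stage seeds default to it.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(out_dir = "phytosdm_run", seed = 1) {
  cfg <- list(
    data = list(
      source = "synthetic",
      sites_csv = NULL, stack_dir = NULL,
      landscape = list(rows = 60, cols = 60, cellsize = 1, n_temp = 12,
                       n_precip = 8, block_cor = 0.7, field_range = 6,
                       coefficients = list(temp_01 = -0.6, temp_02 = -0.4,
                                           precip_01 = 0.35, ph = -0.25,
                                           coast_distance = -0.3),
                       nonlinear = FALSE, noise_sd = 0.5, baseline = -1.2,
                       seed = seed),
      n_sites = 120, site_seed = seed, coast_weight = 0),
    screen = list(response = "phytolith_pct", restrict_distance = 75),
    learners = list(
      random_forest = list(ntree = 2000, mtry = 2, min_node = 5),
      gam = list(vars = default_gam_vars(), k = 10, method = "REML"),
      lasso = list(nfolds = 10)),
    cv = list(k = 5, seed = seed),
    ensemble = list(back_transform = TRUE),
    novelty = list(n_ref = 3000, n_pc = 3, k_near = 3, threshold = 3,
                   seed = seed),
    diagnostics = list(knn_k = 5, n_sim = 999, seed = seed),
    accumulation = list(cover = 0.75, biomass = 200, production = 0.04,
                        bulk_density = 1.5, depth = 60, threshold = 0.003,
                        dissolution = 0),
    out_dir = out_dir)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' The file representation round-trips losslessly.
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  # gam vars may arrive as a list of scalars
  if (!is.null(cfg$learners$gam$vars)) {
    cfg$learners$gam$vars <- unlist(cfg$learners$gam$vars)
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Validate a pipeline configuration
#'
#' Schema and range checks with no side effects.
#'
#' @param config A `pipeline_config`, or a path to a JSON config file.
#' @return Character vector of problems; empty means valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_config(config)
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)

  src <- config$data$source
  if (is.null(src) || !src %in% c("synthetic", "files")) {
    note("data.source must be 'synthetic' or 'files'")
  } else if (src == "files") {
    if (is.null(config$data$sites_csv)) note("data.sites_csv is required")
    if (is.null(config$data$stack_dir)) note("data.stack_dir is required")
  } else {
    lc <- config$data$landscape
    ok <- tryCatch({
      do.call(landscape_config, lc)
      TRUE
    }, error = function(e) {
      note(paste0("data.landscape: ", conditionMessage(e)))
      FALSE
    })
    if (ok && (is.null(config$data$n_sites) || config$data$n_sites < 10)) {
      note("data.n_sites must be at least 10")
    }
  }
  known <- c("random_forest", "gam", "lasso")
  bad <- setdiff(names(config$learners), known)
  if (length(bad) > 0) {
    note(paste0("learners: unknown learner name '", bad[1], "'"))
  }
  if (length(config$learners) == 0) note("learners: at least one required")
  if (is.null(config$cv$k) || config$cv$k < 2) note("cv.k must be >= 2")
  nv <- config$novelty
  if (!is.null(nv)) {
    if (nv$n_ref < 1) note("novelty.n_ref must be positive")
    if (nv$n_pc < 1) note("novelty.n_pc must be positive")
    if (nv$k_near < 1) note("novelty.k_near must be positive")
    if (nv$threshold < 0) note("novelty.threshold must be nonnegative")
  }
  dg <- config$diagnostics
  if (!is.null(dg)) {
    if (dg$n_sim < 1) note("diagnostics.n_sim must be positive")
    if (dg$knn_k < 1) note("diagnostics.knn_k must be positive")
  }
  ac <- config$accumulation
  if (!is.null(ac)) {
    ok <- tryCatch({
      do.call(accumulation_scenario, ac)
      TRUE
    }, error = function(e) {
      note(paste0("accumulation: ", conditionMessage(e)))
      FALSE
    })
  }
  for (nm in c("cv", "novelty", "diagnostics")) {
    if (!is.null(config[[nm]]) && is.null(config[[nm]]$seed)) {
      note(paste0(nm, ".seed must be explicit"))
    }
  }
  problems
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: load or simulate data; correlation
#' screen (full and coastal restricted range); fit and cross-validate the
#' learners; derive ensemble weights; map the ensemble prediction; compute
#' and apply the environmental-novelty mask; Moran's I permutation test and
#' cross-model residual correlation; and the accumulation-time report. All
#' artifacts are written to `config$out_dir` and listed in a manifest with
#' content hashes; rerunning the same configuration reproduces identical
#' hashes.
#'
#' @param config A `pipeline_config` (see [default_pipeline_config()]), or a
#'   path to a JSON config file.
#' @return The manifest (invisibly also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop("invalid configuration: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  add_artifact <- function(class, path) {
    artifacts[[length(artifacts) + 1]] <<- list(
      class = class, path = basename(path),
      md5 = unname(tools::md5sum(path)))
  }

  # ---- data ----------------------------------------------------------------
  dat <- stage("data", {
    if (config$data$source == "synthetic") {
      lc <- do.call(landscape_config, config$data$landscape)
      stk <- generate_landscape(lc)
      sites <- sample_sites(stk, config$data$n_sites,
                            seed = config$data$site_seed,
                            coast_weight = config$data$coast_weight %||% 0)
      sites <- simulate_response(sites, lc)
      list(stack = stk, sites = sites)
    } else {
      list(stack = read_stack(config$data$stack_dir),
           sites = read_sites(config$data$sites_csv))
    }
  })
  sites_path <- file.path(out, "sites.csv")
  write_sites(dat$sites, sites_path)
  add_artifact("sites", sites_path)

  # ---- correlation screen --------------------------------------------------
  stage("screen", {
    full <- correlation_screen(dat$sites, config$screen$response)
    write_correlation(full, file.path(out, "correlations_full.csv"))
    if (!is.null(config$screen$restrict_distance) &&
        "coast_distance" %in% site_covariates(dat$sites)) {
      restr <- correlation_screen(
        dat$sites, config$screen$response,
        restrict = coast_restriction(config$screen$restrict_distance))
      write_correlation(restr, file.path(out, "correlations_restricted.csv"))
      add_artifact("correlation_table",
                   file.path(out, "correlations_restricted.csv"))
    }
    add_artifact("correlation_table", file.path(out, "correlations_full.csv"))
  })

  # ---- cross-validation + ensemble -----------------------------------------
  specs <- stage("crossval", {
    specs <- config_to_specs(config)
    if (config$cv$k > nrow(dat$sites)) {
      stop("k = ", config$cv$k, " exceeds the ", nrow(dat$sites), " sites")
    }
    specs
  })
  model <- stage("crossval", {
    fit_ensemble(dat$sites, specs, k = config$cv$k, seed = config$cv$seed)
  })
  stage("crossval", {
    rep <- list(k = model$cv$k, seed = model$cv$seed,
                metrics = model$cv$metrics,
                weights = as.list(model$cv$weights),
                folds = as.list(model$cv$folds),
                fit_statistics = ensemble_fit_statistics(model, dat$sites))
    jsonlite::write_json(rep, file.path(out, "cv_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    add_artifact("cv_report", file.path(out, "cv_report.json"))
  })

  # ---- per-learner importance ----------------------------------------------
  stage("importance", {
    for (nm in names(model$fits)) {
      imp <- variable_importance(model$fits[[nm]], dat$sites)
      p <- file.path(out, paste0("importance_", nm, ".csv"))
      write.csv(format(as.data.frame(imp), digits = 12), p,
                row.names = FALSE, quote = FALSE)
      add_artifact("importance_table", p)
    }
  })

  # ---- ensemble maps -------------------------------------------------------
  pred <- stage("predict", {
    ensemble_predict(model, dat$stack,
                     back_transform = isTRUE(config$ensemble$back_transform))
  })
  nov <- stage("predict", {
    env_pc_distance(dat$stack, dat$sites,
                    n_ref = config$novelty$n_ref,
                    n_pc = config$novelty$n_pc,
                    k_near = config$novelty$k_near,
                    seed = config$novelty$seed)
  })
  stage("predict", {
    write_grid_map(pred, file.path(out, "ensemble_prediction.asc"))
    add_artifact("ensemble_map", file.path(out, "ensemble_prediction.asc"))
    write_grid_map(nov$map, file.path(out, "novelty.asc"))
    jsonlite::write_json(
      list(n_ref = nov$n_ref, n_pc = nov$n_pc, k_near = nov$k_near,
           seed = nov$seed, var_explained = nov$var_explained,
           retained_variance = sum(nov$var_explained[seq_len(nov$n_pc)])),
      file.path(out, "novelty.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    add_artifact("novelty_map", file.path(out, "novelty.asc"))
    add_artifact("novelty_report", file.path(out, "novelty.json"))
    masked <- apply_novelty_mask(pred, nov,
                                 threshold = config$novelty$threshold)
    write_grid_map(masked, file.path(out, "ensemble_prediction_masked.asc"))
    add_artifact("ensemble_map_masked",
                 file.path(out, "ensemble_prediction_masked.asc"))
  })

  # ---- spatial diagnostics -------------------------------------------------
  stage("diagnose", {
    obs <- log_transform(dat$sites$phytolith_pct)
    sw <- knn_weights(dat$sites, k = config$diagnostics$knn_k)
    morans <- lapply(names(model$fits), function(nm) {
      res <- obs - predict_sites(model$fits[[nm]], dat$sites)
      mc <- morans_mc(res, sw, n_sim = config$diagnostics$n_sim,
                      seed = config$diagnostics$seed)
      list(learner = nm, i_observed = mc$i_observed, p_value = mc$p_value,
           n_sim = mc$n_sim)
    })
    jsonlite::write_json(morans, file.path(out, "morans.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_artifact("morans_report", file.path(out, "morans.json"))
    rc <- residual_correlation(model$fits, dat$sites)
    p <- file.path(out, "residual_correlation.csv")
    write.csv(format(as.data.frame(rc), digits = 12), p, quote = FALSE)
    add_artifact("residual_correlation", p)
  })

  # ---- accumulation --------------------------------------------------------
  stage("accumulate", {
    sc <- do.call(accumulation_scenario, config$accumulation)
    rep <- time_to_threshold(sc)
    jsonlite::write_json(c(unclass(sc), rep),
                         file.path(out, "accumulation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_artifact("accumulation_report", file.path(out, "accumulation.json"))
  })

  settings <- list(
    random_forest = model$fits$random_forest$settings,
    gam = model$fits$gam$settings,
    lasso = model$fits$lasso$settings)
  manifest <- list(package = "phytoSDM",
                   config = unclass(config),
                   learner_settings = settings,
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

config_to_specs <- function(config) {
  specs <- list()
  for (nm in names(config$learners)) {
    specs[[nm]] <- do.call(learner_spec,
                           c(list(kind = nm), config$learners[[nm]]))
  }
  specs
}

write_correlation <- function(tab, path) {
  df <- as.data.frame(tab)
  df$r <- format(df$r, digits = 12)
  df$p_value <- format(df$p_value, digits = 12)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
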