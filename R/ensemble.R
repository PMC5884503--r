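#' Learner specifications
#'
#' A learner spec names one of the three learner kinds and the arguments to
#' fit it with; `default_learner_specs()` returns the standard trio
#' (random forest with 2000 trees and `mtry = 2`; lasso with CV-selected
#' penalty; penalized additive smooths on a 10-variable subset).
#'
#' @param kind One of `"random_forest"`, `"lasso"`, `"gam"`.
#' @param ... Arguments forwarded to the corresponding `fit_*` function.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(kind, ...) {
  kind <- match.arg(kind, c("random_forest", "lasso", "gam"))
  structure(list(kind = kind, args = list(...)), class = "learner_spec")
}

#' @rdname learner_spec
#' @param gam_vars Variable subset for the GAM member (default
#'   [default_gam_vars()]).
#' @export
default_learner_specs <- function(gam_vars = default_gam_vars()) {
  list(random_forest = learner_spec("random_forest", ntree = 2000, mtry = 2),
       gam = learner_spec("gam", vars = gam_vars),
       lasso = learner_spec("lasso"))
}

#' Fit one learner from its spec
#' @param spec A [learner_spec()].
#' @param sites Training `site_table`.
#' @param seed Seed forwarded to stochastic learners.
#' @return A `phyto_fit`.
#' @export
fit_learner <- function(spec, sites, seed = 1) {
  stopifnot(inherits(spec, "learner_spec"))
  args <- spec$args
  if (spec$kind == "gam") {
    if (is.null(args$vars)) args$vars <- default_gam_vars()
    args$vars <- intersect(args$vars,
                           site_covariates(site_table(as.data.frame(sites))))
    do.call(fit_gam, c(list(sites = sites), args))
  } else {
    fn <- switch(spec$kind, random_forest = fit_random_forest,
                 lasso = fit_lasso)
    do.call(fn, c(list(sites = sites, seed = seed), args))
  }
}

#' Prediction quality metrics
#'
#' The evaluation suite used throughout: Pearson correlation between
#' predicted and observed (`rho`), coefficient of determination
#' `R2 = 1 - SS_res / SS_tot`, root-mean-square error, mean absolute error,
#' and mean error `mean(predicted - observed)` (negative values indicate
#' under-prediction). If the predictions are constant, `rho` is reported as 0
#' with `degenerate = TRUE` rather than `NaN`; a zero-variance observed
#' vector makes `R2` undefined (`NA`, flagged).
#'
#' @param observed,predicted Equal-length numeric vectors, `n >= 2`.
#' @return Named list: `rho`, `r2`, `rmse`, `mae`, `me`, `degenerate`.
#' @export
metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    stop("observed and predicted must be equal-length vectors, n >= 2",
         call. = FALSE)
  }
  ok <- is.finite(observed) & is.finite(predicted)
  o <- observed[ok]; p <- predicted[ok]
  err <- p - o
  degenerate <- FALSE
  if (sd(p) == 0 || sd(o) == 0) {
    rho <- 0
    degenerate <- TRUE
  } else {
    rho <- cor(o, p)
  }
  sst <- sum((o - mean(o))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(err^2) / sst
  if (sst == 0) degenerate <- TRUE
  list(rho = rho, r2 = r2, rmse = sqrt(mean(err^2)), mae = mean(abs(err)),
       me = mean(err), degenerate = degenerate)
}

#' k-fold cross-validation of the learner set
#'
#' Assigns every site to one of `k` folds (sizes differing by at most one,
#' fixed by `seed`), and evaluates each learner on pooled out-of-fold
#' predictions of log phytolith content — every learner sees the identical
#' partition. Also reports the ensemble built from the members'
#' correlation-derived weights applied to their out-of-fold predictions.
#'
#' @param sites A `site_table` with response.
#' @param specs Named list of [learner_spec()]s.
#' @param k Number of folds (default 5), `2 <= k <= n`.
#' @param seed Integer seed fixing the partition and member fits.
#' @return A `cv_report`: list with `metrics` (data.frame, one row per
#'   learner plus `"ensemble"`), `folds` (named map site_id -> fold), `oof`
#'   (matrix of out-of-fold log predictions), `weights`, `k`, `seed`.
#' @export
kfold_cv <- function(sites, specs = default_learner_specs(), k = 5,
                     seed = 1) {
  sites <- site_table(as.data.frame(sites))
  n <- nrow(sites)
  if (k < 2 || k > n) {
    stop("cross-validation requires 2 <= k <= number of sites (k = ", k,
         ", n = ", n, ")", call. = FALSE)
  }
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "kind")
  folds <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  names(folds) <- sites$site_id
  obs <- log_transform(sites$phytolith_pct)

  oof <- matrix(NA_real_, n, length(specs),
                dimnames = list(sites$site_id, names(specs)))
  for (f in seq_len(k)) {
    train <- site_table(as.data.frame(sites)[folds != f, , drop = FALSE])
    test <- site_table(as.data.frame(sites)[folds == f, , drop = FALSE])
    for (nm in names(specs)) {
      fit <- fit_learner(specs[[nm]], train, seed = seed + f)
      oof[folds == f, nm] <- predict_sites(fit, test)
    }
  }

  rows <- lapply(names(specs), function(nm) {
    m <- metrics(obs, oof[, nm])
    data.frame(learner = nm, rho = m$rho, r2 = m$r2, rmse = m$rmse,
               mae = m$mae, me = m$me, degenerate = m$degenerate)
  })
  member <- do.call(rbind, rows)
  w <- compute_weights(member$rho)
  names(w) <- member$learner
  ens_pred <- as.numeric(oof %*% w)
  me <- metrics(obs, ens_pred)
  tab <- rbind(member,
               data.frame(learner = "ensemble", rho = me$rho, r2 = me$r2,
                          rmse = me$rmse, mae = me$mae, me = me$me,
                          degenerate = me$degenerate))
  rownames(tab) <- NULL
  structure(list(metrics = tab, folds = folds, oof = oof, weights = w,
                 k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report:", x$k, "folds, seed", x$seed, "\n")
  print(x$metrics, digits = 4)
  invisible(x)
}

#' Ensemble weights from cross-validated correlations
#'
#' Each member's weight is proportional to its cross-validated Pearson
#' correlation between predicted and observed values, clamped at zero
#' (a member whose predictions correlate non-positively gets weight 0) and
#' normalized to sum to one. If no member has positive correlation, equal
#' weights are returned with a warning.
#'
#' @param cv A `cv_report`, or a numeric vector of member correlations.
#' @return Numeric weights, nonnegative, summing to 1.
#' @export
compute_weights <- function(cv) {
  rho <- if (inherits(cv, "cv_report")) {
    m <- cv$metrics[cv$metrics$learner != "ensemble", ]
    stats::setNames(m$rho, m$learner)
  } else {
    cv
  }
  if (length(rho) == 0) stop("empty CV report", call. = FALSE)
  if (all(!is.finite(rho))) stop("no learner has a finite rho", call. = FALSE)
  w <- pmax(ifelse(is.finite(rho), rho, 0), 0)
  if (sum(w) == 0) {
    warning("no member has positive CV correlation; using equal weights",
            call. = FALSE)
    w <- rep(1, length(rho))
  }
  w / sum(w)
}

#' Fit the weighted ensemble
#'
#' Runs [kfold_cv()], derives member weights from the cross-validated
#' correlations, then refits every member on all data. Weights are
#' nonnegative and sum to one.
#'
#' @inheritParams kfold_cv
#' @return An `ensemble_model`: list with `fits`, `weights`, `cv`.
#' @export
fit_ensemble <- function(sites, specs = default_learner_specs(), k = 5,
                         seed = 1) {
  cv <- kfold_cv(sites, specs, k = k, seed = seed)
  if (is.null(names(specs))) names(specs) <- vapply(specs, `[[`, "", "kind")
  fits <- lapply(names(specs), function(nm) {
    fit_learner(specs[[nm]], sites, seed = seed)
  })
  names(fits) <- names(specs)
  structure(list(fits = fits, weights = cv$weights, cv = cv),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model with members:",
      paste(sprintf("%s (w = %.3f)", names(x$weights), x$weights),
            collapse = ", "), "\n")
  invisible(x)
}

#' Ensemble prediction over a raster stack or at sites
#'
#' The ensemble prediction is the weighted sum of the members' log-scale
#' predictions; missing cells propagate. With `back_transform = TRUE` the map
#' is exponentiated per cell to percent units (a naive back-transform with no
#' smearing correction); the map's `units` metadata records the scale.
#'
#' @param model An `ensemble_model`.
#' @param stack A [covariate_stack()].
#' @param back_transform Exponentiate to percent units?
#' @return A `grid_map`.
#' @export
ensemble_predict <- function(model, stack, back_transform = FALSE) {
  stopifnot(inherits(model, "ensemble_model"))
  maps <- lapply(model$fits, predict_raster, stack = stack)
  acc <- maps[[1]]$values * model$weights[[1]]
  for (i in seq_along(maps)[-1]) {
    check_geometry(maps[[1]], maps[[i]])
    acc <- acc + maps[[i]]$values * model$weights[[i]]
  }
  if (back_transform) acc <- exp(acc)
  grid_map(acc, xmin = stack$xmin, ymax = stack$ymax,
           cellsize = stack$cellsize,
           units = if (back_transform) "percent" else "log percent")
}

#' @rdname ensemble_predict
#' @param sites A `site_table`.
#' @return `ensemble_predict_sites()`: numeric vector of log-scale
#'   predictions.
#' @export
ensemble_predict_sites <- function(model, sites) {
  stopifnot(inherits(model, "ensemble_model"))
  preds <- vapply(model$fits, predict_sites, numeric(nrow(sites)),
                  sites = sites)
  as.numeric(preds %*% model$weights)
}

#' Resubstitution fit statistics of the ensemble
#'
#' Training-data (fit to all data) metrics of the ensemble on the log scale:
#' `R2`, mean absolute error, mean error (`predicted - observed`; negative
#' means systematic under-prediction) and median error.
#'
#' @param model An `ensemble_model`.
#' @param sites The training `site_table`.
#' @return Named list: `r2`, `mae`, `me`, `median_error`.
#' @export
ensemble_fit_statistics <- function(model, sites) {
  sites <- site_table(as.data.frame(sites))
  obs <- log_transform(sites$phytolith_pct)
  pred <- ensemble_predict_sites(model, sites)
  m <- metrics(obs, pred)
  list(r2 = m$r2, mae = m$mae, me = m$me,
       median_error = median(pred - obs))
}
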