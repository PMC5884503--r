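#' Fitted abundance learners
#'
#' All learners model the natural log of phytolith content
#' (`log(phytolith_pct)`) as a function of site covariates and predict on the
#' log scale; back-transformation to percent happens only at the ensemble
#' stage. A fit records its kind, training variables, settings actually used
#' and (where stochastic) its seed.
#'
#' @name phyto_fit
NULL

new_phyto_fit <- function(kind, vars, state, settings, seed = NA_integer_) {
  structure(list(kind = kind, vars = vars, scale = "log", state = state,
                 settings = settings, seed = seed),
            class = "phyto_fit")
}

#' @export
print.phyto_fit <- function(x, ...) {
  cat("phyto_fit:", x$kind, "on", length(x$vars),
      "covariates (log response)\n")
  invisible(x)
}

training_matrix <- function(sites, vars, require_response = TRUE,
                            min_sites = 10) {
  sites <- site_table(as.data.frame(sites))
  absent <- setdiff(vars, names(sites))
  if (length(absent) > 0) {
    stop("missing covariate(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (require_response) {
    if (!"phytolith_pct" %in% names(sites)) {
      stop("sites carry no phytolith_pct response", call. = FALSE)
    }
    if (nrow(sites) < min_sites) {
      stop("at least ", min_sites, " sites are required", call. = FALSE)
    }
  }
  x <- as.matrix(as.data.frame(sites)[, vars, drop = FALSE])
  storage.mode(x) <- "double"
  y <- if (require_response) log_transform(sites$phytolith_pct) else NULL
  list(x = x, y = y)
}

#' Fit a regression random forest on log phytolith content
#'
#' A bagged ensemble of CART regression trees with variance-reduction splits:
#' 2000 trees, two candidate variables per split (`mtry = 2`) and minimum
#' node size 5 by default. Importance is the split-criterion (impurity)
#' decrease accumulated per variable, averaged over trees; out-of-bag
#' predictions are retained. Deterministic given `seed`.
#'
#' @param sites A `site_table` with response; at least 10 rows.
#' @param seed Integer seed.
#' @param ntree Number of trees.
#' @param mtry Candidate variables per split.
#' @param min_node Minimum node size (nodes this small are not split).
#' @param vars Covariates to use (default: all).
#' @return A `phyto_fit` of kind `random_forest`.
#' @export
fit_random_forest <- function(sites, seed = 1, ntree = 2000, mtry = 2,
                              min_node = 5, vars = NULL) {
  if (is.null(vars)) vars <- site_covariates(site_table(as.data.frame(sites)))
  if (length(vars) < 2) {
    stop("the random forest requires at least 2 covariates", call. = FALSE)
  }
  tm <- training_matrix(sites, vars)
  res <- withr::with_seed(seed,
    grow_forest_cpp(tm$x, tm$y, as.integer(ntree), as.integer(mtry),
                    as.integer(min_node)))
  names(res$importance) <- vars
  oob <- res$oob_prediction
  oob_r2 <- if (sum(is.finite(oob)) > 2 && var(tm$y) > 0) {
    ok <- is.finite(oob)
    1 - sum((tm$y[ok] - oob[ok])^2) / sum((tm$y[ok] - mean(tm$y[ok]))^2)
  } else NA_real_
  new_phyto_fit("random_forest", vars,
                state = list(trees = res$trees, importance = res$importance,
                             oob_prediction = oob, oob_r2 = oob_r2,
                             y_range = range(tm$y)),
                settings = list(ntree = ntree, mtry = mtry,
                                min_node = min_node),
                seed = seed)
}

#' Fit a lasso regression on log phytolith content
#'
#' Linear regression with an L1 penalty via `glmnet`. By default the penalty
#' is chosen by internal 10-fold cross-validation minimizing mean squared
#' error (`lambda.min`), with the fold assignment fixed by `seed`. Predictors
#' are standardized internally. Zero-variance covariates are dropped with a
#' warning. Pass `lambda` to skip CV and fit at a fixed penalty (`lambda = 0`
#' reproduces ordinary least squares).
#'
#' @param sites A `site_table` with response; at least 10 rows.
#' @param seed Integer seed for the CV fold assignment.
#' @param nfolds Internal CV folds.
#' @param lambda Optional fixed penalty; `NULL` (default) selects by CV.
#' @param vars Covariates to use (default: all).
#' @param standardize,intercept Passed to `glmnet`.
#' @return A `phyto_fit` of kind `lasso`.
#' @export
fit_lasso <- function(sites, seed = 1, nfolds = 10, lambda = NULL,
                      vars = NULL, standardize = TRUE, intercept = TRUE) {
  if (is.null(vars)) vars <- site_covariates(site_table(as.data.frame(sites)))
  tm <- training_matrix(sites, vars)
  sds <- apply(tm$x, 2, sd)
  if (any(sds == 0)) {
    drop <- vars[sds == 0]
    warning("dropping zero-variance covariate(s): ",
            paste(drop, collapse = ", "), call. = FALSE)
    vars <- vars[sds > 0]
    if (length(vars) < 2) {
      stop("fewer than 2 usable covariates remain", call. = FALSE)
    }
    tm$x <- tm$x[, vars, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (is.null(lambda)) {
    foldid <- withr::with_seed(seed,
      sample(rep(seq_len(nfolds), length.out = nrow(tm$x))))
    cvfit <- glmnet::cv.glmnet(tm$x, tm$y, alpha = 1, foldid = foldid,
                               standardize = standardize,
                               intercept = intercept)
    lam <- cvfit$lambda.min
    obj <- cvfit$glmnet.fit
  } else {
    obj <- glmnet::glmnet(tm$x, tm$y, alpha = 1, standardize = standardize,
                          intercept = intercept, thresh = 1e-14)
    lam <- lambda
  }
  beta <- if (is.null(lambda)) {
    as.numeric(coef(obj, s = lam))
  } else {
    as.numeric(coef(obj, s = lam, exact = TRUE, x = tm$x, y = tm$y,
                    alpha = 1, standardize = standardize,
                    intercept = intercept, thresh = 1e-14))
  }
  names(beta) <- c("(Intercept)", vars)
  new_phyto_fit("lasso", vars,
                state = list(glmnet = obj, lambda = lam, beta = beta,
                             train_sd = sds, x = tm$x, y = tm$y,
                             lambda_fixed = !is.null(lambda),
                             standardize = standardize,
                             intercept = intercept),
                settings = list(nfolds = nfolds, lambda = lam,
                                lambda_fixed = !is.null(lambda)),
                seed = seed)
}

#' Fit a penalized additive model on log phytolith content
#'
#' An additive model of univariate penalized cubic regression spline smooths
#' (`mgcv`, basis dimension `k = 10`), with an extra penalty on each smooth's
#' null space (`select = TRUE`) so over-smoothed terms can shrink to
#' effectively zero influence. Smoothing parameters are selected by REML
#' (recorded in the fit). Variables with fewer than 10 distinct values fall
#' back to a linear term, recorded in the fit.
#'
#' @param sites A `site_table` with response; at least 10 rows.
#' @param vars Non-empty covariate subset to smooth over.
#' @param k Basis dimension per smooth.
#' @param method Smoothing selection criterion, passed to `mgcv::gam`.
#' @return A `phyto_fit` of kind `gam`.
#' @export
fit_gam <- function(sites, vars, k = 10, method = "REML") {
  if (missing(vars) || length(vars) == 0) {
    stop("a non-empty variable subset is required", call. = FALSE)
  }
  tm <- training_matrix(sites, vars)
  dat <- as.data.frame(tm$x)
  dat$.logp <- tm$y
  if (var(tm$y) < 1e-12) {
    # constant response: every smooth would shrink to nothing anyway, and
    # REML smoothing-parameter selection breaks down at zero scale
    g <- mgcv::gam(.logp ~ 1, data = dat)
    return(new_phyto_fit("gam", vars,
                         state = list(gam = g, data = dat,
                                      smooth_vars = character(0),
                                      linear_vars = character(0), k = k,
                                      method = method),
                         settings = list(k = k, method = method,
                                         select = TRUE, constant = TRUE,
                                         linear_fallback = character(0))))
  }
  n_distinct <- vapply(dat[vars], function(v) length(unique(v)), integer(1))
  smooth_vars <- vars[n_distinct >= 10]
  linear_vars <- vars[n_distinct < 10]
  terms <- c(sprintf("s(%s, k = %d, bs = \"cr\")", smooth_vars, k),
             linear_vars)
  fml <- stats::as.formula(paste(".logp ~", paste(terms, collapse = " + ")))
  g <- mgcv::gam(fml, data = dat, select = TRUE, method = method)
  new_phyto_fit("gam", vars,
                state = list(gam = g, data = dat, smooth_vars = smooth_vars,
                             linear_vars = linear_vars, k = k,
                             method = method),
                settings = list(k = k, method = method, select = TRUE,
                                linear_fallback = linear_vars))
}

#' Per-variable importance of a fitted learner
#'
#' Learner-specific raw scores — forest: mean impurity (split-criterion)
#' decrease; lasso: absolute standardized coefficient (sign retained); GAM:
#' deviance increase when the term is dropped and the model refit (a
#' chi-square-style nested-model score) — each then scaled by the maximum so
#' the top variable scores 1. Exact ties at the top are broken by variable
#' name order (later tied variables are demoted by one ulp so the top is
#' unique).
#'
#' @param fit A `phyto_fit`.
#' @param sites The training `site_table` (used for GAM refits).
#' @return Data.frame of class `importance_table` with `variable`, `raw`,
#'   `scaled`, `sign`.
#' @export
variable_importance <- function(fit, sites = NULL) {
  stopifnot(inherits(fit, "phyto_fit"))
  if (fit$kind == "random_forest") {
    raw <- fit$state$importance
    sgn <- rep(NA_real_, length(raw))
  } else if (fit$kind == "lasso") {
    beta <- fit$state$beta[fit$vars]
    raw <- abs(beta * fit$state$train_sd)
    sgn <- sign(beta)
  } else if (fit$kind == "gam") {
    raw <- gam_drop_scores(fit)
    sgn <- rep(NA_real_, length(raw))
  } else {
    stop("unknown learner kind: ", fit$kind, call. = FALSE)
  }
  out <- data.frame(variable = fit$vars, raw = unname(raw[fit$vars]),
                    sign = unname(sgn), stringsAsFactors = FALSE)
  mx <- max(out$raw)
  if (mx <= 0) {
    warning("all importance scores are zero", call. = FALSE)
    out$scaled <- 0
  } else {
    out$scaled <- out$raw / mx
    top <- order(-out$scaled, out$variable)[1]
    tied <- which(out$scaled >= 1 & seq_len(nrow(out)) != top)
    out$scaled[tied] <- 1 - .Machine$double.eps
  }
  out <- out[, c("variable", "raw", "scaled", "sign")]
  class(out) <- c("importance_table", class(out))
  out
}

# deviance increase from refitting with each term deleted
gam_drop_scores <- function(fit) {
  st <- fit$state
  full_dev <- stats::deviance(st$gam)
  scores <- vapply(fit$vars, function(v) {
    keep_s <- setdiff(st$smooth_vars, v)
    keep_l <- setdiff(st$linear_vars, v)
    terms <- c(sprintf("s(%s, k = %d, bs = \"cr\")", keep_s, st$k), keep_l)
    if (length(terms) == 0) terms <- "1"
    fml <- stats::as.formula(paste(".logp ~", paste(terms, collapse = " + ")))
    g <- mgcv::gam(fml, data = st$data, select = TRUE, method = st$method)
    max(stats::deviance(g) - full_dev, 0)
  }, numeric(1))
  names(scores) <- fit$vars
  scores
}

#' Predict log phytolith content at sites or over a raster stack
#'
#' `predict_sites()` returns one log-scale prediction per record;
#' `predict_raster()` evaluates the fit at every non-missing cell of a
#' covariate stack and returns a log-scale [grid_map()] (masked cells stay
#' missing). A raster prediction at a cell center equals the site prediction
#' for a site placed at that cell.
#'
#' @param fit A `phyto_fit`.
#' @param sites A `site_table` carrying all training variables.
#' @return `predict_sites()`: numeric vector of log-scale predictions.
#' @export
predict_sites <- function(fit, sites) {
  stopifnot(inherits(fit, "phyto_fit"))
  tm <- training_matrix(sites, fit$vars, require_response = FALSE)
  predict_matrix(fit, tm$x)
}

predict_matrix <- function(fit, x) {
  out <- rep(NA_real_, nrow(x))
  ok <- stats::complete.cases(x)
  if (!any(ok)) return(out)
  xs <- x[ok, , drop = FALSE]
  if (fit$kind == "random_forest") {
    out[ok] <- predict_forest_cpp(fit$state$trees, xs)
  } else if (fit$kind == "lasso") {
    st <- fit$state
    p <- if (isTRUE(st$lambda_fixed)) {
      predict(st$glmnet, newx = xs, s = st$lambda, exact = TRUE,
              x = st$x, y = st$y, alpha = 1,
              standardize = st$standardize, intercept = st$intercept,
              thresh = 1e-14)
    } else {
      predict(st$glmnet, newx = xs, s = st$lambda)
    }
    out[ok] <- as.numeric(p)
  } else if (fit$kind == "gam") {
    out[ok] <- as.numeric(predict(fit$state$gam,
                                  newdata = as.data.frame(xs)))
  } else {
    stop("unknown learner kind: ", fit$kind, call. = FALSE)
  }
  out
}

#' @rdname predict_sites
#' @param stack A [covariate_stack()] carrying all training variables as
#'   layers.
#' @return `predict_raster()`: a `grid_map` in log-percent units.
#' @export
predict_raster <- function(fit, stack) {
  stopifnot(inherits(fit, "phyto_fit"), inherits(stack, "covariate_stack"))
  absent <- setdiff(fit$vars, names(stack$layers))
  if (length(absent) > 0) {
    stop("stack lacks layer(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  df <- stack_to_df(stack, drop_missing = FALSE)
  x <- as.matrix(df[, fit$vars, drop = FALSE])
  pred <- predict_matrix(fit, x)
  pred[!as.vector(t(stack$mask))] <- NA_real_
  grid_map(matrix(pred, stack$nrow, stack$ncol, byrow = TRUE),
           xmin = stack$xmin, ymax = stack$ymax, cellsize = stack$cellsize,
           units = "log percent")
}
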