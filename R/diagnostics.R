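#' k-nearest-neighbour spatial weights
#'
#' Each site's neighbours are its `k` nearest other sites by Euclidean
#' distance (self excluded; duplicate coordinates allowed), with row
#' weights `1/k` so every row sums to one. Distance ties are broken by site
#' order (earlier records first).
#'
#' @param sites A `site_table`, or a two-column matrix/data.frame of
#'   coordinates.
#' @param k Number of neighbours, `1 <= k < n`.
#' @return A `spatial_weights`: list with `neighbors` (list of integer
#'   indices), `weights` (list of numeric weights), `ids`, `k`, `n`.
#' @export
knn_weights <- function(sites, k = 5) {
  if (inherits(sites, "site_table") ||
      (is.data.frame(sites) && all(c("x", "y") %in% names(sites)))) {
    coords <- cbind(sites$x, sites$y)
    ids <- if ("site_id" %in% names(sites)) sites$site_id else
      as.character(seq_len(nrow(coords)))
  } else {
    coords <- as.matrix(sites)
    ids <- as.character(seq_len(nrow(coords)))
  }
  n <- nrow(coords)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < n", call. = FALSE)
  d <- as.matrix(dist(coords))
  neighbors <- lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    others[order(d[i, others], others)][seq_len(k)]
  })
  structure(list(neighbors = neighbors,
                 weights = rep(list(rep(1 / k, k)), n),
                 ids = ids, k = k, n = n),
            class = "spatial_weights")
}

#' Dense row-standardized weight matrix
#' @param sw A `spatial_weights`.
#' @return An `n x n` numeric matrix.
#' @export
weights_matrix <- function(sw) {
  W <- matrix(0, sw$n, sw$n)
  for (i in seq_len(sw$n)) W[i, sw$neighbors[[i]]] <- sw$weights[[i]]
  W
}

#' Moran's I spatial autocorrelation statistic
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with
#' `z = value - mean(value)` and `S0` the sum of all weights. Under the
#' permutation null its expectation is `-1/(n - 1)`.
#'
#' @param values Numeric vector, one per site, non-constant.
#' @param weights A `spatial_weights` (or a dense weight matrix).
#' @return The Moran's I statistic.
#' @export
morans_i <- function(values, weights) {
  W <- if (inherits(weights, "spatial_weights")) weights_matrix(weights)
       else as.matrix(weights)
  n <- length(values)
  if (n < 3 || nrow(W) != n) {
    stop("need >= 3 values matching the weights", call. = FALSE)
  }
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom < .Machine$double.eps * n) {
    stop("values are constant; Moran's I is undefined", call. = FALSE)
  }
  s0 <- sum(W)
  (n / s0) * sum(z * (W %*% z)) / denom
}

#' Permutation test for Moran's I
#'
#' Compares the observed statistic to `n_sim` random permutations of the
#' values over the locations. One-sided (greater) p-value:
#' `(1 + #{I_sim >= I_obs}) / (1 + n_sim)` — large I indicates positive
#' spatial autocorrelation (e.g. missing spatial covariates in residuals).
#' Deterministic given `seed`.
#'
#' @inheritParams morans_i
#' @param n_sim Number of permutations (default 999).
#' @param seed Integer seed.
#' @return List: `i_observed`, `p_value`, `i_sim` (the permuted statistics),
#'   `n_sim`.
#' @export
morans_mc <- function(values, weights, n_sim = 999, seed = 1) {
  W <- if (inherits(weights, "spatial_weights")) weights_matrix(weights)
       else as.matrix(weights)
  i_obs <- morans_i(values, W)
  n <- length(values)
  s0 <- sum(W)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_sim), function(s) sample(values), numeric(n))
  })
  Z <- sweep(perm, 2, colMeans(perm))
  i_sim <- (n / s0) * colSums(Z * (W %*% Z)) / colSums(Z^2)
  p <- (1 + sum(i_sim >= i_obs)) / (1 + n_sim)
  list(i_observed = i_obs, p_value = p, i_sim = i_sim, n_sim = n_sim)
}

#' Pairwise correlation of model residuals
#'
#' Residuals are observed minus predicted log phytolith content per fitted
#' learner; the result is the symmetric Pearson correlation matrix of those
#' residual vectors (unit diagonal).
#'
#' @param fits Named list of `phyto_fit`s (>= 2).
#' @param sites A `site_table` with response.
#' @return Correlation matrix with one row/column per fit.
#' @export
residual_correlation <- function(fits, sites) {
  if (length(fits) < 2) stop("need at least 2 fits", call. = FALSE)
  sites <- site_table(as.data.frame(sites))
  obs <- log_transform(sites$phytolith_pct)
  res <- vapply(fits, function(f) obs - predict_sites(f, sites),
                numeric(nrow(sites)))
  cor(res)
}

#' Environmental-novelty distance map
#'
#' Quantifies extrapolation risk: covariates from `n_ref` random reference
#' cells are standardized (reference means/SDs) and transformed into
#' principal components; every cell and every sampling site is projected into
#' that space, and each cell's novelty is the mean Euclidean distance, in the
#' first `n_pc` components, to its `k_near` nearest site projections. Cells
#' far from all sampled environments get large distances and should not be
#' trusted. Reference cells are drawn uniformly over non-missing cells (with
#' replacement if fewer than `n_ref` exist). Deterministic given `seed`.
#'
#' @param stack A [covariate_stack()].
#' @param sites A `site_table` sharing the stack's covariate names.
#' @param n_ref Number of reference points (default 3000).
#' @param n_pc Number of leading principal components (default 3).
#' @param k_near Number of nearest sites to average over (default 3).
#' @param seed Integer seed.
#' @return A `novelty_map`: list with `map` (a `grid_map` in PC units),
#'   `var_explained` (variance fraction per PC, all PCs), `n_ref`, `n_pc`,
#'   `k_near`, `seed`, `vars`.
#' @export
env_pc_distance <- function(stack, sites, n_ref = 3000, n_pc = 3,
                            k_near = 3, seed = 1) {
  sites <- site_table(as.data.frame(sites))
  vars <- sort(intersect(stack_layers(stack), site_covariates(sites)))
  if (length(vars) == 0) {
    stop("stack and sites share no covariate names", call. = FALSE)
  }
  if (n_pc > length(vars)) {
    stop("n_pc (", n_pc, ") exceeds the number of shared covariates (",
         length(vars), ")", call. = FALSE)
  }
  if (k_near > nrow(sites)) {
    stop("k_near exceeds the number of sites", call. = FALSE)
  }
  df <- stack_to_df(stack, drop_missing = FALSE)
  valid <- as.vector(t(stack$mask))
  cells <- as.matrix(df[valid, vars, drop = FALSE])
  ref_idx <- withr::with_seed(seed,
    sample(nrow(cells), n_ref, replace = nrow(cells) < n_ref))
  ref <- cells[ref_idx, , drop = FALSE]
  mu <- colMeans(ref)
  sdev <- apply(ref, 2, sd)
  sdev[sdev == 0] <- 1 # constant covariates carry no PC information
  zscore <- function(m) sweep(sweep(m, 2, mu), 2, sdev, "/")
  pca <- prcomp(zscore(ref), center = FALSE, scale. = FALSE)
  var_explained <- pca$sdev^2 / sum(pca$sdev^2)
  rot <- pca$rotation[, seq_len(n_pc), drop = FALSE]
  cell_pc <- zscore(cells) %*% rot
  site_pc <- zscore(as.matrix(as.data.frame(sites)[, vars,
                                                   drop = FALSE])) %*% rot
  # mean distance to the k_near nearest site projections, per cell
  d2 <- outer(rowSums(cell_pc^2), rep(1, nrow(site_pc))) -
    2 * cell_pc %*% t(site_pc) +
    outer(rep(1, nrow(cell_pc)), rowSums(site_pc^2))
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  ndist <- apply(d, 1, function(r) mean(sort(r)[seq_len(k_near)]))
  full <- rep(NA_real_, nrow(df))
  full[valid] <- ndist
  map <- grid_map(matrix(full, stack$nrow, stack$ncol, byrow = TRUE),
                  xmin = stack$xmin, ymax = stack$ymax,
                  cellsize = stack$cellsize, units = "environmental PC units")
  structure(list(map = map, var_explained = var_explained, n_ref = n_ref,
                 n_pc = n_pc, k_near = k_near, seed = seed, vars = vars),
            class = "novelty_map")
}

#' Mask environmentally novel cells of a prediction map
#'
#' Cells whose novelty distance exceeds `threshold` (default 3 environmental
#' PC units) are set to missing; all other cells are unchanged bit-for-bit.
#' Idempotent for a fixed novelty map and threshold.
#'
#' @param pred A prediction `grid_map`.
#' @param novelty A `novelty_map` (or a `grid_map` of distances) on the same
#'   geometry.
#' @param threshold Masking threshold in PC units (default 3).
#' @return The masked `grid_map`.
#' @export
apply_novelty_mask <- function(pred, novelty, threshold = 3.0) {
  nov <- if (inherits(novelty, "novelty_map")) novelty$map else novelty
  check_geometry(pred, nov, "prediction and novelty maps")
  out <- pred
  out$values[!is.na(nov$values) & nov$values > threshold] <- NA_real_
  out
}

#' Remove the NPP trend from a prediction map
#'
#' Regresses the prediction on net primary productivity (ordinary least
#' squares over jointly non-missing cells) and returns the residual map —
#' what the spatial prediction says beyond a simple productivity gradient.
#'
#' @param pred Prediction `grid_map`.
#' @param npp NPP `grid_map` on the same geometry (see
#'   [stack_layer_map()]).
#' @return A `grid_map` of residuals, plus attributes `intercept` and
#'   `slope` of the fitted line.
#' @export
npp_detrend <- function(pred, npp) {
  check_geometry(pred, npp, "prediction and NPP maps")
  ok <- is.finite(pred$values) & is.finite(npp$values)
  if (sum(ok) < 3) stop("fewer than 3 joint non-missing cells", call. = FALSE)
  x <- npp$values[ok]
  if (sd(x) == 0) stop("NPP is constant; detrending is undefined",
                       call. = FALSE)
  y <- pred$values[ok]
  fit <- lm(y ~ x)
  vals <- matrix(NA_real_, pred$nrow, pred$ncol)
  vals[ok] <- y - stats::fitted(fit)
  out <- grid_map(vals, xmin = pred$xmin, ymax = pred$ymax,
                  cellsize = pred$cellsize,
                  units = paste(pred$units, "(NPP-detrended)"))
  attr(out, "intercept") <- unname(coef(fit)[1])
  attr(out, "slope") <- unname(coef(fit)[2])
  out
}

#' Hierarchical clustering of covariates by correlation distance
#'
#' Distance between two covariates is `1 - |Pearson r|`, so tightly (anti-)
#' correlated variables merge first; the hierarchy uses average linkage.
#' Constant covariates are excluded with a warning.
#'
#' @param sites A `site_table` with >= 2 non-constant covariates.
#' @return List: `hclust` (an [stats::hclust] tree), `dist` (the distance
#'   matrix), `excluded` (names of constant covariates).
#' @export
variable_cluster <- function(sites) {
  sites <- site_table(as.data.frame(sites))
  covs <- site_covariates(sites)
  x <- as.data.frame(sites)[, covs, drop = FALSE]
  const <- covs[vapply(x, function(v) sd(v) == 0, logical(1))]
  if (length(const) > 0) {
    warning("excluding constant covariate(s): ",
            paste(const, collapse = ", "), call. = FALSE)
  }
  keep <- setdiff(covs, const)
  if (length(keep) < 2) {
    stop("need at least 2 non-constant covariates", call. = FALSE)
  }
  r <- cor(x[, keep, drop = FALSE])
  d <- stats::as.dist(1 - abs(r))
  list(hclust = hclust(d, method = "average"), dist = d, excluded = const)
}
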