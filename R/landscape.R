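#' Configuration of a synthetic landscape
#'
#' Describes a simulated study region with the statistical structure the
#' analysis assumes of real covariate data: a deterministic coast-distance
#' gradient increasing left to right, a block of inter-correlated temperature
#' variables (sharing a latent field that itself carries part of the coastal
#' gradient), a correlated precipitation block, soil layers (pH, bulk
#' density, CEC, and sand/silt/clay fractions summing to one per cell), an
#' NPP layer, and a log-scale phytolith response driven by a configurable
#' linear (optionally smoothly nonlinear) combination of standardized
#' covariates plus site-level noise.
#'
#' @param rows,cols Grid dimensions (at least 4 x 4).
#' @param cellsize Cell edge length in map units (kilometres by convention).
#' @param n_temp,n_precip Number of layers in the temperature and
#'   precipitation blocks.
#' @param block_cor Within-block correlation of the climate blocks, in
#'   `[0, 1)`. Induced by mixing a shared latent field at weight
#'   `sqrt(block_cor)` with an independent field at weight
#'   `sqrt(1 - block_cor)`, so the population pairwise correlation equals
#'   `block_cor` exactly.
#' @param field_range Smoothing length of the Gaussian random fields, in map
#'   units (the kernel standard deviation).
#' @param coefficients Named list/vector of response coefficients; each name
#'   must be a generated covariate. The response is
#'   `log(p) = baseline + sum(coef * standardized covariate) + noise`.
#' @param nonlinear If `TRUE`, each contributing covariate enters through the
#'   smooth bend `z + 0.4 * sin(1.5 * z)` instead of linearly.
#' @param noise_sd Standard deviation of site-level noise on the log scale.
#' @param baseline Baseline log phytolith content (log percent).
#' @param seed Integer seed; all landscape randomness derives from it.
#' @return A validated list of class `landscape_config`.
#' @export
landscape_config <- function(rows = 60, cols = 60, cellsize = 1,
                             n_temp = 12, n_precip = 8, block_cor = 0.7,
                             field_range = 6,
                             coefficients = list(),
                             nonlinear = FALSE, noise_sd = 0.5,
                             baseline = -1.2, seed = 1) {
  if (rows < 4 || cols < 4) stop("grid must be at least 4 x 4", call. = FALSE)
  if (cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
  if (block_cor < 0 || block_cor >= 1) {
    stop("within-block correlation must lie in [0, 1)", call. = FALSE)
  }
  if (n_temp < 0 || n_precip < 0) {
    stop("block sizes must be nonnegative", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              cellsize = cellsize, n_temp = as.integer(n_temp),
              n_precip = as.integer(n_precip), block_cor = block_cor,
              field_range = field_range,
              coefficients = as.list(coefficients),
              nonlinear = isTRUE(nonlinear), noise_sd = noise_sd,
              baseline = baseline, seed = as.integer(seed))
  known <- landscape_layer_names(cfg)
  unknown <- setdiff(names(cfg$coefficients), known)
  if (length(unknown) > 0) {
    stop("response coefficient(s) name no generated covariate: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  class(cfg) <- "landscape_config"
  cfg
}

#' Names of the covariates a configuration generates
#' @param config A `landscape_config`.
#' @return Character vector of layer names.
#' @export
landscape_layer_names <- function(config) {
  c("coast_distance",
    sprintf("temp_%02d", seq_len(config$n_temp)),
    sprintf("precip_%02d", seq_len(config$n_precip)),
    "ph", "bulk_density", "cec", "sand", "silt", "clay", "npp")
}

# Smoothed-white-noise Gaussian random field, standardized to mean 0 / sd 1.
# Separable Gaussian kernel smoothing via row/column smoothing matrices with
# edge renormalization (no wrap-around).
gaussian_field <- function(nr, nc, sd_cells) {
  w <- matrix(rnorm(nr * nc), nr, nc)
  if (sd_cells <= 0) return(standardize_field(w))
  smoother <- function(n) {
    d <- abs(outer(seq_len(n), seq_len(n), "-"))
    k <- exp(-0.5 * (d / sd_cells)^2)
    k / rowSums(k)
  }
  f <- smoother(nr) %*% w %*% t(smoother(nc))
  standardize_field(f)
}

standardize_field <- function(f) {
  s <- sd(as.vector(f))
  if (s == 0) return(f - mean(f))
  (f - mean(f)) / s
}

# Correlated block: sqrt(rho) * shared + sqrt(1 - rho) * independent.
mixed_layer <- function(shared, rho, nr, nc, sd_cells) {
  sqrt(rho) * shared + sqrt(1 - rho) * gaussian_field(nr, nc, sd_cells)
}

#' Generate a synthetic covariate stack
#'
#' Deterministic given `config$seed`. The generated stack contains a
#' deterministic `coast_distance` layer (column index times cell size, zero at
#' the left edge), `temp_*` and `precip_*` blocks whose members share a latent
#' field at the configured within-block correlation, soil layers with
#' sand/silt/clay fractions summing to one (softmax of three independent
#' fields), and an `npp` layer negatively tied to coast distance.
#'
#' @param config A [landscape_config()].
#' @return A [covariate_stack()].
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$rows; nc <- config$cols
  sdc <- config$field_range / config$cellsize
  withr::with_seed(config$seed, {
    coast <- matrix(rep((seq_len(nc) - 1) * config$cellsize, each = nr),
                    nr, nc)
    coastz <- standardize_field(coast)
    layers <- list(coast_distance = coast)

    # temperature block: shared latent carries part of the coastal gradient
    if (config$n_temp > 0) {
      shared_t <- 0.6 * coastz + sqrt(1 - 0.6^2) * gaussian_field(nr, nc, sdc)
      for (j in seq_len(config$n_temp)) {
        layers[[sprintf("temp_%02d", j)]] <-
          mixed_layer(shared_t, config$block_cor, nr, nc, sdc)
      }
    }
    if (config$n_precip > 0) {
      shared_p <- -0.4 * coastz + sqrt(1 - 0.4^2) * gaussian_field(nr, nc, sdc)
      for (j in seq_len(config$n_precip)) {
        layers[[sprintf("precip_%02d", j)]] <-
          mixed_layer(shared_p, config$block_cor, nr, nc, sdc)
      }
    }

    layers$ph <- 6.5 + 0.8 * gaussian_field(nr, nc, sdc)
    layers$bulk_density <- 1.4 + 0.15 * gaussian_field(nr, nc, sdc)
    layers$cec <- 15 + 5 * gaussian_field(nr, nc, sdc)
    # texture shares: softmax of three independent fields, sums to 1 exactly
    e1 <- exp(gaussian_field(nr, nc, sdc))
    e2 <- exp(gaussian_field(nr, nc, sdc))
    e3 <- exp(gaussian_field(nr, nc, sdc))
    tot <- e1 + e2 + e3
    layers$sand <- e1 / tot
    layers$silt <- e2 / tot
    layers$clay <- e3 / tot
    layers$npp <- 600 + 200 * (-0.6 * coastz +
                               0.8 * gaussian_field(nr, nc, sdc))

    covariate_stack(layers[landscape_layer_names(config)],
                    xmin = 0, ymax = nr * config$cellsize,
                    cellsize = config$cellsize)
  })
}

#' Sample site locations from a stack
#'
#' Draws `n` distinct cells uniformly without replacement among non-missing
#' cells (optionally oversampling the coast) and returns a site table whose
#' records carry the covariate values at their cell centers. The response
#' column is absent until [simulate_response()] fills it.
#'
#' @param stack A [covariate_stack()].
#' @param n Number of sites; at most the number of non-missing cells.
#' @param seed Integer seed.
#' @param coast_weight Nonnegative coastal oversampling strength: sampling
#'   probability is proportional to `exp(-coast_weight * scaled coast
#'   distance)`. Zero (the default) is uniform.
#' @return A `site_table` without `phytolith_pct`.
#' @export
sample_sites <- function(stack, n, seed = 1, coast_weight = 0) {
  df <- stack_to_df(stack, drop_missing = TRUE)
  if (n > nrow(df)) {
    stop("requested ", n, " sites but only ", nrow(df),
         " non-missing cells are available", call. = FALSE)
  }
  prob <- NULL
  if (coast_weight > 0 && "coast_distance" %in% names(df)) {
    cd <- df$coast_distance
    rng <- diff(range(cd))
    prob <- exp(-coast_weight * if (rng > 0) (cd - min(cd)) / rng else cd * 0)
  }
  pick <- withr::with_seed(seed, sample(nrow(df), n, prob = prob))
  out <- df[pick, , drop = FALSE]
  out <- cbind(data.frame(site_id = sprintf("site_%03d", seq_len(n)),
                          x = out$x, y = out$y),
               out[, setdiff(names(out), c("row", "col", "x", "y")),
                   drop = FALSE])
  rownames(out) <- NULL
  site_table(out)
}

#' Simulate the phytolith response at sampled sites
#'
#' Fills `phytolith_pct` as `exp(baseline + sum_j coef_j * z_j + noise)`,
#' where `z_j` is the covariate standardized over the given sites (sample
#' mean and standard deviation) and noise is `Normal(0, noise_sd)` on the log
#' scale. With `nonlinear = TRUE` each `z_j` enters through the smooth bend
#' `z + 0.4 sin(1.5 z)`. The stored response is the back-transformed percent
#' value, strictly positive by construction. Deterministic given
#' `config$seed`.
#'
#' @param sites A `site_table` carrying every covariate named in
#'   `config$coefficients`.
#' @param config A [landscape_config()].
#' @return The site table with `phytolith_pct` filled.
#' @export
simulate_response <- function(sites, config) {
  stopifnot(inherits(config, "landscape_config"))
  sites <- site_table(as.data.frame(sites))
  need <- names(config$coefficients)
  absent <- setdiff(need, names(sites))
  if (length(absent) > 0) {
    stop("sites lack covariate(s) named in coefficients: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  eta <- rep(config$baseline, nrow(sites))
  for (nm in need) {
    v <- sites[[nm]]
    s <- sd(v)
    z <- if (s > 0) (v - mean(v)) / s else v * 0
    if (config$nonlinear) z <- z + 0.4 * sin(1.5 * z)
    eta <- eta + config$coefficients[[nm]] * z
  }
  noise <- if (config$noise_sd > 0) {
    withr::with_seed(config$seed + 1L,
                     rnorm(nrow(sites), 0, config$noise_sd))
  } else {
    rep(0, nrow(sites))
  }
  sites$phytolith_pct <- exp(eta + noise)
  site_table(as.data.frame(sites))
}

#' Stock benchmark configurations
#'
#' `default_benchmark_config()` is the package's stated synthetic world for
#' end-to-end exercises: a 60 x 60 km landscape, 28 covariates, a response
#' driven mainly by temperature-stability variables with precipitation, pH
#' and coastal terms, and log-scale noise sd 0.5.
#' `sparse_benchmark_config()` is the sparse linear recovery world: 30
#' covariates of which exactly 5 carry effects, noise sd 0.5, built for 200
#' sites.
#'
#' @param seed Integer seed.
#' @return A [landscape_config()].
#' @export
default_benchmark_config <- function(seed = 1) {
  landscape_config(
    rows = 60, cols = 60, cellsize = 1, n_temp = 12, n_precip = 8,
    block_cor = 0.7, field_range = 6,
    coefficients = list(temp_01 = -0.6, temp_02 = -0.4, precip_01 = 0.35,
                        ph = -0.25, coast_distance = -0.3),
    nonlinear = FALSE, noise_sd = 0.5, baseline = -1.2, seed = seed)
}

#' @rdname default_benchmark_config
#' @export
sparse_benchmark_config <- function(seed = 1) {
  # recovery benchmark: weak within-block correlation so the 5 true effects
  # are identifiable among the 25 null covariates (impurity importance and
  # lasso support both degrade by design under heavily confounded blocks)
  landscape_config(
    rows = 60, cols = 60, cellsize = 1, n_temp = 13, n_precip = 9,
    block_cor = 0.3, field_range = 6,
    coefficients = list(temp_01 = -1.0, precip_01 = 0.9,
                        coast_distance = -0.8, ph = -0.7, npp = 0.6),
    nonlinear = FALSE, noise_sd = 0.5, baseline = -1.2, seed = seed)
}

#' Default GAM variable subset for the synthetic benchmarks
#'
#' Mirrors restricting the additive model to a small set of interpretable
#' predictors (coastal, temperature, precipitation, soil and productivity
#' terms) because smooths are expensive in degrees of freedom.
#'
#' @return Character vector of 10 covariate names.
#' @export
default_gam_vars <- function() {
  c("coast_distance", "temp_01", "temp_02", "temp_03",
    "precip_01", "precip_02", "ph", "bulk_density", "sand", "npp")
}
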