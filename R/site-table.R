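#' Construct and validate a site table
#'
#' A site table holds one record per soil sampling site: a unique `site_id`,
#' planar coordinates `x`/`y` (map units), one column per environmental
#' covariate, and optionally `phytolith_pct`, the phytolith content in percent
#' of dry soil mass (strictly positive wherever present, so its natural log is
#' always defined).
#'
#' @param df A data.frame with columns `site_id`, `x`, `y`, covariate columns,
#'   and optionally `phytolith_pct`.
#' @return The validated data.frame with class `site_table`.
#' @export
site_table <- function(df) {
  required <- c("site_id", "x", "y")
  if (anyDuplicated(names(df))) {
    stop("duplicate column name(s): ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("site table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$site_id)) {
    dup <- df$site_id[duplicated(df$site_id)][1]
    stop("duplicate site_id: ", dup, call. = FALSE)
  }
  if ("phytolith_pct" %in% names(df)) {
    bad <- which(!is.na(df$phytolith_pct) & df$phytolith_pct <= 0)
    if (length(bad) > 0) {
      stop("non-positive phytolith_pct at row ", bad[1],
           " (site ", df$site_id[bad[1]],
           "); the log transform requires positive values", call. = FALSE)
    }
  }
  covs <- setdiff(names(df), c(required, "phytolith_pct"))
  non_num <- covs[!vapply(df[covs], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stop("non-numeric covariate column(s): ", paste(non_num, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- unique(c("site_table", class(df)))
  df
}

#' Covariate column names of a site table
#' @param sites A `site_table`.
#' @return Character vector of covariate names.
#' @export
site_covariates <- function(sites) {
  setdiff(names(sites), c("site_id", "x", "y", "phytolith_pct"))
}

#' Read / write a site table as CSV
#'
#' Columns: `site_id`, `x`, `y`, covariates, `phytolith_pct` (optional).
#' Values round-trip to full double precision.
#'
#' @param path CSV file path.
#' @return `read_sites()` returns a `site_table`.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  site_table(df)
}

#' @rdname read_sites
#' @param sites A `site_table`.
#' @export
write_sites <- function(sites, path) {
  sites <- site_table(as.data.frame(sites))
  # keep the canonical column order: id, coords, covariates, response
  ord <- c("site_id", "x", "y", site_covariates(sites),
           intersect("phytolith_pct", names(sites)))
  df <- as.data.frame(sites)[, ord, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    # full precision, locale-independent text representation
    format(v, digits = 17, trim = TRUE, scientific = FALSE)
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Natural-log transform of phytolith content
#'
#' Phytolith content is modelled on the natural-log scale; these two helpers
#' are exact inverses.
#'
#' @param p Phytolith content in percent dry mass; must be strictly positive.
#' @return `log_transform()` returns `log(p)`; `back_transform()` returns
#'   `exp(y)`.
#' @export
log_transform <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("phytolith content must be finite and strictly positive", call. = FALSE)
  }
  log(p)
}

#' @rdname log_transform
#' @param y Log-scale value.
#' @export
back_transform <- function(y) {
  if (any(!is.finite(y))) stop("log-scale value must be finite", call. = FALSE)
  exp(y)
}

#' Depth-weighted average of a soil covariate
#'
#' Integrates values reported for the standard 0-5, 5-15 and 15-30 cm depth
#' slabs into one value for the 0-30 cm column, weighting each slab by its
#' thickness (5, 10, 15 cm) — a weighted average by volume at constant area.
#'
#' @param v1,v2,v3 Values for the 0-5, 5-15 and 15-30 cm slabs.
#' @return `(5*v1 + 10*v2 + 15*v3) / 30`, vectorized over the inputs.
#' @export
depth_weighted_average <- function(v1, v2, v3) {
  if (any(!is.finite(c(v1, v2, v3)))) {
    stop("depth_weighted_average requires finite inputs", call. = FALSE)
  }
  (5 * v1 + 10 * v2 + 15 * v3) / 30
}

#' Pearson correlation screen of covariates against a response
#'
#' Computes the Pearson product-moment correlation between each covariate and
#' the chosen response over the (optionally restricted) site set, with a
#' two-sided t-test on n - 2 degrees of freedom and the conventional
#' significance stars (* <= .05, ** <= .01, *** <= .001). A restricted-range
#' variant (e.g. only sites within 75 km of the coast) is expressed by
#' `restrict`.
#'
#' @param sites A `site_table` with the response present.
#' @param response Name of the response column (default `phytolith_pct`).
#' @param restrict Optional restriction: either a logical vector over rows of
#'   `sites`, or a function taking the site data.frame and returning one.
#' @return A data.frame of class `correlation_table` with columns `variable`,
#'   `r`, `p_value`, `stars`, `n`, `degenerate`.
#' @export
correlation_screen <- function(sites, response = "phytolith_pct",
                               restrict = NULL) {
  sites <- site_table(as.data.frame(sites))
  if (!response %in% names(sites)) {
    stop("response column not found: ", response, call. = FALSE)
  }
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(restrict)) {
    keep <- if (is.function(restrict)) restrict(as.data.frame(sites)) else restrict
    if (!is.logical(keep) || length(keep) != nrow(sites)) {
      stop("restrict must yield one logical per site", call. = FALSE)
    }
  }
  df <- as.data.frame(sites)[keep & !is.na(sites[[response]]), , drop = FALSE]
  if (nrow(df) < 3) stop("fewer than 3 sites after restriction", call. = FALSE)

  covs <- setdiff(site_covariates(sites), response)
  y <- df[[response]]
  rows <- lapply(covs, function(v) {
    x <- df[[v]]
    n <- sum(is.finite(x) & is.finite(y))
    if (sd(x) == 0 || sd(y) == 0) {
      return(data.frame(variable = v, r = NA_real_, p_value = NA_real_,
                        stars = "", n = n, degenerate = TRUE))
    }
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    data.frame(variable = v, r = unname(ct$estimate), p_value = ct$p.value,
               stars = significance_stars(ct$p.value), n = n,
               degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_table", class(out))
  out
}

#' Significance stars for a p-value
#'
#' The printed convention: `***` for p <= 0.001, `**` for p <= 0.01,
#' `*` for p <= 0.05, empty otherwise.
#'
#' @param p Vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  out <- character(length(p))
  out[p <= 0.05] <- "*"
  out[p <= 0.01] <- "**"
  out[p <= 0.001] <- "***"
  out[is.na(p)] <- ""
  out
}

#' Coastal restricted-range predicate
#'
#' Returns a restriction function selecting sites whose `coast_distance`
#' covariate is at most `max_distance` (same map units as the covariate),
#' mirroring a screen limited to sites within a fixed distance of the coast.
#'
#' @param max_distance Maximum coast distance to keep.
#' @param variable Name of the coast-distance covariate.
#' @return A function usable as `restrict` in [correlation_screen()].
#' @export
coast_restriction <- function(max_distance, variable = "coast_distance") {
  force(max_distance)
  function(df) {
    if (!variable %in% names(df)) {
      stop("restriction variable not found: ", variable, call. = FALSE)
    }
    df[[variable]] <= max_distance
  }
}
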