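#' Phytolith accumulation scenario
#'
#' Parameters of the well-mixed soil accumulation model: a grass community
#' with fractional `cover` producing `biomass` g/m2/yr of dry matter, a
#' fraction `production` of which is phytolith silica, deposits into a soil
#' mixing zone of `depth` cm at bulk density `bulk_density` g/cm3. The model
#' asks how long until the mixing zone reaches a phytolith mass fraction of
#' `threshold` (e.g. 0.003 = 0.30 percent), optionally with first-order
#' dissolution at rate `dissolution` per year.
#'
#' @param cover Grass cover fraction in `[0, 1]`.
#' @param biomass Annual biomass production, g/m2/yr, positive.
#' @param production Phytolith mass fraction of biomass, in `(0, 1)`.
#' @param bulk_density Soil bulk density, g/cm3, positive.
#' @param depth Mixing-zone depth, cm, positive.
#' @param threshold Target phytolith mass fraction, in `(0, 1)`.
#' @param dissolution First-order dissolution rate, fraction/yr in `[0, 1)`.
#' @return A validated list of class `accumulation_scenario`.
#' @export
accumulation_scenario <- function(cover = 0.75, biomass = 200,
                                  production = 0.04, bulk_density = 1.5,
                                  depth = 60, threshold = 0.003,
                                  dissolution = 0) {
  check_range <- function(v, lo, hi, nm, lo_open = FALSE, hi_open = FALSE) {
    ok <- is.finite(v) && (if (lo_open) v > lo else v >= lo) &&
      (if (hi_open) v < hi else v <= hi)
    if (!ok) stop(nm, " out of range", call. = FALSE)
  }
  check_range(cover, 0, 1, "cover")
  check_range(biomass, 0, Inf, "biomass", lo_open = TRUE)
  check_range(production, 0, 1, "production", lo_open = TRUE, hi_open = TRUE)
  check_range(bulk_density, 0, Inf, "bulk_density", lo_open = TRUE)
  check_range(depth, 0, Inf, "depth", lo_open = TRUE)
  if (!(is.finite(threshold) && threshold >= 0 && threshold < 1)) {
    stop("threshold out of range", call. = FALSE)
  }
  check_range(dissolution, 0, 1, "dissolution", hi_open = TRUE)
  structure(list(cover = cover, biomass = biomass, production = production,
                 bulk_density = bulk_density, depth = depth,
                 threshold = threshold, dissolution = dissolution),
            class = "accumulation_scenario")
}

#' Annual phytolith input to the soil
#'
#' `cover x biomass x production` — e.g. 75 percent annual-grass cover at
#' 200 g/m2/yr biomass with 4 percent phytolith production deposits
#' 6 g/m2/yr of silica.
#'
#' @param cover Grass cover fraction in `[0, 1]`.
#' @param biomass Annual biomass production, g/m2/yr, positive.
#' @param production Phytolith mass fraction of biomass, in `(0, 1)`.
#' @return Annual phytolith input, g/m2/yr.
#' @export
annual_input <- function(cover, biomass, production) {
  if (!is.finite(cover) || cover < 0 || cover > 1) {
    stop("cover out of range [0, 1]", call. = FALSE)
  }
  if (!is.finite(biomass) || biomass <= 0) {
    stop("biomass must be positive", call. = FALSE)
  }
  if (!is.finite(production) || production <= 0 || production >= 1) {
    stop("production out of range (0, 1)", call. = FALSE)
  }
  cover * biomass * production
}

#' Mass of the phytolith mixing zone under 1 m2
#'
#' `bulk_density (g/cm3) x depth (cm) x 10,000 cm2/m2` — e.g. 1.5 g/cm3 over
#' the upper 60 cm gives 900,000 g per square metre of ground.
#'
#' @param bulk_density Soil bulk density, g/cm3, positive.
#' @param depth Mixing-zone depth, cm, positive.
#' @return Soil mass of the column, g per m2.
#' @export
mixing_zone_mass <- function(bulk_density, depth) {
  if (!is.finite(bulk_density) || bulk_density <= 0) {
    stop("bulk_density must be positive", call. = FALSE)
  }
  if (!is.finite(depth) || depth <= 0) {
    stop("depth must be positive", call. = FALSE)
  }
  bulk_density * depth * 10000
}

#' Minimum years for soil to reach a phytolith threshold
#'
#' With no dissolution, phytolith stock grows linearly and
#' `t = threshold x mixing mass / annual input` (the default scenario gives
#' 450 years to reach 0.30 percent). With first-order dissolution `delta`,
#' the stock follows `S(t) = (input / delta) (1 - exp(-delta t))`, which is
#' solved for the target; if the steady state `input / delta` is below the
#' target the threshold is unreachable and `Inf` is returned with
#' `reachable = FALSE`. Dissolution can only lengthen the wait, so the
#' zero-dissolution answer is the minimum.
#'
#' @param scenario An [accumulation_scenario()].
#' @return List: `years`, `reachable`, `input` (g/m2/yr), `mass` (g/m2),
#'   `target` (g/m2).
#' @export
time_to_threshold <- function(scenario) {
  stopifnot(inherits(scenario, "accumulation_scenario"))
  input <- annual_input(scenario$cover, scenario$biomass,
                        scenario$production)
  mass <- mixing_zone_mass(scenario$bulk_density, scenario$depth)
  target <- scenario$threshold * mass
  if (target == 0) {
    return(list(years = 0, reachable = TRUE, input = input, mass = mass,
                target = target))
  }
  if (input == 0) {
    return(list(years = Inf, reachable = FALSE, input = input, mass = mass,
                target = target))
  }
  delta <- scenario$dissolution
  if (delta == 0) {
    years <- target / input
  } else if (input / delta <= target) {
    return(list(years = Inf, reachable = FALSE, input = input, mass = mass,
                target = target))
  } else {
    years <- -log(1 - target * delta / input) / delta
  }
  list(years = years, reachable = TRUE, input = input, mass = mass,
       target = target)
}
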