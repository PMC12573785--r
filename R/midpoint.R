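#' Fate-model constants
#'
#' @param area_A effective surface volume of the open ocean free of ice
#'   shelves, in m3, over which a well-mixed emission is absorbed. Default
#'   3.61e14 m3 (the 361e6 km2 ice-free ocean surface taken as a 1 m
#'   exchange layer); see the methods vignette for the provenance of this
#'   constant.
#' @return An object of class `"oa_constants"`.
#' @export
model_constants <- function(area_A = 3.61e14) {
  if (!is.numeric(area_A) || length(area_A) != 1L || !is.finite(area_A) ||
      area_A <= 0) {
    stop("'area_A' must be a single positive number (m3)", call. = FALSE)
  }
  structure(list(area_A = area_A), class = "oa_constants")
}

#' Change in dissolved inorganic carbon per unit emission
#'
#' \deqn{\Delta DIC = \frac{\Delta E_i \cdot DF_i}{M_{CO2} \cdot A}}
#' The emission rate times the pathway's dissolution factor, converted to
#' moles and diluted over the exchange volume.
#'
#' @param emission_kg_per_yr emission rate of the substance, kg/yr (>= 0).
#' @param pathway a [substance_pathway()].
#' @param constants a [model_constants()].
#' @return Change in DIC, mol/m3 per year.
#' @export
delta_dic <- function(emission_kg_per_yr, pathway, constants = model_constants()) {
  stopifnot(inherits(pathway, "oa_pathway"), inherits(constants, "oa_constants"))
  if (any(emission_kg_per_yr < 0)) {
    stop("emission must be non-negative", call. = FALSE)
  }
  emission_kg_per_yr * dissolution_factor(pathway) /
    (pathway$molar_mass_co2 * constants$area_A)
}

#' Fate factor: spCO2 change per unit emission via the Revelle factor
#'
#' The Revelle factor relates the fractional change in surface CO2 partial
#' pressure to the fractional change in DIC; solved for the pressure change
#' given a unit (1 kg/yr) emission it yields the fate factor
#' \deqn{FF_{j,i} = \frac{spCO2_j \cdot RF_j \cdot DF_i}{M_{CO2} \cdot A \cdot DIC_j}}
#' in Pa yr/kg, one value per region and substance.
#'
#' @param states data.frame from [regional_average()] (columns `region_id`,
#'   `rf_mean`, `spco2_mean`, `dic_mean`).
#' @param pathway a [substance_pathway()].
#' @param constants a [model_constants()].
#' @return data.frame with columns `region_id`, `substance_id`, `value`
#'   (Pa yr/kg).
#' @export
fate_factor <- function(states, pathway, constants = model_constants()) {
  stopifnot(is.data.frame(states),
            all(c("region_id", "rf_mean", "spco2_mean", "dic_mean") %in% names(states)),
            inherits(pathway, "oa_pathway"))
  if (any(states$dic_mean <= 0)) {
    stop("dic_mean must be positive in every region", call. = FALSE)
  }
  value <- states$spco2_mean * states$rf_mean * dissolution_factor(pathway) /
    (pathway$molar_mass_co2 * constants$area_A * states$dic_mean)
  data.frame(region_id = states$region_id,
             substance_id = pathway$substance_id,
             value = value)
}

#' Fate sensitivity factors: regional regression of pH on spCO2
#'
#' Per region, ordinary least squares of pH on spCO2 over all pooled
#' non-missing (month, cell) samples. The slope (pH/Pa, expected negative in
#' an acidifying ocean) is the fate sensitivity factor. Regions with fewer
#' than 3 samples or no spCO2 variance cannot be fit and are dropped with a
#' warning.
#'
#' @param fields an [ocean_fields()] object.
#' @param partition an [region_partition()] on the same grid.
#' @param region_id optional subset of regions to fit.
#' @return data.frame with columns `region_id`, `slope`, `intercept`,
#'   `r_squared`, `n_obs`.
#' @export
fit_fsf <- function(fields, partition, region_id = NULL) {
  stopifnot(inherits(fields, "oa_fields"), inherits(partition, "oa_partition"))
  reg <- region_index(partition, fields$grid)
  ids <- if (is.null(region_id)) partition$regions$region_id else region_id
  res <- lapply(ids, function(id) {
    cells <- which(!is.na(reg) & reg == id)
    x <- as.vector(fields$spco2[, cells, drop = FALSE])
    y <- as.vector(fields$ph[, cells, drop = FALSE])
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L || stats::var(x) == 0) {
      return(data.frame(region_id = id, slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_,
                        n_obs = length(x)))
    }
    fit <- stats::lm(y ~ x)
    ss_res <- sum(stats::residuals(fit)^2)
    ss_tot <- sum((y - mean(y))^2)
    data.frame(region_id = id,
               slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
               n_obs = length(x))
  })
  out <- do.call(rbind, res)
  bad <- !is.finite(out$slope)
  if (any(bad)) {
    warning(sprintf("FSF fit failed in %d region(s) (fewer than 3 samples or constant spCO2): %s",
                    sum(bad),
                    paste(utils::head(out$region_id[bad], 5L), collapse = ", ")),
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out
}

#' Midpoint characterization factor per region and substance
#'
#' \deqn{CF_{mid,j,i} = FF_{j,i} \times (-FSF_j)} in pH yr/kg. The fate
#' sensitivity slope is negative where CO2 uptake acidifies, so the extra
#' sign makes the CF positive for a net impact. A positive slope is passed
#' through as a negative CF with a warning, never silently clamped.
#'
#' @param ff data.frame from [fate_factor()].
#' @param fsf data.frame from [fit_fsf()].
#' @return data.frame with columns `region_id`, `substance_id`, `value`
#'   (pH yr/kg); regions present in both inputs only.
#' @export
midpoint_cf <- function(ff, fsf) {
  stopifnot(is.data.frame(ff), is.data.frame(fsf))
  m <- merge(ff, fsf[, c("region_id", "slope")], by = "region_id")
  if (nrow(m) == 0L) {
    stop("no region shared between fate factors and fate sensitivities",
         call. = FALSE)
  }
  if (any(m$slope > 0)) {
    warning(sprintf("%d region(s) have a positive pH~spCO2 slope; their midpoint CFs are negative",
                    length(unique(m$region_id[m$slope > 0]))), call. = FALSE)
  }
  data.frame(region_id = m$region_id,
             substance_id = m$substance_id,
             value = m$value * (-m$slope))
}

#' Area-weighted global aggregate of per-region values
#'
#' Weighted arithmetic mean with weights `area_km2 / sum(area_km2)` over the
#' regions present in `values`; weights are always renormalized over the
#' surviving regions, so regions dropped upstream shed their area from the
#' denominator.
#'
#' @param values data.frame with columns `region_id`, `value`.
#' @param partition an [region_partition()] carrying the areas.
#' @return A single number.
#' @export
aggregate_regional <- function(values, partition) {
  stopifnot(is.data.frame(values),
            all(c("region_id", "value") %in% names(values)),
            inherits(partition, "oa_partition"))
  if (nrow(values) == 0L) stop("nothing to aggregate", call. = FALSE)
  area <- partition$regions$area_km2[match(values$region_id,
                                           partition$regions$region_id)]
  if (anyNA(area)) {
    stop("value table references a region absent from the partition",
         call. = FALSE)
  }
  sum(values$value * area) / sum(area)
}

#' Normalize globally aggregated CFs to CO2 equivalents
#'
#' \deqn{CF_{norm,i} = CF_{agg,i} / CF_{agg,CO2}}
#'
#' @param aggregated named numeric vector of globally aggregated CFs, one per
#'   substance; must contain `"CO2"`.
#' @return Named numeric vector of kg CO2-eq per kg values; CO2 is exactly 1.
#' @export
normalize_cfs <- function(aggregated) {
  if (!("CO2" %in% names(aggregated))) {
    stop("reference substance 'CO2' missing from aggregated CFs", call. = FALSE)
  }
  if (aggregated[["CO2"]] == 0) {
    stop("CO2 aggregate is zero; cannot normalize", call. = FALSE)
  }
  aggregated / aggregated[["CO2"]]
}

#' Run the full midpoint chain on one field set
#'
#' Convenience wrapper: regional averaging, fate factors for every pathway,
#' fate sensitivity regressions, per-region midpoint CFs, area-weighted
#' global aggregation and CO2-equivalent normalization.
#'
#' @param fields an [ocean_fields()] object.
#' @param partition an [region_partition()].
#' @param pathways named list of [substance_pathway()] objects; defaults to
#'   the CO2/CO/CH4 registry.
#' @param constants a [model_constants()].
#' @return A list of class `"oa_midpoint"` with elements `states`, `ff`,
#'   `fsf`, `cf` (all data.frames), `global` and `normalized` (named
#'   vectors).
#' @export
midpoint_pipeline <- function(fields, partition,
                              pathways = default_pathways(),
                              constants = model_constants()) {
  states <- regional_average(fields, partition)
  fsf <- fit_fsf(fields, partition)
  ff <- do.call(rbind, lapply(pathways, fate_factor,
                              states = states, constants = constants))
  cf <- midpoint_cf(ff, fsf)
  global <- vapply(names(pathways), function(s) {
    aggregate_regional(cf[cf$substance_id == s, c("region_id", "value")],
                       partition)
  }, numeric(1L))
  structure(list(states = states, ff = ff, fsf = fsf, cf = cf,
                 global = global, normalized = normalize_cfs(global)),
            class = "oa_midpoint")
}

#' @export
print.oa_midpoint <- function(x, ...) {
  cat(sprintf("Midpoint characterization: %d regions x %d substances = %d CFs\n",
              length(unique(x$cf$region_id)),
              length(unique(x$cf$substance_id)), nrow(x$cf)))
  cat("Global area-weighted CFs [pH yr/kg] and CO2-equivalents:\n")
  for (s in names(x$global)) {
    cat(sprintf("  %-4s %.4g  (%.2f kg CO2-eq/kg)\n",
                s, x$global[[s]], x$normalized[[s]]))
  }
  invisible(x)
}

#' Compare two climate-scenario field sets
#'
#' For two field sets on the same grid, months and partition (e.g. Revelle
#' factors modeled under two concentration pathways), reports the mean
#' change in regional Revelle factor, the mean change in the per-region CF
#' of the given substance, and their ratio (CF sensitivity per unit RF).
#'
#' @param fields_a,fields_b [ocean_fields()] objects sharing grid and months.
#' @param partition an [region_partition()].
#' @param pathway a [substance_pathway()].
#' @param constants a [model_constants()].
#' @return list with `mean_delta_rf`, `mean_delta_cf`, `sensitivity`, and
#'   the per-region delta table `deltas`.
#' @export
compare_scenarios <- function(fields_a, fields_b, partition,
                              pathway = default_pathways()$CO2,
                              constants = model_constants()) {
  stopifnot(inherits(fields_a, "oa_fields"), inherits(fields_b, "oa_fields"))
  if (!identical(dim(fields_a$rf), dim(fields_b$rf)) ||
      !identical(fields_a$months, fields_b$months) ||
      !isTRUE(all.equal(fields_a$grid[c("lat", "lon")],
                        fields_b$grid[c("lat", "lon")]))) {
    stop("scenario field sets must share grid and month axes", call. = FALSE)
  }
  run <- function(f) {
    st <- regional_average(f, partition)
    cf <- midpoint_cf(fate_factor(st, pathway, constants), fit_fsf(f, partition))
    merge(st[, c("region_id", "rf_mean")], cf[, c("region_id", "value")],
          by = "region_id")
  }
  a <- run(fields_a)
  b <- run(fields_b)
  m <- merge(a, b, by = "region_id", suffixes = c("_a", "_b"))
  deltas <- data.frame(region_id = m$region_id,
                       delta_rf = m$rf_mean_b - m$rf_mean_a,
                       delta_cf = m$value_b - m$value_a)
  mean_drf <- mean(deltas$delta_rf)
  mean_dcf <- mean(deltas$delta_cf)
  list(mean_delta_rf = mean_drf,
       mean_delta_cf = mean_dcf,
       sensitivity = if (mean_drf != 0) mean_dcf / mean_drf else NA_real_,
       deltas = deltas)
}
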