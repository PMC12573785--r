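# run code under a fixed seed on a private RNG stream, restoring global state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Synthetic grid with an idealized land/ocean geometry
#'
#' A regular lat/lon grid of cell centers with two full-height rectangular
#' continents (longitudes \[-80, -40) and \[30, 70)). The four single-cell
#' ocean columns hugging the continental margins play the role of coastal
#' water; the rest of the ocean is open water.
#'
#' @param resolution cell size in degrees (default 2).
#' @return data.frame with columns `lat`, `lon`, `ocean`, `coastal`.
#' @export
generate_grid <- function(resolution = 2) {
  stopifnot(resolution > 0, 180 %% resolution == 0)
  lat <- seq(-90 + resolution / 2, 90 - resolution / 2, by = resolution)
  lon <- seq(-180 + resolution / 2, 180 - resolution / 2, by = resolution)
  g <- expand.grid(lon = lon, lat = lat)[, c("lat", "lon")]
  land <- (g$lon >= -80 & g$lon < -40) | (g$lon >= 30 & g$lon < 70)
  g$ocean <- !land
  west_of <- function(edge) g$lon >= edge - resolution & g$lon < edge
  east_of <- function(edge) g$lon >= edge & g$lon < edge + resolution
  g$coastal <- g$ocean & (west_of(-80) | east_of(-40) | west_of(30) | east_of(70))
  rownames(g) <- NULL
  g
}

# equirectangular cell area in km2 at a given latitude
cell_area_km2 <- function(lat, resolution) {
  (111.32 * resolution)^2 * cos(lat * pi / 180)
}

#' Synthetic region partition: coastal bands plus open-ocean blocks
#'
#' Splits the coastal columns of the synthetic grid into `n_ecoregions`
#' thin latitudinal band segments (coastal biogeographic units) and the open
#' ocean into `n_fao` large longitude-ordered blocks (open-ocean fishing
#' areas). Region areas are the summed cos-latitude cell areas in km2. The
#' partition is disjoint by construction and covers every ocean cell.
#'
#' @param n_ecoregions number of coastal units (default 232).
#' @param n_fao number of open-ocean units (default 18).
#' @param grid a grid from [generate_grid()]; built at `resolution` if
#'   omitted.
#' @param resolution grid cell size in degrees when `grid` is omitted.
#' @return An [region_partition()]; the grid used is attached as attribute
#'   `"grid"`.
#' @export
generate_regions <- function(n_ecoregions = 232L, n_fao = 18L,
                             grid = NULL, resolution = 2) {
  if (is.null(grid)) grid <- generate_grid(resolution)
  stopifnot(n_ecoregions >= 1L, n_fao >= 1L)
  res <- min(diff(sort(unique(grid$lat))))
  coastal <- which(grid$coastal)
  open <- which(grid$ocean & !grid$coastal)
  if (length(coastal) < n_ecoregions) {
    stop(sprintf("grid too coarse: %d coastal cells cannot host %d ecoregions",
                 length(coastal), n_ecoregions), call. = FALSE)
  }
  if (length(open) < n_fao) {
    stop(sprintf("grid too coarse: %d open-ocean cells cannot host %d fao areas",
                 length(open), n_fao), call. = FALSE)
  }
  # coastal cells ordered strip by strip, south to north, then chunked
  coastal <- coastal[order(grid$lon[coastal], grid$lat[coastal])]
  eco_of <- ceiling(seq_along(coastal) / (length(coastal) / n_ecoregions))
  eco_of <- pmin(eco_of, n_ecoregions)
  open <- open[order(grid$lon[open], grid$lat[open])]
  fao_of <- ceiling(seq_along(open) / (length(open) / n_fao))
  fao_of <- pmin(fao_of, n_fao)
  assignment <- rbind(
    data.frame(lat = grid$lat[coastal], lon = grid$lon[coastal],
               region_id = sprintf("eco%03d", eco_of)),
    data.frame(lat = grid$lat[open], lon = grid$lon[open],
               region_id = sprintf("fao%02d", fao_of))
  )
  area <- tapply(cell_area_km2(assignment$lat, res), assignment$region_id, sum)
  regions <- data.frame(
    region_id = names(area),
    region_type = ifelse(startsWith(names(area), "eco"), "ecoregion", "fao"),
    area_km2 = as.numeric(area))
  part <- region_partition(regions, assignment)
  attr(part, "grid") <- grid
  part
}

#' Configuration of the synthetic ocean-field generator
#'
#' Defaults emulate the observational structure the fate model assumes: a
#' Revelle factor rising poleward from about 10 to 16, surface spCO2 near
#' 40 Pa with a mild latitudinal gradient and a seasonal cycle, pH tied to
#' spCO2 through a negative per-region slope spanning the span of plausible
#' regional pH sensitivities, and DIC near 2.1 mol/m3.
#'
#' @param resolution grid cell size, degrees.
#' @param months number of monthly layers (default 12).
#' @param rf_base,rf_polar_amplitude Revelle factor at the equator and its
#'   poleward increase.
#' @param spco2_base mean surface partial pressure of CO2, Pa.
#' @param dic_base mean dissolved inorganic carbon, mol/m3.
#' @param fsf_range range (most severe, least severe) of the true negative
#'   pH-per-Pa slopes assigned to regions.
#' @param noise_sd named list of Gaussian noise standard deviations per
#'   variable (`rf`, `spco2`, `ph`, `dic`).
#' @param seed integer seed for the generator's private RNG stream.
#' @return An object of class `"oa_field_config"`.
#' @export
field_gen_config <- function(resolution = 2, months = 12L,
                             rf_base = 10, rf_polar_amplitude = 6,
                             spco2_base = 40, dic_base = 2.1,
                             fsf_range = c(-1.6e-2, -1.47e-4),
                             noise_sd = list(rf = 0.2, spco2 = 0.5,
                                             ph = 0.002, dic = 0.02),
                             seed = 1L) {
  stopifnot(resolution > 0, months >= 1L, rf_base > 0, spco2_base > 0,
            dic_base > 0, all(fsf_range < 0), length(fsf_range) == 2L)
  sd <- lapply(noise_sd, as.numeric)
  stopifnot(all(c("rf", "spco2", "ph", "dic") %in% names(sd)),
            all(unlist(sd) >= 0))
  structure(list(resolution = resolution, months = as.integer(months),
                 rf_base = rf_base, rf_polar_amplitude = rf_polar_amplitude,
                 spco2_base = spco2_base, dic_base = dic_base,
                 fsf_range = sort(fsf_range), noise_sd = sd,
                 seed = as.integer(seed)),
            class = "oa_field_config")
}

#' Generate synthetic gridded monthly ocean fields
#'
#' Pure function of (config, partition): the Revelle factor rises poleward,
#' spCO2 carries latitudinal and seasonal structure, pH responds to spCO2
#' through each region's true negative slope (drawn uniformly from
#' `fsf_range` under the config seed, and recoverable from the attribute
#' `"true_fsf"`), and DIC stays near its base value. Without a partition the
#' pH slope varies smoothly with latitude instead. Land cells are `NA`.
#'
#' @param config an [field_gen_config()].
#' @param partition optional [generate_regions()] partition on the same
#'   resolution; enables per-region pH sensitivities.
#' @return An [ocean_fields()] object with attribute `"true_fsf"`
#'   (data.frame `region_id`, `slope`) when a partition is supplied.
#' @export
generate_fields <- function(config = field_gen_config(), partition = NULL) {
  stopifnot(inherits(config, "oa_field_config"))
  grid <- if (!is.null(partition) && !is.null(attr(partition, "grid"))) {
    attr(partition, "grid")
  } else {
    generate_grid(config$resolution)
  }
  n_cells <- nrow(grid)
  n_months <- config$months
  months <- sprintf("m%02d", seq_len(n_months))
  sd <- config$noise_sd

  with_local_seed(config$seed, {
    # per-cell true pH sensitivity: regional where a partition is given
    if (!is.null(partition)) {
      ids <- partition$regions$region_id
      slopes <- stats::runif(length(ids), config$fsf_range[1L], config$fsf_range[2L])
      names(slopes) <- ids
      reg <- region_index(partition, grid)
      slope_cell <- unname(slopes[reg])
      true_fsf <- data.frame(region_id = ids, slope = unname(slopes))
    } else {
      severity <- abs(grid$lat) / 90
      slope_cell <- config$fsf_range[2L] +
        (config$fsf_range[1L] - config$fsf_range[2L]) * severity
      true_fsf <- NULL
    }
    slope_cell[is.na(slope_cell)] <- mean(config$fsf_range)

    lat_m <- matrix(grid$lat, n_months, n_cells, byrow = TRUE)
    lon_m <- matrix(grid$lon, n_months, n_cells, byrow = TRUE)
    month_m <- matrix(seq_len(n_months), n_months, n_cells)
    noise <- function(s) {
      if (s > 0) matrix(stats::rnorm(n_months * n_cells, 0, s), n_months, n_cells)
      else matrix(0, n_months, n_cells)
    }
    rf <- config$rf_base + config$rf_polar_amplitude * abs(lat_m) / 90 + noise(sd$rf)
    season <- sin(2 * pi * (month_m - 1) / max(n_months, 2) + lon_m * pi / 180)
    spco2 <- config$spco2_base + 3 * cos(lat_m * pi / 180) + 2 * season +
      noise(sd$spco2)
    slope_m <- matrix(slope_cell, n_months, n_cells, byrow = TRUE)
    intercept_m <- 8.1 - slope_m * config$spco2_base
    ph <- intercept_m + slope_m * spco2 + noise(sd$ph)
    dic <- config$dic_base + 0.05 * abs(lat_m) / 90 + noise(sd$dic)

    land <- !grid$ocean
    for (nm in c("rf", "spco2", "ph", "dic")) {
      m <- get(nm)
      m[, land] <- NA_real_
      assign(nm, m)
    }
    out <- ocean_fields(grid, months, rf, spco2, ph, dic)
    attr(out, "true_fsf") <- true_fsf
    out
  })
}

#' Configuration of the synthetic species-experiment generator
#'
#' Defaults emulate the structure of a compiled acidification-experiment
#' dataset: 32 animal species spread over three calcification levels (with
#' strong calcifiers failing at the mildest acidification), four climate
#' zones (some species spanning two), and trophic levels 2-4; each species
#' contributes one single-stressor assay with a control near pH 8.1 and a
#' descending test-pH ladder, responses drawn from its true logistic
#' dose-response curve plus noise.
#'
#' @param n_species number of species (default 32).
#' @param ph50_mean named vector of true pH50 means per calcification level;
#'   order strong > slight > non encodes the expected sensitivity ranking.
#' @param ph50_sd spread of true pH50 within a calcification level.
#' @param beta_range range of true logistic slopes (pH units).
#' @param calc_prop mix over calcification levels.
#' @param test_ph descending ladder of test pH conditions (>= 3).
#' @param control_ph control condition pH.
#' @param control_response control response magnitude (arbitrary trait units).
#' @param noise_sd Gaussian noise on the relative-response scale.
#' @param seed integer seed.
#' @return An object of class `"oa_species_config"`.
#' @export
species_gen_config <- function(n_species = 32L,
                               ph50_mean = c(strong = 7.75, slight = 7.55, non = 7.25),
                               ph50_sd = 0.15,
                               beta_range = c(0.1, 0.3),
                               calc_prop = c(strong = 0.375, slight = 0.25, non = 0.375),
                               test_ph = c(8.0, 7.8, 7.6, 7.4, 7.2, 7.0),
                               control_ph = 8.1,
                               control_response = 100,
                               noise_sd = 0.03,
                               seed = 1L) {
  stopifnot(n_species >= 1L, length(test_ph) >= 3L,
            all(names(ph50_mean) == c("strong", "slight", "non")),
            ph50_mean["strong"] > ph50_mean["slight"],
            ph50_mean["slight"] > ph50_mean["non"],
            all(beta_range > 0), noise_sd >= 0,
            abs(sum(calc_prop) - 1) < 1e-8)
  structure(list(n_species = as.integer(n_species), ph50_mean = ph50_mean,
                 ph50_sd = ph50_sd, beta_range = beta_range,
                 calc_prop = calc_prop, test_ph = sort(test_ph, decreasing = TRUE),
                 control_ph = control_ph, control_response = control_response,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "oa_species_config")
}

#' Generate synthetic species acidification experiments
#'
#' Pure function of the config. Each species draws a true (pH50, beta) from
#' its calcification level's distribution; test responses follow the
#' logistic dose-response curve at those parameters plus Gaussian noise on
#' the relative-response scale. Most assays record a harm-decreasing trait
#' (e.g. calcification rate); every sixth records a harm-increasing one
#' (e.g. bioerosion). Categories are cycled deterministically so every
#' calcification level, climate zone and trophic level is populated. All
#' records pass [screen_experiment()] by construction.
#'
#' @param config an [species_gen_config()].
#' @return list of [experiment_record()] objects with attribute
#'   `"true_params"` (data.frame `species_id`, `ph50`, `beta`,
#'   `calcification`).
#' @export
generate_experiments <- function(config = species_gen_config()) {
  stopifnot(inherits(config, "oa_species_config"))
  n <- config$n_species
  zones <- c("tropical", "subtropical", "temperate", "polar")
  calc_n <- round(config$calc_prop * n)
  calc_n[1L] <- n - sum(calc_n[-1L])
  calcification <- rep(names(config$calc_prop), times = calc_n)

  with_local_seed(config$seed, {
    true_ph50 <- pmin(pmax(stats::rnorm(n, config$ph50_mean[calcification],
                                        config$ph50_sd), 6.6), 8.5)
    true_beta <- stats::runif(n, config$beta_range[1L], config$beta_range[2L])
    records <- vector("list", n)
    for (i in seq_len(n)) {
      zone <- zones[(i - 1L) %% 4L + 1L]
      if (i %% 3L == 0L) zone <- c(zone, zones[i %% 4L + 1L])
      trophic <- 2L + (i - 1L) %% 3L
      harm_increases <- i %% 6L == 0L
      crr <- logistic_crr(config$test_ph, true_ph50[i], true_beta[i])
      err_obs <- crr + if (config$noise_sd > 0) {
        stats::rnorm(length(crr), 0, config$noise_sd)
      } else 0
      r_c <- config$control_response
      if (harm_increases) {
        err_obs <- pmin(err_obs, 1 - 1e-9)   # keep the response finite
        response <- r_c / (1 - err_obs)
      } else {
        err_obs <- pmin(err_obs, 1)          # a trait cannot fall below zero
        response <- r_c * (1 - err_obs)
      }
      records[[i]] <- experiment_record(
        experiment_id = sprintf("exp%03d", i),
        species_id = sprintf("sp%02d", i),
        trait = if (harm_increases) "bioerosion_rate" else "calcification_rate",
        direction = if (harm_increases) "harm_increases_response"
                    else "harm_decreases_response",
        ph_c = config$control_ph, r_c = r_c,
        tests = data.frame(ph = config$test_ph, response = response),
        calcification = calcification[i],
        climate_zones = zone,
        trophic_level = trophic)
    }
    attr(records, "true_params") <- data.frame(
      species_id = sprintf("sp%02d", seq_len(n)),
      ph50 = true_ph50, beta = true_beta,
      calcification = calcification)
    records
  })
}
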