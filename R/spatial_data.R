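#' Gridded monthly surface-ocean fields
#'
#' Container for the four monthly surface-ocean variables the fate model
#' consumes: Revelle factor (`rf`, dimensionless), surface partial pressure of
#' CO2 (`spco2`, Pa), total-scale pH (`ph`) and dissolved inorganic carbon
#' (`dic`, mol/m3). All variables share one lat/lon grid of cell centers and
#' one ordered month axis. Land (or otherwise missing) cells carry `NA`,
#' never zero.
#'
#' @param grid data.frame with columns `lat`, `lon` (cell centers, degrees;
#'   longitude in \[-180, 180), latitude in \[-90, 90\]) and logical `ocean`.
#' @param months character vector of ordered month labels.
#' @param rf,spco2,ph,dic numeric matrices, `length(months)` rows by
#'   `nrow(grid)` columns.
#' @return An object of class `"oa_fields"`.
#' @export
ocean_fields <- function(grid, months, rf, spco2, ph, dic) {
  stopifnot(is.data.frame(grid), all(c("lat", "lon", "ocean") %in% names(grid)))
  if (any(grid$lat < -90 | grid$lat > 90)) {
    stop("grid latitudes must lie in [-90, 90]", call. = FALSE)
  }
  if (any(grid$lon < -180 | grid$lon >= 180)) {
    stop("grid longitudes must lie in [-180, 180)", call. = FALSE)
  }
  months <- as.character(months)
  vars <- list(rf = rf, spco2 = spco2, ph = ph, dic = dic)
  for (nm in names(vars)) {
    v <- vars[[nm]]
    if (is.null(v)) stop(sprintf("missing variable '%s'", nm), call. = FALSE)
    if (!is.matrix(v) || nrow(v) != length(months) || ncol(v) != nrow(grid)) {
      stop(sprintf("variable '%s' must be a %d x %d matrix (months x cells)",
                   nm, length(months), nrow(grid)), call. = FALSE)
    }
  }
  ocean_idx <- which(grid$ocean)
  if (length(ocean_idx) > 0L && all(is.na(rf[, ocean_idx]))) {
    stop("variable 'rf' is entirely missing on ocean cells", call. = FALSE)
  }
  # physically implausible values point at unit mix-ups in the input
  chk <- function(v, ok, what) {
    bad <- v[, ocean_idx, drop = FALSE]
    bad <- bad[is.finite(bad)]
    if (length(bad) && !all(ok(bad))) {
      stop(sprintf("variable '%s' has values outside the plausible range (%s)",
                   what, paste(range(bad), collapse = " .. ")), call. = FALSE)
    }
  }
  chk(rf,  function(x) x > 0,            "rf")
  chk(dic, function(x) x > 0,            "dic")
  chk(ph,  function(x) x >= 6 & x <= 9,  "ph")
  structure(
    list(grid = grid, months = months,
         rf = rf, spco2 = spco2, ph = ph, dic = dic),
    class = "oa_fields"
  )
}

#' @export
print.oa_fields <- function(x, ...) {
  cat(sprintf("Gridded ocean fields: %d months x %d cells (%d ocean)\n",
              length(x$months), nrow(x$grid), sum(x$grid$ocean)))
  for (nm in c("rf", "spco2", "ph", "dic")) {
    v <- x[[nm]][, x$grid$ocean, drop = FALSE]
    cat(sprintf("  %-5s mean %8.4g  range [%.4g, %.4g]\n", nm,
                mean(v, na.rm = TRUE), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write / read gridded fields as long-format CSV
#'
#' The on-disk interchange format is a long table with columns
#' `month, lat, lon, variable, value`; one row per (month, cell, variable),
#' missing values as empty fields. [read_fields_csv()] validates the result
#' through [ocean_fields()]; a cell is flagged as ocean when any variable is
#' non-missing there.
#'
#' @param fields an [ocean_fields()] object.
#' @param path file path.
#' @return `write_fields_csv()` returns `path` invisibly; `read_fields_csv()`
#'   returns an `"oa_fields"` object.
#' @export
write_fields_csv <- function(fields, path) {
  stopifnot(inherits(fields, "oa_fields"))
  g <- fields$grid
  nm <- length(fields$months)
  nc <- nrow(g)
  long <- do.call(rbind, lapply(c("rf", "spco2", "ph", "dic"), function(v) {
    data.frame(month = rep(fields$months, times = nc),
               lat = rep(g$lat, each = nm),
               lon = rep(g$lon, each = nm),
               variable = v,
               value = as.vector(fields[[v]]))
  }))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_fields_csv
#' @export
read_fields_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("month", "lat", "lon", "variable", "value")
  if (!all(need %in% names(long))) {
    stop(sprintf("fields CSV must have columns %s", paste(need, collapse = ", ")),
         call. = FALSE)
  }
  months <- unique(as.character(long$month))
  key <- paste(long$lat, long$lon)
  cells <- !duplicated(key)
  grid <- data.frame(lat = long$lat[cells], lon = long$lon[cells])
  cell_of <- match(key, key[cells])
  month_of <- match(as.character(long$month), months)
  out <- list()
  for (v in c("rf", "spco2", "ph", "dic")) {
    rows <- long$variable == v
    if (!any(rows)) stop(sprintf("missing variable '%s'", v), call. = FALSE)
    m <- matrix(NA_real_, length(months), nrow(grid))
    m[cbind(month_of[rows], cell_of[rows])] <- long$value[rows]
    out[[v]] <- m
  }
  any_data <- Reduce(`|`, lapply(out, function(m) colSums(!is.na(m)) > 0))
  grid$ocean <- any_data
  ocean_fields(grid, months, out$rf, out$spco2, out$ph, out$dic)
}

#' Disjoint spatial partition of the ocean into characterization regions
#'
#' Pairs a region table (coastal "ecoregion" units and open-ocean "fao"
#' units with their areas in km2) with a cell-to-region assignment. Every
#' ocean cell belongs to at most one region; assigning a cell twice is
#' rejected, mirroring the requirement that the coastal and open-ocean
#' layers be made non-overlapping before use.
#'
#' @param regions data.frame with columns `region_id`, `region_type`
#'   (`"ecoregion"` or `"fao"`), `area_km2` (> 0).
#' @param assignment data.frame with columns `lat`, `lon`, `region_id`
#'   mapping cell centers to regions; unlisted cells are unassigned.
#' @return An object of class `"oa_partition"`.
#' @export
region_partition <- function(regions, assignment) {
  stopifnot(is.data.frame(regions),
            all(c("region_id", "region_type", "area_km2") %in% names(regions)))
  stopifnot(is.data.frame(assignment),
            all(c("lat", "lon", "region_id") %in% names(assignment)))
  if (anyDuplicated(regions$region_id)) {
    stop("duplicate region_id in region table", call. = FALSE)
  }
  if (!all(regions$region_type %in% c("ecoregion", "fao"))) {
    stop("region_type must be 'ecoregion' or 'fao'", call. = FALSE)
  }
  if (any(!is.finite(regions$area_km2)) || any(regions$area_km2 <= 0)) {
    stop("all region areas must be positive (km2)", call. = FALSE)
  }
  key <- paste(round(assignment$lat, 6), round(assignment$lon, 6))
  dup <- duplicated(key)
  if (any(dup)) {
    stop(sprintf("cell (%s, %s) assigned to more than one region; the partition must be disjoint",
                 assignment$lat[dup][1L], assignment$lon[dup][1L]), call. = FALSE)
  }
  unknown <- setdiff(unique(assignment$region_id), regions$region_id)
  if (length(unknown)) {
    stop(sprintf("assignment references unknown region id(s): %s",
                 paste(utils::head(unknown, 5L), collapse = ", ")), call. = FALSE)
  }
  if (nrow(assignment) == 0L) {
    warning("empty assignment: partition covers zero cells", call. = FALSE)
  }
  structure(list(regions = regions, assignment = assignment),
            class = "oa_partition")
}

#' @export
print.oa_partition <- function(x, ...) {
  tab <- table(x$regions$region_type)
  cat(sprintf("Region partition: %d regions (%s), %d assigned cells\n",
              nrow(x$regions),
              paste(sprintf("%s %s", names(tab), tab), collapse = ", "),
              nrow(x$assignment)))
  invisible(x)
}

#' Read a region partition from its two CSV tables
#'
#' @param region_path CSV with columns `region_id`, `region_type`, `area_km2`.
#' @param assignment_path CSV with columns `lat`, `lon`, `region_id`.
#' @return An `"oa_partition"` object.
#' @export
read_partition_csv <- function(region_path, assignment_path) {
  region_partition(utils::read.csv(region_path, stringsAsFactors = FALSE),
                   utils::read.csv(assignment_path, stringsAsFactors = FALSE))
}

#' @rdname read_partition_csv
#' @param partition an `"oa_partition"` object.
#' @param out_dir directory receiving `regions.csv` and `assignment.csv`.
#' @export
write_partition_csv <- function(partition, out_dir) {
  stopifnot(inherits(partition, "oa_partition"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(partition$regions, file.path(out_dir, "regions.csv"),
                   row.names = FALSE)
  utils::write.csv(partition$assignment, file.path(out_dir, "assignment.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

# region id per grid cell (NA when unassigned), matched on rounded centers
region_index <- function(partition, grid) {
  akey <- paste(round(partition$assignment$lat, 6),
                round(partition$assignment$lon, 6))
  gkey <- paste(round(grid$lat, 6), round(grid$lon, 6))
  partition$assignment$region_id[match(gkey, akey)]
}

#' Regionally averaged carbonate state
#'
#' Arithmetic (unweighted) mean of Revelle factor, spCO2 and DIC over all
#' non-missing (month, cell) samples of each region: months and cells are
#' pooled into one sample set, with no month or cell-area weighting. Regions
#' whose cells hold no data are dropped with a warning.
#'
#' @param fields an [ocean_fields()] object.
#' @param partition an [region_partition()] object on the same grid.
#' @return data.frame with columns `region_id`, `rf_mean`, `spco2_mean`,
#'   `dic_mean`, `n_obs` (count of pooled samples with a non-missing Revelle
#'   factor).
#' @export
regional_average <- function(fields, partition) {
  stopifnot(inherits(fields, "oa_fields"), inherits(partition, "oa_partition"))
  reg <- region_index(partition, fields$grid)
  has <- !is.na(reg)
  if (!any(has)) stop("partition assigns no cell of this grid", call. = FALSE)
  ids <- partition$regions$region_id
  f <- factor(reg[has], levels = ids)
  mean_by_region <- function(m) {
    mm <- m[, has, drop = FALSE]
    tot <- rowsum(colSums(mm, na.rm = TRUE), f)[, 1L]
    cnt <- rowsum(colSums(!is.na(mm)), f)[, 1L]
    list(mean = ifelse(cnt > 0, tot / cnt, NA_real_), n = cnt)
  }
  rf <- mean_by_region(fields$rf)
  sp <- mean_by_region(fields$spco2)
  di <- mean_by_region(fields$dic)
  out <- data.frame(region_id = ids,
                    rf_mean = rf$mean, spco2_mean = sp$mean,
                    dic_mean = di$mean, n_obs = rf$n,
                    row.names = NULL)
  empty <- out$n_obs == 0 | !is.finite(out$rf_mean) |
    !is.finite(out$spco2_mean) | !is.finite(out$dic_mean)
  if (any(empty)) {
    warning(sprintf("%d region(s) with no usable samples dropped: %s",
                    sum(empty),
                    paste(utils::head(out$region_id[empty], 5L), collapse = ", ")),
            call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  out
}
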