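# tiny hand-sized fixtures used across the suite; everything built in code

# 1-month, 4-cell ocean grid with explicit values for hand-checkable means
tiny_fields <- function(rf = c(10, 14, 12, 12),
                        spco2 = c(40, 40, 38, 42),
                        ph = c(8.1, 8.1, 8.12, 8.08),
                        dic = c(2.1, 2.1, 2.0, 2.2),
                        months = "m01") {
  grid <- data.frame(lat = c(-1, -1, 1, 1), lon = c(-1, 1, -1, 1),
                     ocean = TRUE)
  as_m <- function(v) matrix(rep(v, length(months)), length(months),
                             length(v), byrow = TRUE)
  ocean_fields(grid, months, as_m(rf), as_m(spco2), as_m(ph), as_m(dic))
}

# two regions over the tiny grid: cells 1-2 south ("eco001"), 3-4 north ("fao01")
tiny_partition <- function(area = c(1, 3)) {
  region_partition(
    regions = data.frame(region_id = c("eco001", "fao01"),
                         region_type = c("ecoregion", "fao"),
                         area_km2 = area),
    assignment = data.frame(lat = c(-1, -1, 1, 1), lon = c(-1, 1, -1, 1),
                            region_id = c("eco001", "eco001", "fao01", "fao01")))
}

# fields whose pH is an exact linear function of spCO2, per region
linear_ph_fields <- function(slopes = c(eco001 = -0.01, fao01 = -0.002),
                             n_months = 6) {
  months <- sprintf("m%02d", seq_len(n_months))
  grid <- data.frame(lat = c(-1, -1, 1, 1), lon = c(-1, 1, -1, 1), ocean = TRUE)
  reg <- c(1, 1, 2, 2)
  spco2 <- outer(seq_len(n_months), c(38, 40, 39, 41), function(m, b) b + 0.5 * m)
  ph <- matrix(NA_real_, n_months, 4)
  for (j in 1:4) ph[, j] <- 8.5 + slopes[reg[j]] * spco2[, j]
  const <- function(v) matrix(v, n_months, 4)
  ocean_fields(grid, months, const(12), spco2, ph, const(2.1))
}

# a small synthetic study set shared by dose-response/SSD tests
small_species_config <- function(...) {
  species_gen_config(n_species = 12, seed = 42, ...)
}

# reduced-size spatial world for property loops
small_world <- function(seed = 1, n_eco = 20, n_fao = 6, resolution = 5,
                        months = 4, ...) {
  part <- generate_regions(n_eco, n_fao, resolution = resolution)
  cfg <- field_gen_config(resolution = resolution, months = months,
                          seed = seed, ...)
  list(partition = part, fields = generate_fields(cfg, part), config = cfg)
}
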