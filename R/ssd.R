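#' Conversion from potentially affected to potentially disappeared fraction
#'
#' Effect factors are computed on the potentially affected fraction (PAF)
#' scale and reported as potentially disappeared fraction (PDF) assuming
#' affected species disappear one-for-one.
#' @export
PAF_TO_PDF <- 1.0

# parse a scope label into a species filter
scope_filter <- function(species, scope) {
  if (identical(scope, "global")) return(rep(TRUE, nrow(species)))
  parts <- strsplit(scope, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) {
    stop(sprintf("scope must be 'global', 'calcification:<level>' or 'region:<zone>', got '%s'",
                 scope), call. = FALSE)
  }
  switch(parts[1L],
    calcification = species$calcification == parts[2L],
    region = vapply(strsplit(species$climate_zones, ";", fixed = TRUE),
                    function(z) parts[2L] %in% z, logical(1L)),
    stop(sprintf("unknown scope kind '%s'", parts[1L]), call. = FALSE))
}

#' Fit a species sensitivity distribution
#'
#' Species are ranked by descending tolerance pH (the species affected at the
#' mildest acidification, i.e. the highest pH, is the most sensitive and
#' ranks first) and given Hazen plotting positions \eqn{(i - 0.5)/n} as the
#' cumulative affected fraction. A logistic curve with a logit link is then
#' fit through the (pH, fraction) points by quasibinomial GLM, giving an
#' affected fraction that falls as pH rises. The free quasibinomial
#' dispersion affects only the reported uncertainty, not the fitted curve.
#'
#' @param species per-species summary from [species_summary()] (columns
#'   `species_id`, `ph50`, `ph10`, `calcification`, `climate_zones`).
#' @param scope `"global"`, `"calcification:<strong|slight|non>"` or
#'   `"region:<tropical|subtropical|temperate|polar>"`. Species carrying
#'   several climate zones enter every matching regional scope.
#' @param basis which per-species threshold builds the curve: `"ph50"` or
#'   `"ph10"`.
#' @param min_species minimum species count required to fit (default 5).
#' @return An object of class `"oa_ssd"`: `points` (pH, proportion),
#'   `intercept`, `slope` (logit scale, slope < 0), `location` (pH of 50
#'   percent affected), `dispersion`, `n_species`, `scope`, `basis`.
#' @export
build_ssd <- function(species, scope = "global", basis = c("ph50", "ph10"),
                      min_species = 5L) {
  basis <- match.arg(basis)
  stopifnot(is.data.frame(species), basis %in% names(species))
  keep <- scope_filter(species, scope)
  vals <- species[[basis]][keep]
  n <- length(vals)
  if (n < min_species) {
    stop(sprintf("scope '%s' has %d species, below the floor of %d",
                 scope, n, min_species), call. = FALSE)
  }
  if (stats::var(vals) == 0) {
    stop(sprintf("scope '%s': all species share one %s value; SSD is degenerate",
                 scope, basis), call. = FALSE)
  }
  ph <- sort(vals, decreasing = TRUE)
  prop <- (seq_len(n) - 0.5) / n
  fit <- stats::glm(prop ~ ph, family = stats::quasibinomial(link = "logit"))
  co <- stats::coef(fit)
  structure(
    list(points = data.frame(ph = ph, proportion = prop),
         intercept = unname(co[1L]), slope = unname(co[2L]),
         location = -unname(co[1L]) / unname(co[2L]),
         dispersion = summary(fit)$dispersion,
         n_species = n, scope = scope, basis = basis),
    class = "oa_ssd"
  )
}

#' @export
print.oa_ssd <- function(x, ...) {
  cat(sprintf("Species sensitivity distribution (%s, basis %s): %d species\n",
              x$scope, x$basis, x$n_species))
  cat(sprintf("  logit slope %.4g/pH, HC50 = %.4f, HC20 = %.4f\n",
              x$slope, hazardous_level(x, 0.5), hazardous_level(x, 0.2)))
  invisible(x)
}

#' @export
predict.oa_ssd <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$points$ph else {
    if (is.data.frame(newdata)) newdata$ph else newdata
  }
  stats::plogis(object$intercept + object$slope * ph)
}

#' @export
plot.oa_ssd <- function(x, ...) {
  ph_grid <- seq(min(x$points$ph) - 0.3, max(x$points$ph) + 0.3, length.out = 200L)
  graphics::plot(x$points$ph, x$points$proportion,
                 xlab = "pH", ylab = "fraction of species affected",
                 xlim = rev(range(ph_grid)), ylim = c(0, 1),
                 main = sprintf("SSD (%s, %s)", x$scope, x$basis), ...)
  graphics::lines(ph_grid, predict(x, ph_grid))
  invisible(x)
}

#' pH at which a given fraction of species is affected
#'
#' Closed-form inverse of the fitted logit curve:
#' \eqn{HC_x = (\mathrm{logit}(x) - a)/b}. Because the affected fraction
#' falls with rising pH (b < 0), milder hazard levels sit at higher pH:
#' HC20 >= HC50 on any fitted curve.
#'
#' @param curve an `"oa_ssd"`.
#' @param x affected fraction in (0, 1), e.g. 0.2 for HC20.
#' @return The hazardous pH level.
#' @export
hazardous_level <- function(curve, x) {
  stopifnot(inherits(curve, "oa_ssd"))
  if (!is.numeric(x) || any(x <= 0) || any(x >= 1)) {
    stop("affected fraction must lie strictly inside (0, 1)", call. = FALSE)
  }
  (stats::qlogis(x) - curve$intercept) / curve$slope
}

#' Effect factor from a hazardous pH level
#'
#' \deqn{EF_x = \frac{x}{pH_{orig} - HC_x}} in PAF per pH unit of departure
#' from the preindustrial reference state, reported on the PDF scale via the
#' one-to-one [PAF_TO_PDF] conversion.
#'
#' @param hc hazardous pH level (e.g. from [hazardous_level()]).
#' @param x affected fraction defining the level (0.20 for EF20, 0.50 for
#'   EF50).
#' @param ph_orig reference-state pH, default 8.19 (preindustrial global
#'   surface mean).
#' @return An object of class `"oa_ef"` with `value` (PDF/pH), `hc`, `x`,
#'   `ph_orig`.
#' @export
effect_factor <- function(hc, x, ph_orig = 8.19) {
  stopifnot(is.numeric(hc), is.numeric(x), x > 0, x < 1)
  if (hc >= ph_orig) {
    stop(sprintf("hazardous level (%.3f) at or above the reference pH (%.3f): non-positive exposure window",
                 hc, ph_orig), call. = FALSE)
  }
  structure(list(value = x / (ph_orig - hc) * PAF_TO_PDF,
                 hc = hc, x = x, ph_orig = ph_orig),
            class = "oa_ef")
}

#' @export
print.oa_ef <- function(x, ...) {
  cat(sprintf("Effect factor EF%d: %.4g PDF/pH (HC = %.4f, reference pH %.2f)\n",
              round(100 * x$x), x$value, x$hc, x$ph_orig))
  invisible(x)
}

#' Full table of effect factors by scope
#'
#' EF20 (from the pH10-based SSD at 20 percent affected) and EF50 (from the
#' pH50-based SSD at 50 percent) for the global scope, each calcification
#' level and each climate zone: 16 factors on a category-complete species
#' set. Scopes with too few species are skipped and listed in the
#' `"skipped"` attribute.
#'
#' @param species per-species summary from [species_summary()].
#' @param ph_orig reference-state pH, default 8.19.
#' @param min_species minimum species per scope (default 5).
#' @return data.frame with columns `scope`, `level` (`"EF20"`/`"EF50"`),
#'   `basis`, `hc`, `value`, `n_species`; attribute `"skipped"` lists scopes
#'   that could not be fit.
#' @export
effect_factor_table <- function(species, ph_orig = 8.19, min_species = 5L) {
  scopes <- c("global",
              paste0("calcification:", c("strong", "slight", "non")),
              paste0("region:", c("tropical", "subtropical", "temperate", "polar")))
  levels <- list(EF20 = list(basis = "ph10", x = 0.20),
                 EF50 = list(basis = "ph50", x = 0.50))
  rows <- list()
  skipped <- character(0)
  for (sc in scopes) {
    for (lv in names(levels)) {
      spec <- levels[[lv]]
      row <- tryCatch({
        curve <- build_ssd(species, scope = sc, basis = spec$basis,
                           min_species = min_species)
        hc <- hazardous_level(curve, spec$x)
        ef <- effect_factor(hc, spec$x, ph_orig)
        data.frame(scope = sc, level = lv, basis = spec$basis,
                   hc = hc, value = ef$value, n_species = curve$n_species)
      }, error = function(e) {
        skipped <<- c(skipped, sprintf("%s/%s: %s", sc, lv, conditionMessage(e)))
        NULL
      })
      rows[[paste(sc, lv)]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(skipped)) {
    warning(sprintf("%d effect factor(s) skipped:\n  %s",
                    length(skipped), paste(skipped, collapse = "\n  ")),
            call. = FALSE)
  }
  attr(out, "skipped") <- skipped
  out
}
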