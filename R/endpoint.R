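#' Endpoint characterization factor per region and substance
#'
#' Extends the midpoint chain to ecosystem damage:
#' \deqn{CF_{end,j,i} = FF_{j,i} \times (-FSF_j) \times EF}
#' in PDF yr per kg emitted. By construction the endpoint CF is the midpoint
#' CF scaled by the effect factor, so the spatial pattern is identical to
#' the midpoint's.
#'
#' @param ff data.frame from [fate_factor()].
#' @param fsf data.frame from [fit_fsf()].
#' @param ef an [effect_factor()] object, or a single PDF/pH value.
#' @param ef_scope label recorded for provenance (default `"global:EF20"`).
#' @return data.frame with columns `region_id`, `substance_id`, `ef_scope`,
#'   `value` (PDF yr/kg).
#' @export
endpoint_cf <- function(ff, fsf, ef, ef_scope = "global:EF20") {
  ef_value <- if (inherits(ef, "oa_ef")) ef$value else ef
  stopifnot(is.numeric(ef_value), length(ef_value) == 1L, is.finite(ef_value))
  mid <- midpoint_cf(ff, fsf)
  data.frame(region_id = mid$region_id,
             substance_id = mid$substance_id,
             ef_scope = ef_scope,
             value = mid$value * ef_value)
}

#' Regional endpoint table with global aggregates
#'
#' One endpoint CF per (region, substance) pair plus an area-weighted global
#' value per substance. A region-to-climate-zone map with zone-specific
#' effect factors is out of the default path; absent one, a single effect
#' factor (the global EF20 by default) applies everywhere.
#'
#' @param ff data.frame of fate factors (all substances stacked).
#' @param fsf data.frame from [fit_fsf()].
#' @param ef an [effect_factor()] or single PDF/pH value.
#' @param partition an [region_partition()] carrying the area weights.
#' @param ef_scope provenance label, default `"global:EF20"`.
#' @return list with `regional` (data.frame of per-region endpoint CFs) and
#'   `global` (named vector, one aggregate per substance, PDF yr/kg).
#' @export
endpoint_table <- function(ff, fsf, ef, partition, ef_scope = "global:EF20") {
  stopifnot(is.data.frame(ff), nrow(ff) > 0L, inherits(partition, "oa_partition"))
  regional <- endpoint_cf(ff, fsf, ef, ef_scope)
  substances <- unique(regional$substance_id)
  global <- vapply(substances, function(s) {
    aggregate_regional(regional[regional$substance_id == s,
                                c("region_id", "value")], partition)
  }, numeric(1L))
  names(global) <- substances
  list(regional = regional, global = global)
}

#' Damage score of an emission inventory entry
#'
#' @param emission_kg emitted mass, kg (>= 0).
#' @param cf a characterization factor value, or a one-row CF data.frame
#'   with a `value` column (midpoint pH yr/kg or endpoint PDF yr/kg).
#' @return emission times CF, in the CF's units times kg (pH yr or PDF yr).
#' @export
impact <- function(emission_kg, cf) {
  if (any(emission_kg < 0)) stop("emission must be non-negative", call. = FALSE)
  value <- if (is.data.frame(cf)) {
    stopifnot("value" %in% names(cf), nrow(cf) == 1L)
    cf$value
  } else cf
  emission_kg * value
}
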