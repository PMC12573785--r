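#' A single species acidification experiment
#'
#' One assay exposing a species to a ladder of lowered-pH treatments and
#' recording a vital trait (growth, calcification, fertilization, bioerosion,
#' ...) against a control. `direction` states how harm shows in the raw
#' response: `"harm_increases_response"` for traits like bioerosion that rise
#' as conditions worsen, `"harm_decreases_response"` for traits like
#' calcification that fall.
#'
#' @param experiment_id,species_id identifiers.
#' @param trait name of the vital function measured.
#' @param direction `"harm_increases_response"` or `"harm_decreases_response"`.
#' @param ph_c,r_c control pH and control response.
#' @param tests data.frame with columns `ph` and `response`, one row per test
#'   condition; test pH values must be distinct.
#' @param calcification `"strong"`, `"slight"` or `"non"`.
#' @param climate_zones character vector, nonempty subset of
#'   `c("tropical", "subtropical", "temperate", "polar")`; a species may span
#'   several zones.
#' @param trophic_level integer 2, 3 or 4 (primary to tertiary consumer).
#' @param n_stressors number of stressors applied (1 = acidification only).
#' @param kingdom taxon kingdom; the screen retains `"animalia"` only.
#' @return An object of class `"oa_experiment"`.
#' @export
experiment_record <- function(experiment_id, species_id, trait, direction,
                              ph_c, r_c, tests,
                              calcification, climate_zones, trophic_level,
                              n_stressors = 1L, kingdom = "animalia") {
  direction <- match.arg(direction,
                         c("harm_increases_response", "harm_decreases_response"))
  stopifnot(is.data.frame(tests), all(c("ph", "response") %in% names(tests)),
            nrow(tests) >= 1L)
  all_ph <- c(ph_c, tests$ph)
  if (any(!is.finite(all_ph)) || any(all_ph < 5) || any(all_ph > 9)) {
    stop("all pH values must be finite and in [5, 9]", call. = FALSE)
  }
  if (anyDuplicated(tests$ph)) {
    stop("test pH values must be distinct", call. = FALSE)
  }
  if (direction == "harm_decreases_response" && !(r_c > 0)) {
    stop("control response must be positive when harm decreases the response",
         call. = FALSE)
  }
  if (!calcification %in% c("strong", "slight", "non")) {
    stop("calcification must be 'strong', 'slight' or 'non'", call. = FALSE)
  }
  zones <- c("tropical", "subtropical", "temperate", "polar")
  if (length(climate_zones) < 1L || !all(climate_zones %in% zones)) {
    stop(sprintf("climate_zones must be a nonempty subset of {%s}",
                 paste(zones, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(experiment_id = experiment_id, species_id = species_id,
         trait = trait, direction = direction,
         ph_c = ph_c, r_c = r_c,
         tests = tests[order(-tests$ph), , drop = FALSE],
         calcification = calcification,
         climate_zones = unique(climate_zones),
         trophic_level = as.integer(trophic_level),
         n_stressors = as.integer(n_stressors),
         kingdom = kingdom),
    class = "oa_experiment"
  )
}

#' Screen an experiment for inclusion
#'
#' Retains single-stressor animal experiments at trophic levels 2-4 with at
#' least three pH test conditions (the two-parameter logistic response needs
#' one residual degree of freedom). Screening reports a reason, it never
#' raises.
#'
#' @param record an [experiment_record()].
#' @return list with logical `accept` and character `reason` (`""` when
#'   accepted).
#' @export
screen_experiment <- function(record) {
  stopifnot(inherits(record, "oa_experiment"))
  if (!identical(tolower(record$kingdom), "animalia")) {
    return(list(accept = FALSE, reason = "kingdom other than animalia"))
  }
  if (record$n_stressors > 1L) {
    return(list(accept = FALSE, reason = "multiple stressors"))
  }
  if (!record$trophic_level %in% 2:4) {
    return(list(accept = FALSE, reason = "trophic level outside 2-4"))
  }
  if (length(unique(record$tests$ph)) < 3L) {
    return(list(accept = FALSE, reason = "insufficient conditions (< 3 test pH levels)"))
  }
  list(accept = TRUE, reason = "")
}

#' Empirical relative response at each test pH
#'
#' Normalizes the raw trait responses against the control:
#' harm-increasing traits use \eqn{eRR_t = 1 - R_c / R_t}, harm-decreasing
#' traits \eqn{eRR_t = 1 - R_t / R_c}. Values can be negative when a species
#' fares better than its control; they are retained, not clipped.
#'
#' @param record an [experiment_record()].
#' @return data.frame with columns `ph` and `err` (the empirical relative
#'   response at that pH).
#' @export
empirical_relative_response <- function(record) {
  stopifnot(inherits(record, "oa_experiment"))
  if (record$direction == "harm_increases_response") {
    if (any(record$tests$response == 0)) {
      stop(sprintf("experiment %s: zero test response with harm-increasing trait",
                   record$experiment_id), call. = FALSE)
    }
    err <- 1 - record$r_c / record$tests$response
  } else {
    if (record$r_c == 0) {
      stop(sprintf("experiment %s: zero control response", record$experiment_id),
           call. = FALSE)
    }
    err <- 1 - record$tests$response / record$r_c
  }
  data.frame(ph = record$tests$ph, err = err)
}

# logistic response: relative effect as pH falls below ph50 (beta > 0)
logistic_crr <- function(ph, ph50, beta) {
  1 / (1 + 10^((ph - ph50) / beta))
}

#' Fit the logistic dose-response curve of one experiment
#'
#' Nonlinear least squares of the calculated relative response
#' \deqn{cRR_t = \frac{1}{1 + 10^{(pH_t - pH_{50})/\beta}}}
#' on the empirical relative responses, with \eqn{\beta > 0} so the effect
#' rises towards 1 as pH falls below \eqn{pH_{50}} and is exactly 0.5 at
#' \eqn{pH_{50}}. Bounds: \eqn{pH_{50} \in [5, 9]}, \eqn{\beta \in (0, 2]}.
#' Fitting runs a bounded Levenberg-Marquardt pass seeded from a coarse grid
#' search; an unidentifiable or failed fit returns `converged = FALSE`
#' rather than raising.
#'
#' @param points data.frame with columns `ph`, `err` (from
#'   [empirical_relative_response()]); at least 3 distinct pH values.
#' @return An object of class `"oa_drc"` with elements `ph50`, `beta`,
#'   `ph10`, `converged`, `residual_sse`, `n`, and the fitted `points`.
#' @export
fit_dose_response <- function(points) {
  stopifnot(is.data.frame(points), all(c("ph", "err") %in% names(points)))
  if (any(!is.finite(points$ph)) || any(!is.finite(points$err))) {
    stop("non-finite dose-response input", call. = FALSE)
  }
  if (length(unique(points$ph)) < 3L) {
    stop("at least 3 distinct pH levels are required", call. = FALSE)
  }
  out <- structure(list(ph50 = NA_real_, beta = NA_real_, ph10 = NA_real_,
                        converged = FALSE, residual_sse = NA_real_,
                        n = nrow(points), points = points),
                   class = "oa_drc")
  if (stats::var(points$err) < 1e-12) return(out)  # flat response: unidentifiable

  sse <- function(p) sum((points$err - logistic_crr(points$ph, p[1L], p[2L]))^2)
  grid <- expand.grid(ph50 = seq(5, 9, by = 0.1),
                      beta = c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.5))
  g_sse <- mapply(function(a, b) sse(c(a, b)), grid$ph50, grid$beta)
  # one start per candidate slope: a single steep start can sit on a flat
  # spot of the objective where the gradient vanishes
  starts <- lapply(split(seq_len(nrow(grid)), grid$beta), function(idx) {
    as.numeric(grid[idx[which.min(g_sse[idx])], ])
  })
  starts <- starts[order(vapply(starts, sse, numeric(1L)))]

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(err ~ 1 / (1 + 10^((ph - ph50) / beta)),
                        data = points,
                        start = list(ph50 = st[1L], beta = st[2L]),
                        lower = c(ph50 = 5, beta = 1e-6),
                        upper = c(ph50 = 9, beta = 2),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      cand <- list(par = unname(p), sse = sum(stats::residuals(fit)^2))
      if (is.null(best) || cand$sse < best$sse) best <- cand
    }
  }
  if (is.null(best)) {
    # derivative-free fallback with a box penalty
    pen <- function(p) {
      if (p[1L] < 5 || p[1L] > 9 || p[2L] < 1e-6 || p[2L] > 2) return(1e6)
      sse(p)
    }
    for (st in starts) {
      opt <- stats::optim(st, pen, method = "Nelder-Mead")
      if (opt$convergence == 0 && opt$value < 1e6 &&
          (is.null(best) || opt$value < best$sse)) {
        best <- list(par = opt$par, sse = opt$value)
      }
    }
  }
  if (!is.null(best)) {
    out$ph50 <- best$par[1L]
    out$beta <- best$par[2L]
    out$residual_sse <- best$sse
    out$converged <- TRUE
    out$ph10 <- ph10_from_fit(out)
  }
  out
}

#' @export
print.oa_drc <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Logistic dose-response fit (n = %d): pH50 = %.4f, beta = %.4f, pH10 = %.4f (SSE %.3g)\n",
                x$n, x$ph50, x$beta, x$ph10, x$residual_sse))
  } else {
    cat(sprintf("Logistic dose-response fit (n = %d): did not converge\n", x$n))
  }
  invisible(x)
}

#' @export
predict.oa_drc <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from an unconverged fit", call. = FALSE)
  ph <- if (is.null(newdata)) object$points$ph else {
    if (is.data.frame(newdata)) newdata$ph else newdata
  }
  logistic_crr(ph, object$ph50, object$beta)
}

#' @export
residuals.oa_drc <- function(object, ...) {
  if (!object$converged) stop("no residuals for an unconverged fit", call. = FALSE)
  object$points$err - predict(object)
}

#' pH of a 10 percent trait reduction
#'
#' Closed form from the fitted parameters:
#' \deqn{pH_{10} = \beta \log_{10} 9 + pH_{50}}
#' (at \eqn{pH_{10}} the logistic equals 0.10 exactly; the constant 9 is
#' \eqn{(1 - 0.1)/0.1}). With \eqn{\beta > 0} this lies above \eqn{pH_{50}}:
#' a 10 percent effect is reached at milder acidification.
#'
#' @param fit a converged `"oa_drc"`.
#' @return The pH at which the fitted effect is 10 percent.
#' @export
ph10_from_fit <- function(fit) {
  stopifnot(inherits(fit, "oa_drc"))
  if (!isTRUE(fit$converged)) {
    stop("cannot derive pH10 from an unconverged fit", call. = FALSE)
  }
  fit$beta * log10(9) + fit$ph50
}

#' Per-species sensitivity summary
#'
#' One (pH50, pH10) pair per species: the arithmetic mean over that species'
#' converged experiment fits, carrying the species' calcification level,
#' climate zones (union over experiments) and trophic level. Species with no
#' converged fit are dropped with a warning.
#'
#' @param fits list of `"oa_drc"` objects, parallel to `records`.
#' @param records list of [experiment_record()] objects.
#' @return data.frame with columns `species_id`, `ph50`, `ph10`,
#'   `calcification`, `climate_zones` (semicolon-joined), `trophic_level`,
#'   `n_experiments`.
#' @export
species_summary <- function(fits, records) {
  stopifnot(length(fits) == length(records))
  rows <- mapply(function(f, r) {
    if (!inherits(f, "oa_drc") || !isTRUE(f$converged)) return(NULL)
    data.frame(species_id = r$species_id, ph50 = f$ph50, ph10 = f$ph10,
               calcification = r$calcification,
               climate_zones = paste(r$climate_zones, collapse = ";"),
               trophic_level = r$trophic_level)
  }, fits, records, SIMPLIFY = FALSE)
  all_species <- unique(vapply(records, `[[`, "", "species_id"))
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0L) {
    stop("no converged fits to summarize", call. = FALSE)
  }
  dropped <- setdiff(all_species, df$species_id)
  if (length(dropped)) {
    warning(sprintf("%d species with no converged fit dropped: %s",
                    length(dropped),
                    paste(utils::head(dropped, 5L), collapse = ", ")),
            call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(df, df$species_id), function(d) {
    zones <- unique(unlist(strsplit(d$climate_zones, ";", fixed = TRUE)))
    data.frame(species_id = d$species_id[1L],
               ph50 = mean(d$ph50), ph10 = mean(d$ph10),
               calcification = d$calcification[1L],
               climate_zones = paste(zones, collapse = ";"),
               trophic_level = d$trophic_level[1L],
               n_experiments = nrow(d))
  }))
  rownames(out) <- NULL
  out
}

#' Read / write species experiments as long-format CSV
#'
#' One row per test condition with the experiment-level fields repeated:
#' columns `experiment_id, species_id, trait, direction, ph_c, r_c, ph_t,
#' r_t, calcification, climate_zones` (semicolon-separated), `trophic_level,
#' n_stressors, kingdom`.
#'
#' @param path file path.
#' @return `read_experiments_csv()` returns a list of [experiment_record()]
#'   objects.
#' @export
read_experiments_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$experiment_id), function(d) {
    experiment_record(
      experiment_id = d$experiment_id[1L], species_id = d$species_id[1L],
      trait = d$trait[1L], direction = d$direction[1L],
      ph_c = d$ph_c[1L], r_c = d$r_c[1L],
      tests = data.frame(ph = d$ph_t, response = d$r_t),
      calcification = d$calcification[1L],
      climate_zones = strsplit(d$climate_zones[1L], ";", fixed = TRUE)[[1L]],
      trophic_level = d$trophic_level[1L],
      n_stressors = d$n_stressors[1L], kingdom = d$kingdom[1L])
  })
}

#' @rdname read_experiments_csv
#' @param records list of [experiment_record()] objects.
#' @export
write_experiments_csv <- function(records, path) {
  long <- do.call(rbind, lapply(records, function(r) {
    data.frame(experiment_id = r$experiment_id, species_id = r$species_id,
               trait = r$trait, direction = r$direction,
               ph_c = r$ph_c, r_c = r$r_c,
               ph_t = r$tests$ph, r_t = r$tests$response,
               calcification = r$calcification,
               climate_zones = paste(r$climate_zones, collapse = ";"),
               trophic_level = r$trophic_level,
               n_stressors = r$n_stressors, kingdom = r$kingdom)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
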