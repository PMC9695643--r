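#' Apoptosis temperature band
#'
#' Temperature window treated as inducing programmed cell death: 43-50 degC
#' by default. Membership is half-open, `[lower, upper)`: a voxel at
#' exactly the upper bound counts as necrotic, not apoptotic.
#'
#' @param lower,upper band limits, degC (`lower < upper`).
#' @return An object of class `apoptosis_band`.
#' @export
apoptosis_band <- function(lower = 43, upper = 50) {
  if (!(lower < upper)) stop("lower must be below upper", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "apoptosis_band")
}

#' Thermal-hazard band weighting
#'
#' Named, versioned weighting of temperature bands over normal tissue:
#' weight 0 below the first breakpoint, then `weights[k]` on
#' `[breaks[k], breaks[k + 1])` (the last band is unbounded above). The
#' default scheme weights the apoptosis band 1 and the necrosis range 2; it
#' is a declared stand-in and can be swapped without code change.
#'
#' @param breaks strictly increasing temperature breakpoints, degC.
#' @param weights non-negative weight per band (same length as `breaks`).
#' @param name scheme label carried into provenance.
#' @return An object of class `hazard_weighting`.
#' @export
hazard_weighting <- function(breaks = c(43, 50), weights = c(1, 2),
                             name = "band-stand-in-v1") {
  stopifnot(length(breaks) == length(weights), length(breaks) >= 1,
            !is.unsorted(breaks, strictly = TRUE), all(weights >= 0))
  structure(list(breaks = breaks, weights = weights, name = name),
            class = "hazard_weighting")
}

#' Instantaneous apoptosis ratio
#'
#' Fraction of the tumor volume whose temperature lies inside the apoptosis
#' band: in-band tumor voxels / total tumor voxels. Lies in `[0, 1]` and is
#' invariant under relabeling of voxels within the mask.
#'
#' @param temp temperature array, degC.
#' @param tumor_mask logical array (non-empty) selecting tumor voxels.
#' @param band an [apoptosis_band()].
#' @return scalar in `[0, 1]`.
#' @export
apoptosis_ratio <- function(temp, tumor_mask, band = apoptosis_band()) {
  if (!any(tumor_mask)) stop("tumor mask is empty", call. = FALSE)
  tt <- temp[tumor_mask]
  mean(tt >= band$lower & tt < band$upper)
}

#' Instantaneous thermal hazard value
#'
#' Band-weighted fraction of the normal-tissue volume:
#' `sum(weight(T) * V) / (total normal volume)` with the weights of a
#' [hazard_weighting()]. Zero when all normal tissue is below the first
#' breakpoint; monotone non-decreasing under pointwise heating.
#'
#' @param temp temperature array, degC.
#' @param normal_mask logical array (non-empty) selecting normal-tissue
#'   voxels.
#' @param weighting a [hazard_weighting()].
#' @return non-negative scalar.
#' @export
thermal_hazard <- function(temp, normal_mask, weighting = hazard_weighting()) {
  if (!any(normal_mask)) stop("normal mask is empty", call. = FALSE)
  tn <- temp[normal_mask]
  w <- c(0, weighting$weights)[findInterval(tn, weighting$breaks) + 1]
  mean(w)
}

#' Time-averaged retention of a metric trace
#'
#' Time-weighted mean by trapezoidal integration over the snapshot times,
#' divided by the spanned interval.
#'
#' @param times snapshot times, s (strictly increasing, >= 2 unless the
#'   series is constant-with-one-sample).
#' @param values metric values at `times`.
#' @return scalar time average.
#' @export
retention_average <- function(times, values) {
  n <- length(times)
  if (n == 0 || length(values) != n)
    stop("times and values must be non-empty and matched", call. = FALSE)
  if (n == 1) return(values)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  sum(diff(times) * (utils::head(values, -1) + utils::tail(values, -1)) / 2) /
    (times[n] - times[1])
}

#' Effective apoptosis retention ratio
#'
#' Ratio of the time-averaged apoptosis retention to the time-averaged
#' thermal hazard, `thetaA* / max(thetaH*, eps)`. The guard `eps` keeps the
#' objective finite when no normal tissue is ever harmed.
#'
#' @param theta_a_star time-averaged apoptosis retention, in `[0, 1]`.
#' @param theta_h_star time-averaged thermal hazard (>= 0).
#' @param eps hazard floor (default 1e-3).
#' @return non-negative scalar (vectorized over its first two arguments).
#' @export
effective_ratio <- function(theta_a_star, theta_h_star, eps = 1e-3) {
  if (any(theta_a_star < 0) || any(theta_a_star > 1) || any(theta_h_star < 0))
    stop("theta_a_star must lie in [0, 1] and theta_h_star be >= 0",
         call. = FALSE)
  theta_a_star / pmax(theta_h_star, eps)
}

#' Dose metrics for a temperature series
#'
#' Evaluates the instantaneous apoptosis ratio over the tumor and the
#' thermal hazard over normal tissue at every stored snapshot, and their
#' time averages and effective ratio.
#'
#' @param series a `temperature_series` with stored fields
#'   ([run_treatment()] with `keep_fields = TRUE`, or
#'   [synth_temperature_series()]).
#' @param phantom the matching [build_phantom()] result (masks).
#' @param band an [apoptosis_band()].
#' @param weighting a [hazard_weighting()].
#' @param eps hazard floor for [effective_ratio()].
#' @return A tibble of class `metric_series` with columns `time_s`,
#'   `theta_A`, `theta_H`; the scalars are attributes and in [glance()].
#' @export
treatment_metrics <- function(series, phantom, band = apoptosis_band(),
                              weighting = hazard_weighting(), eps = 1e-3) {
  stopifnot(inherits(series, "temperature_series"),
            inherits(phantom, "tissue_phantom"))
  if (is.null(series$fields))
    stop("series has no stored fields; rerun with keep_fields = TRUE",
         call. = FALSE)
  th_a <- vapply(series$fields, apoptosis_ratio, numeric(1),
                 tumor_mask = phantom$tumor_mask, band = band)
  th_h <- vapply(series$fields, thermal_hazard, numeric(1),
                 normal_mask = phantom$normal_mask, weighting = weighting)
  a_star <- retention_average(series$times, th_a)
  h_star <- retention_average(series$times, th_h)
  out <- tibble::tibble(time_s = series$times, theta_A = th_a, theta_H = th_h)
  structure(out,
            class = c("metric_series", class(out)),
            theta_A_star = a_star, theta_H_star = h_star,
            theta_eff_star = effective_ratio(a_star, h_star, eps),
            eps = eps, weighting = weighting$name)
}

#' @export
glance.metric_series <- function(x, ...) {
  tibble::tibble(
    theta_A_star = attr(x, "theta_A_star"),
    theta_H_star = attr(x, "theta_H_star"),
    theta_eff_star = attr(x, "theta_eff_star"),
    hazard_weighting = attr(x, "weighting")
  )
}

#' Export a metric series as CSV plus JSON summary
#'
#' Writes the per-snapshot traces (`time_s`, `thetaA`, `thetaH`) to CSV
#' and, if `json_path` is given, the scalar summaries and condition
#' parameters as JSON.
#'
#' @param metrics a [treatment_metrics()] result.
#' @param path CSV output path.
#' @param json_path optional JSON summary path.
#' @param condition optional named list of condition parameters to embed.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path, json_path = NULL, condition = NULL) {
  stopifnot(inherits(metrics, "metric_series"))
  df <- data.frame(time_s = metrics$time_s, thetaA = metrics$theta_A,
                   thetaH = metrics$theta_H)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      c(list(thetaA_star = attr(metrics, "theta_A_star"),
             thetaH_star = attr(metrics, "theta_H_star"),
             thetaEff_star = attr(metrics, "theta_eff_star"),
             hazard_weighting = attr(metrics, "weighting")),
        condition),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
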