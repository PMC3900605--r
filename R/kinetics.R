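#' Adsorption rate constant from a free-phage decay series
#'
#' Under first-order adsorption to a fixed host density B, free phage decay as
#' `P(t) = P0 * exp(-k * B * t)`, so each later time point yields an estimate
#' `k = (2.303 / (B * t)) * log10(P0 / P(t))`. These per-time estimates are
#' averaged over the initial monotone-decay window (the leading stretch of
#' time points whose mean titre keeps decreasing; points after the decay stalls
#' are excluded, as usual when free phage reach a background plateau), first
#' within each replicate and then across replicates.
#'
#' @param series a `titer_series` tibble (columns `time_min`, `replicate`,
#'   `pfu_per_ml`) with a time-zero row per replicate, or any tibble with those
#'   columns.
#' @param host_density host cells per ml (B).
#' @return a `kinetics_fit` list: `k` (ml/min), `per_replicate` tibble,
#'   `per_timepoint` tibble (columns `time_min`, `replicate`, `k`),
#'   `host_density`, `window_end` (last time in the decay window).
#' @examples
#' s <- simulate_titer_series(
#'   "adsorption",
#'   params = list(k = 6.4e-9, cell_density = 3e8, cv = 0),
#'   design = list(times = 0:10, replicates = 2), seed = 1
#' )
#' adsorption_rate(s, host_density = 3e8)$k
#' @export
adsorption_rate <- function(series, host_density) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("time_min", "replicate", "pfu_per_ml") %in% names(series)),
            host_density > 0)
  means <- series |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(mean_pfu = mean(.data$pfu_per_ml), .groups = "drop") |>
    dplyr::arrange(.data$time_min)
  if (nrow(means) < 2 || min(means$time_min) != 0) {
    stop("series needs a time-zero point and at least one later time",
         call. = FALSE)
  }
  decreasing <- diff(means$mean_pfu) < 0
  if (!decreasing[1]) stop("no adsorption detected: titre does not decay",
                           call. = FALSE)
  n_window <- which(!c(decreasing, FALSE))[1]  # last index of the decay run
  window_end <- means$time_min[n_window]
  window_times <- means$time_min[means$time_min > 0 &
                                   means$time_min <= window_end]

  per_tp <- series |>
    dplyr::group_by(.data$replicate) |>
    dplyr::mutate(p0 = .data$pfu_per_ml[.data$time_min == 0][1]) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$time_min %in% window_times) |>
    dplyr::mutate(k = (2.303 / (host_density * .data$time_min)) *
                    log10(.data$p0 / .data$pfu_per_ml)) |>
    dplyr::select("time_min", "replicate", "k")

  per_rep <- per_tp |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(k = mean(.data$k), n_timepoints = dplyr::n(),
                     .groups = "drop")

  structure(
    list(k = mean(per_rep$k), per_replicate = per_rep, per_timepoint = per_tp,
         host_density = host_density, window_end = window_end),
    class = "kinetics_fit"
  )
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit> adsorption k = ", format(x$k, digits = 3),
      " ml/min (B = ", format(x$host_density), ", window 0-",
      x$window_end, " min, ", nrow(x$per_replicate), " replicates)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.kinetics_fit <- function(x, ...) x$per_replicate

#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble::tibble(k = x$k,
                 k_sd = stats::sd(x$per_replicate$k),
                 n_replicates = nrow(x$per_replicate),
                 host_density = x$host_density,
                 window_end_min = x$window_end)
}

#' One-step growth curve analysis
#'
#' Extracts latent period, burst size and (when a chloroform-treated series is
#' supplied) eclipse period from one-step growth data. The baseline titre is
#' the mean over the pre-rise time points; the latent period is the first time
#' at which the mean titre exceeds `rise_factor` times baseline; the plateau
#' begins when the relative change between successive mean titres drops below
#' `plateau_tol` after the rise; burst size is the plateau mean divided by the
#' baseline. The chloroform series (total intracellular plus free phage)
#' yields the eclipse period the same way, and eclipse <= latent is enforced.
#' If the titre is still rising at the last time point, the plateau is taken
#' at the final point and the fit is flagged `censored`.
#'
#' @param series a `titer_series` from the one-step design, or a tibble with
#'   columns `time_min`, `replicate`, `pfu_per_ml` and optionally `treatment`
#'   (`"untreated"` / `"chloroform"`).
#' @param treated optional separate chloroform-treated tibble with the same
#'   columns; ignored when `series` already carries a `treatment` column with
#'   both levels.
#' @param rise_factor fold-increase over baseline that marks the end of the
#'   latent (or eclipse) period (default 3).
#' @param plateau_tol relative change between successive means below which the
#'   curve is called flat (default 0.1).
#' @return a `growth_fit` list: `latent_min`, `eclipse_min` (NA without a
#'   treated series), `burst_size`, `baseline_pfu`, `plateau_pfu`,
#'   `plateau_start_min`, `censored`, `means` tibble.
#' @export
one_step_analysis <- function(series, treated = NULL, rise_factor = 3,
                              plateau_tol = 0.1) {
  series <- tibble::as_tibble(series)
  stopifnot(all(c("time_min", "replicate", "pfu_per_ml") %in% names(series)),
            rise_factor > 1, plateau_tol > 0)
  if ("treatment" %in% names(series) && is.null(treated)) {
    treated <- dplyr::filter(series, .data$treatment == "chloroform")
    series <- dplyr::filter(series, .data$treatment != "chloroform")
    if (nrow(treated) == 0) treated <- NULL
  }
  main <- fit_step_curve(series, rise_factor, plateau_tol)

  eclipse <- NA_real_
  if (!is.null(treated) && nrow(tibble::as_tibble(treated))) {
    ecl_fit <- fit_step_curve(tibble::as_tibble(treated), rise_factor,
                              plateau_tol)
    # intracellular phage appear before release: eclipse cannot exceed latent
    eclipse <- min(ecl_fit$rise_time, main$rise_time)
  }

  structure(
    list(
      latent_min = main$rise_time,
      eclipse_min = eclipse,
      burst_size = main$plateau / main$baseline,
      baseline_pfu = main$baseline,
      plateau_pfu = main$plateau,
      plateau_start_min = main$plateau_start,
      censored = main$censored,
      means = main$means
    ),
    class = "growth_fit"
  )
}

fit_step_curve <- function(tbl, rise_factor, plateau_tol) {
  means <- tbl |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(mean_pfu = mean(.data$pfu_per_ml), .groups = "drop") |>
    dplyr::arrange(.data$time_min)
  if (nrow(means) < 3) stop("need at least 3 time points", call. = FALSE)

  risen <- which(means$mean_pfu > rise_factor * means$mean_pfu[1])
  if (!length(risen)) {
    stop("no rise detected: titre never exceeds ", rise_factor,
         "x the initial value", call. = FALSE)
  }
  rise_idx <- risen[1]
  baseline <- mean(means$mean_pfu[seq_len(rise_idx - 1)])
  rise_time <- means$time_min[rise_idx]

  rel_change <- abs(diff(means$mean_pfu)) / utils::head(means$mean_pfu, -1)
  flat <- which(rel_change < plateau_tol & seq_along(rel_change) >= rise_idx)
  censored <- length(flat) == 0
  plateau_idx <- if (censored) nrow(means) else flat[1] + 1L
  plateau <- mean(means$mean_pfu[plateau_idx:nrow(means)])

  list(baseline = baseline, rise_time = rise_time, plateau = plateau,
       plateau_start = means$time_min[plateau_idx], censored = censored,
       means = means)
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> latent ", x$latent_min, " min",
      if (!is.na(x$eclipse_min)) paste0(", eclipse ", x$eclipse_min, " min"),
      ", burst size ", round(x$burst_size, 1),
      if (x$censored) " [censored: no plateau reached]", "\n", sep = "")
  invisible(x)
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(latent_min = x$latent_min, eclipse_min = x$eclipse_min,
                 burst_size = x$burst_size, baseline_pfu = x$baseline_pfu,
                 plateau_pfu = x$plateau_pfu,
                 plateau_start_min = x$plateau_start_min,
                 censored = x$censored)
}

#' @export
tidy.growth_fit <- function(x, ...) x$means
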