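#' Simulate phage titre series (adsorption decay and one-step growth)
#'
#' `kind = "adsorption"` models free-phage loss to adsorption on host cells at
#' density `cell_density`: `P(t) = p0 * exp(-k * B * t)`, sampled at the design
#' time points with multiplicative lognormal noise of a given coefficient of
#' variation. `kind = "one_step"` models a synchronized one-step growth
#' experiment: the plated total count stays at the initial number of infective
#' centres until the latent period, then rises (by default as a step) to a
#' plateau of `burst x initial`; the chloroform-treated series, which releases
#' intracellular mature phage, rises at the eclipse period instead. Noise is
#' unbiased on the mean (`E[pfu] = model value`).
#'
#' The defaults reproduce a typical adsorption design (host at ~3e8 CFU/ml,
#' multiplicity of infection 0.01, samples every minute for 10 min) and
#' one-step design (multiplicity 0.001, two samples every 10 min for 80 min,
#' four replicates).
#'
#' @param kind `"adsorption"` or `"one_step"`.
#' @param params named list overriding the model parameters:
#'   * adsorption: `k` (ml/min), `cell_density` (CFU/ml), `moi`, `p0`
#'     (PFU/ml, default `moi * cell_density`), `cv`;
#'   * one_step: `initial` (infective centres/ml), `burst`, `latent_min`,
#'     `eclipse_min`, `rise_duration_min`, `cv`.
#' @param design named list: `times` (minutes) and `replicates`.
#' @param seed random seed; fixed seed gives byte-identical series.
#'
#' @return a `titer_series` tibble with columns `time_min`, `replicate`,
#'   `treatment` (`"free"`, or `"total"`/`"chloroform"`), `pfu_per_ml`, with
#'   the generating parameters attached as attributes `params` and `design`.
#' @examples
#' ts <- simulate_titer_series("adsorption", params = list(cv = 0), seed = 1)
#' head(ts)
#' @export
simulate_titer_series <- function(kind = c("adsorption", "one_step"),
                                  params = list(), design = list(),
                                  seed = NULL) {
  kind <- match.arg(kind)
  if (kind == "adsorption") {
    p <- utils::modifyList(
      list(k = 6.44e-9, cell_density = 3e8, moi = 0.01, p0 = NULL, cv = 0.1),
      params)
    if (is.null(p$p0)) p$p0 <- p$moi * p$cell_density
    d <- utils::modifyList(list(times = 0:10, replicates = 4), design)
    check_positive(p[c("k", "cell_density", "p0")])
    if (p$cv < 0) stop("cv must be non-negative", call. = FALSE)
    series <- with_seed(seed, {
      grid <- tidyr::expand_grid(replicate = seq_len(d$replicates),
                                 time_min = d$times)
      mu <- p$p0 * exp(-p$k * p$cell_density * grid$time_min)
      grid |>
        dplyr::mutate(treatment = "free",
                      pfu_per_ml = lognoise(mu, p$cv)) |>
        dplyr::select("time_min", "replicate", "treatment", "pfu_per_ml")
    })
  } else {
    p <- utils::modifyList(
      list(initial = 3e5, burst = 153, latent_min = 35, eclipse_min = 25,
           rise_duration_min = 0, cv = 0.1),
      params)
    d <- utils::modifyList(list(times = seq(0, 80, by = 10), replicates = 4),
                           design)
    check_positive(p[c("initial", "burst")])
    if (p$eclipse_min > p$latent_min) {
      stop("eclipse_min must not exceed latent_min", call. = FALSE)
    }
    if (p$cv < 0 || p$latent_min < 0 || p$eclipse_min < 0 ||
        p$rise_duration_min < 0) {
      stop("negative parameters are not allowed", call. = FALSE)
    }
    step_curve <- function(t, onset) {
      frac <- pmin(pmax((t - onset) / max(p$rise_duration_min, 1e-9), 0), 1)
      frac[t >= onset & p$rise_duration_min == 0] <- 1
      p$initial * (1 + frac * (p$burst - 1))
    }
    series <- with_seed(seed, {
      grid <- tidyr::expand_grid(replicate = seq_len(d$replicates),
                                 time_min = d$times,
                                 treatment = c("total", "chloroform"))
      onset <- ifelse(grid$treatment == "total", p$latent_min, p$eclipse_min)
      mu <- step_curve(grid$time_min, onset)
      grid |>
        dplyr::mutate(pfu_per_ml = lognoise(mu, p$cv)) |>
        dplyr::select("time_min", "replicate", "treatment", "pfu_per_ml")
    })
  }
  attr(series, "params") <- p
  attr(series, "design") <- d
  class(series) <- c("titer_series", class(series))
  series
}

# multiplicative lognormal noise with E[x] = mu and sd(x)/mean(x) = cv
lognoise <- function(mu, cv) {
  if (cv == 0) return(mu)
  sigma <- sqrt(log(1 + cv^2))
  mu * exp(stats::rnorm(length(mu), -sigma^2 / 2, sigma))
}

check_positive <- function(lst) {
  bad <- names(lst)[vapply(lst, function(v) !is.numeric(v) || v <= 0,
                           logical(1))]
  if (length(bad)) {
    stop("parameters must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
}
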