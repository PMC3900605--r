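#' @export
tidy.phage_community <- function(x, ...) x$groups

#' @export
tidy.collapsed_assembly <- function(x, ...) x$coverage

#' @export
glance.ltr_call <- function(x, ...) {
  tibble::tibble(
    detected = x$detected,
    start = if (x$detected) x$start else NA_integer_,
    end = if (x$detected) x$end else NA_integer_,
    length = if (x$detected) x$length else NA_integer_,
    coverage_ratio = if (x$detected) x$coverage_ratio else NA_real_,
    n_segments = x$n_segments
  )
}

#' @export
tidy.fr_layout <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.fr_layout <- function(x, ...) {
  energy <- attr(x, "energy")
  tibble::tibble(
    n_nodes = nrow(x),
    iterations = attr(x, "iterations"),
    energy_initial = energy[1],
    energy_final = energy[length(energy)]
  )
}
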