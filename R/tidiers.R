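# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fraction matrix
#'
#' @param x A `bc_fractions` object.
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `fraction`.
#' @export
tidy.bc_fractions <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarise a fraction matrix
#'
#' @param x A `bc_fractions` object.
#' @param ... Unused.
#' @return One-row tibble: `L`, `total_weight`, `max_deviation`,
#'   `rms_deviation` (deviations from the ideal fraction 0.25).
#' @export
glance.bc_fractions <- function(x, ...) {
  dev <- abs(x$fraction - 0.25)
  tibble::tibble(
    L = attr(x, "L"),
    total_weight = attr(x, "total_weight"),
    max_deviation = max(dev),
    rms_deviation = sqrt(mean(dev^2))
  )
}

#' Tidy a balance verdict
#'
#' @param x A `bc_verdict`.
#' @param ... Unused.
#' @return Per-position tibble with columns `position`, `status`.
#' @export
tidy.bc_verdict <- function(x, ...) {
  x$per_position
}

#' Summarise a balance verdict
#'
#' @param x A `bc_verdict`.
#' @param ... Unused.
#' @return One-row tibble: `criterion`, `pass`, `n_inside`, `n_border`,
#'   `n_outside`, `max_outside`, `max_deviation`.
#' @export
glance.bc_verdict <- function(x, ...) {
  tibble::tibble(
    criterion = x$criterion$name,
    pass = x$pass,
    n_inside = x$n_inside,
    n_border = x$n_border,
    n_outside = x$n_outside,
    max_outside = x$criterion$max_outside,
    max_deviation = x$max_deviation
  )
}

#' Tidy a distance matrix
#'
#' @param x A `bc_distmat`.
#' @param ... Unused.
#' @return Tibble of distinct pairs: `id1`, `id2`, `distance`.
#' @export
tidy.bc_distmat <- function(x, ...) {
  w <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    id1 = x$ids[w[, 1]],
    id2 = x$ids[w[, 2]],
    distance = as.integer(x$d[w])
  )
}

#' Summarise a distance matrix
#'
#' @param x A `bc_distmat`.
#' @param ... Unused.
#' @return One-row tibble: `n_barcodes`, `d_min`, `d_max`.
#' @export
glance.bc_distmat <- function(x, ...) {
  tibble::tibble(
    n_barcodes = length(x$ids),
    d_min = x$d_min,
    d_max = x$d_max
  )
}

#' Tidy a set-completion result
#'
#' @param x A `bc_selection`.
#' @param ... Unused.
#' @return The ranked candidate tibble.
#' @export
tidy.bc_selection <- function(x, ...) {
  x$candidates
}

#' Summarise a set-completion result
#'
#' @param x A `bc_selection`.
#' @param ... Unused.
#' @return One-row tibble: `exhaustive`, `n_evaluated`, `n_passing`.
#' @export
glance.bc_selection <- function(x, ...) {
  tibble::tibble(
    exhaustive = x$exhaustive,
    n_evaluated = x$n_evaluated,
    n_passing = nrow(x$candidates)
  )
}
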