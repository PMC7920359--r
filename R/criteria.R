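# Balance criteria: corridors around the ideal per-position nucleotide
# fraction of 0.25. A position whose fractions stay inside the corridor
# reads cleanly; excursions degrade the per-cycle signal-to-noise
# separation the basecaller relies on. Two named corridors ship as
# defaults: "strong", modelled on vendor-approved sets, and "lite", the
# wider tolerance observed across real runs. Both are configuration, not
# constants: users with a vendor panel should regenerate the strong
# corridor with derive_corridor_from_sets().

#' Define a balance criterion
#'
#' A criterion is a fraction corridor `[lower, upper]` around 0.25, a
#' border tolerance defining "on the border" of the corridor (exact float
#' equality being meaningless), and the number of positions allowed
#' outside the corridor before the set fails. By default no position may
#' fall outside: beyond set imbalance there are other causes of misread
#' cycles, so headroom is not spent in advance. An expert cap of up to 2
#' violating positions is tolerated by the method's accounting.
#'
#' @param name Criterion label: `"strong"`, `"lite"`, or `"custom"`.
#' @param lower,upper Corridor bounds with `lower <= 0.25 <= upper`.
#' @param border_tol Half-width of the border band at each bound;
#'   non-negative and at most `(upper - lower) / 2`.
#' @param max_outside Number of outside positions allowed before failure.
#' @return A `bc_criterion` object.
#' @examples
#' criterion("custom", lower = 0.2, upper = 0.3)
#' @export
criterion <- function(name = "custom", lower = 0.15, upper = 0.35,
                      border_tol = 0.01, max_outside = 0) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  border_tol <- as.numeric(border_tol)
  max_outside <- as.integer(max_outside)
  if (is.na(lower) || is.na(upper) || lower < 0 || upper > 1 ||
      lower > 0.25 || upper < 0.25) {
    abort_validation("corridor must satisfy 0 <= lower <= 0.25 <= upper <= 1")
  }
  if (is.na(border_tol) || border_tol < 0) {
    abort_validation("`border_tol` must be non-negative")
  }
  half <- (upper - lower) / 2
  if (border_tol > half) border_tol <- half # degenerate/narrow corridors
  if (is.na(max_outside) || max_outside < 0) {
    abort_validation("`max_outside` must be a non-negative integer")
  }
  structure(
    list(
      name = as.character(name), lower = lower, upper = upper,
      border_tol = border_tol, max_outside = max_outside
    ),
    class = "bc_criterion"
  )
}

#' Default strong and lite criteria
#'
#' The strong corridor reflects the tight balance of vendor-approved
#' sets; the lite corridor the wider excursions that real runs tolerate
#' without a per-cycle quality drop. The published method draws these
#' bounds graphically rather than numerically, so the values here are
#' package defaults chosen to preserve the corridor-plus-violation-cap
#' logic; regenerate the strong corridor from reference sets with
#' [derive_corridor_from_sets()] when a vendor panel is available, or
#' override any field via [criterion()] / [read_criterion()].
#'
#' @param max_outside Violation cap applied to both criteria (default 0;
#'   expert use up to 2).
#' @return Named list with elements `strong` and `lite`.
#' @export
default_criteria <- function(max_outside = 0) {
  list(
    strong = criterion("strong", 0.15, 0.35, 0.01, max_outside),
    lite   = criterion("lite", 0.05, 0.45, 0.01, max_outside)
  )
}

#' Read / write a criterion configuration (YAML)
#'
#' The YAML block carries keys `name`, `lower`, `upper`, `border_tol`,
#' `max_outside`; missing keys take the [criterion()] defaults.
#' @param path YAML file path.
#' @return `read_criterion()`: a `bc_criterion`. `write_criterion()`:
#'   `path`, invisibly. Writing then reading restores an equal criterion.
#' @export
read_criterion <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) abort_validation(sprintf("%s: not a criterion config", path))
  criterion(
    name = cfg$name %||% "custom",
    lower = cfg$lower %||% formals(criterion)$lower,
    upper = cfg$upper %||% formals(criterion)$upper,
    border_tol = cfg$border_tol %||% formals(criterion)$border_tol,
    max_outside = cfg$max_outside %||% formals(criterion)$max_outside
  )
}

#' @rdname read_criterion
#' @param crit A `bc_criterion`.
#' @export
write_criterion <- function(crit, path) {
  stopifnot(inherits(crit, "bc_criterion"))
  yaml::write_yaml(unclass(crit), path)
  invisible(path)
}

#' Derive a corridor from reference sets
#'
#' The data-driven route to a strong criterion: the corridor is the
#' `[min, max]` envelope of every per-position fraction across a list of
#' reference sets known to sequence well (e.g. the vendor's pre-approved
#' sets at equal proportions). Border tolerance and violation cap are
#' taken from arguments, defaulting to the shipped values. A perfectly
#' balanced reference yields the degenerate corridor `[0.25, 0.25]`
#' (with `border_tol` clamped to 0).
#'
#' @param reference_sets A list of `bc_set` objects (a single set is
#'   promoted to a list).
#' @param panel The `bc_panel` the sets reference.
#' @param name,border_tol,max_outside Passed to [criterion()].
#' @return A `bc_criterion`.
#' @export
derive_corridor_from_sets <- function(reference_sets, panel, name = "derived",
                                      border_tol = 0.01, max_outside = 0) {
  if (inherits(reference_sets, "bc_set") || is.data.frame(reference_sets)) {
    reference_sets <- list(reference_sets)
  }
  if (length(reference_sets) == 0) {
    abort_validation("`reference_sets` must contain at least one set")
  }
  vals <- unlist(lapply(reference_sets, function(s) {
    compute_fraction_matrix(s, panel)$fraction
  }))
  criterion(name, lower = min(vals), upper = max(vals),
            border_tol = border_tol, max_outside = max_outside)
}

#' @export
print.bc_criterion <- function(x, ...) {
  cat(sprintf(
    "<criterion '%s'> corridor [%.3f, %.3f], border +/-%.3f, max %d position(s) outside\n",
    x$name, x$lower, x$upper, x$border_tol, x$max_outside
  ))
  invisible(x)
}
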