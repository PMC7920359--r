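# The core computation: weighted per-position nucleotide fractions.
# During sequencing every DNA nanoball on the flow cell is read
# synchronously, one position per cycle, so the signal available to the
# basecaller at a barcode cycle is set by the mix of nucleotides across
# the pooled samples at that position. For a set with members i, mixing
# weights w_i and sequences seq_i,
#
#   f(p, b) = sum_i w_i * [seq_i[p] == b] / sum_i w_i
#
# for position p in 1..L and base b in {A, C, G, T}. Balanced pools keep
# every f(p, b) near 0.25; strong skews starve one fluorophore channel
# and degrade basecalls at that cycle.

#' Compute weighted per-position nucleotide fractions
#'
#' For each barcode position and each base, the weight-normalised share
#' of pooled material carrying that base at that position. The result is
#' invariant under rescaling all weights by a positive constant, and each
#' position's four fractions sum to one.
#'
#' @param set A `bc_set` (or data frame with `id`, optional `weight`).
#' @param panel The `bc_panel` containing the members' sequences.
#' @return A `bc_fractions` tibble in long form with columns `position`
#'   (1-based), `base`, `fraction`, and attributes `L` and
#'   `total_weight` (the raw weight sum).
#' @examples
#' panel <- bc_panel(data.frame(
#'   id = c("A", "C", "G", "T"),
#'   seq = c("AAAA", "CCCC", "GGGG", "TTTT")
#' ))
#' compute_fraction_matrix(bc_set(c("A", "C", "G", "T")), panel)
#' @export
compute_fraction_matrix <- function(set, panel) {
  r <- resolve_set(set, panel)
  fm <- vapply(
    BASES,
    function(b) as.numeric(crossprod(r$w, r$S == b)) / sum(r$w),
    numeric(r$L)
  )
  # r$L x 4 matrix, rows positions, columns A/C/G/T
  out <- tibble::tibble(
    position = rep(seq_len(r$L), times = 4L),
    base = rep(BASES, each = r$L),
    fraction = as.vector(fm)
  )
  structure(out,
    L = r$L,
    total_weight = sum(bc_set(set)$weight),
    class = c("bc_fractions", class(tibble::tibble()))
  )
}

#' Fractions as an L x 4 matrix
#'
#' @param fm A `bc_fractions` object.
#' @return Numeric matrix, one row per position, columns A/C/G/T.
#' @export
fraction_values <- function(fm) {
  stopifnot(inherits(fm, "bc_fractions"))
  L <- attr(fm, "L")
  m <- matrix(NA_real_, L, 4, dimnames = list(NULL, BASES))
  m[cbind(fm$position, match(fm$base, BASES))] <- fm$fraction
  m
}

# Build a bc_fractions object from a bare L x 4 matrix (rows must sum
# to 1). Used to evaluate constructed matrices and by the search code.
as_bc_fractions <- function(m, total_weight = 1) {
  m <- as.matrix(m)
  if (ncol(m) != 4) abort_validation("fraction matrix must have 4 columns (A,C,G,T)")
  if (any(m < -1e-12) || any(m > 1 + 1e-12) ||
      any(abs(rowSums(m) - 1) > 1e-9)) {
    abort_validation("fraction matrix rows must be fractions summing to 1")
  }
  colnames(m) <- BASES
  out <- tibble::tibble(
    position = rep(seq_len(nrow(m)), times = 4L),
    base = rep(BASES, each = nrow(m)),
    fraction = as.vector(m)
  )
  structure(out,
    L = nrow(m), total_weight = total_weight,
    class = c("bc_fractions", class(tibble::tibble()))
  )
}

# Cell-level classification against a corridor; shared by
# evaluate_criterion() and the selection scoring.
classify_cells <- function(m, crit) {
  status <- matrix("inside", nrow(m), ncol(m))
  status[m < crit$lower - crit$border_tol | m > crit$upper + crit$border_tol] <- "outside"
  border <- (abs(m - crit$lower) <= crit$border_tol |
               abs(m - crit$upper) <= crit$border_tol) & status != "outside"
  status[border] <- "border"
  status
}

#' Judge a fraction matrix against a balance criterion
#'
#' Each (position, base) cell is classified against the corridor: outside
#' if the fraction is beyond a bound by more than the border tolerance,
#' border if within the tolerance of a bound, inside otherwise. A
#' position takes the worst status among its four bases (the method
#' counts violating positions, not violating cells). The set passes when
#' the number of outside positions does not exceed the criterion's cap.
#'
#' @param fm A `bc_fractions` object (from [compute_fraction_matrix()]).
#' @param crit A `bc_criterion`.
#' @return A `bc_verdict`: list with the criterion, `pass`, counts
#'   `n_inside` / `n_border` / `n_outside`, `max_deviation`
#'   (max over cells of `|f - 0.25|`), `per_position` (tibble of
#'   position, status), and `offending` (tibble of outside cells:
#'   position, base, fraction).
#' @export
evaluate_criterion <- function(fm, crit) {
  stopifnot(inherits(fm, "bc_fractions"), inherits(crit, "bc_criterion"))
  m <- fraction_values(fm)
  status <- classify_cells(m, crit)
  rank <- matrix(match(status, c("inside", "border", "outside")),
                 nrow(m), ncol(m))
  pos_rank <- apply(rank, 1, max)
  pos_status <- c("inside", "border", "outside")[pos_rank]
  off <- which(status == "outside", arr.ind = TRUE)
  offending <- tibble::tibble(
    position = as.integer(off[, 1]),
    base = BASES[off[, 2]],
    fraction = m[off]
  )
  offending <- dplyr::arrange(offending, .data$position, .data$base)
  n_outside <- sum(pos_status == "outside")
  structure(
    list(
      criterion = crit,
      pass = n_outside <= crit$max_outside,
      n_inside = sum(pos_status == "inside"),
      n_border = sum(pos_status == "border"),
      n_outside = n_outside,
      max_deviation = max(abs(m - 0.25)),
      per_position = tibble::tibble(
        position = seq_len(nrow(m)),
        status = pos_status
      ),
      offending = offending
    ),
    class = "bc_verdict"
  )
}

#' @export
print.bc_verdict <- function(x, ...) {
  cat(sprintf(
    "<balance verdict, criterion '%s'> %s\n", x$criterion$name,
    if (x$pass) "PASS" else "FAIL"
  ))
  cat(sprintf(
    "  positions: %d inside, %d border, %d outside (allowed %d); max |f - 0.25| = %.3f\n",
    x$n_inside, x$n_border, x$n_outside, x$criterion$max_outside,
    x$max_deviation
  ))
  if (nrow(x$offending)) {
    cat("  outside cells:\n")
    purrr::pwalk(x$offending, function(position, base, fraction) {
      cat(sprintf("    position %d, base %s: %.3f\n", position, base, fraction))
    })
  }
  invisible(x)
}

#' Serialize a verdict to the JSON report schema
#'
#' @param verdict A `bc_verdict`.
#' @return A list ready for `jsonlite::toJSON(auto_unbox = TRUE)` with
#'   fields criterion, pass, n_inside, n_border, n_outside,
#'   max_deviation and offending (1-based positions, full precision).
#' @export
verdict_report <- function(verdict) {
  stopifnot(inherits(verdict, "bc_verdict"))
  list(
    criterion = verdict$criterion$name,
    pass = verdict$pass,
    n_inside = verdict$n_inside,
    n_border = verdict$n_border,
    n_outside = verdict$n_outside,
    max_deviation = verdict$max_deviation,
    offending = purrr::pmap(verdict$offending, function(position, base, fraction) {
      list(position = position, base = base, fraction = fraction)
    })
  )
}
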