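# Pairwise barcode comparison. Barcodes are read as fixed-length
# synchronous cycles, so substitution-only Hamming distance is the right
# metric (no indels). The smallest pairwise distance d_min governs how
# many read errors demultiplexing can tolerate before two samples merge.

#' Pairwise Hamming distance matrix of a panel
#'
#' @param panel A `bc_panel` (or a `bc_set` plus `panel`, via
#'   [set_distance()]).
#' @return A `bc_distmat`: list with `ids`, symmetric integer matrix `d`,
#'   `d_min` / `d_max` over distinct pairs with their argmin / argmax
#'   pairs (`min_pairs`, `max_pairs`). For a single-barcode panel the
#'   matrix is 1 x 1 and the extremes are `NA` with `extremes_defined =
#'   FALSE`.
#' @examples
#' p <- make_random_panel(6, L = 10, min_distance = 4, seed = 1)
#' hamming_matrix(p)$d_min
#' @export
hamming_matrix <- function(panel) {
  panel <- bc_panel(panel)
  n <- nrow(panel)
  S <- seq_matrix(panel$seq)
  d <- matrix(0L, n, n, dimnames = list(panel$id, panel$id))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      rest <- (i + 1):n
      di <- rowSums(S[rest, , drop = FALSE] !=
                      matrix(S[i, ], length(rest), ncol(S), byrow = TRUE))
      d[i, rest] <- as.integer(di)
      d[rest, i] <- as.integer(di)
    }
  }
  upper <- d[upper.tri(d)]
  extremes_defined <- n >= 2
  pair_at <- function(val) {
    w <- which(upper.tri(d) & d == val, arr.ind = TRUE)
    tibble::tibble(id1 = panel$id[w[, 1]], id2 = panel$id[w[, 2]],
                   distance = as.integer(d[w]))
  }
  structure(
    list(
      ids = panel$id,
      d = d,
      d_min = if (extremes_defined) min(upper) else NA_integer_,
      d_max = if (extremes_defined) max(upper) else NA_integer_,
      min_pairs = if (extremes_defined) pair_at(min(upper)) else NULL,
      max_pairs = if (extremes_defined) pair_at(max(upper)) else NULL,
      extremes_defined = extremes_defined
    ),
    class = "bc_distmat"
  )
}

#' Hamming distances within a weighted set
#'
#' Convenience wrapper: restricts the panel to the set's members (weights
#' play no role in distances).
#' @param set A `bc_set`.
#' @param panel The `bc_panel`.
#' @return A `bc_distmat` over the set's members, in set order.
#' @export
set_distance <- function(set, panel) {
  r <- resolve_set(set, panel)
  hamming_matrix(tibble::tibble(id = r$ids, seq = r$seqs))
}

#' Check decodability of a panel under a mismatch tolerance
#'
#' Reports two conditions for demultiplexing with up to `m` allowed
#' mismatches:
#' * the no-merge condition `m < d_min` — the number of misread
#'   nucleotides must stay below the smallest pairwise difference,
#'   otherwise a read can land exactly on another sample's barcode;
#' * the strict coding-theory guarantee `d_min >= 2m + 1` — every read
#'   with at most `m` errors has a unique nearest barcode, so no read
#'   can even tie between two samples.
#'
#' The gap between the two matters in practice: raising the mismatch cap
#' rescues otherwise undecoded reads but, once `d_min < 2m + 1`, some
#' reads sit ambiguously between similar barcodes.
#'
#' @param x A `bc_panel`, or a `bc_set` when `panel` is given.
#' @param m Mismatch tolerance (non-negative integer).
#' @param panel Optional `bc_panel` when `x` is a set.
#' @return A `bc_decodability`: list with `m`, `d_min`, logicals
#'   `no_merge` and `strict_guarantee`, and tibbles
#'   `no_merge_violations` (pairs at distance <= m) and
#'   `strict_violations` (pairs at distance < 2m + 1).
#' @export
decodability_check <- function(x, m = 2, panel = NULL) {
  if (m < 0) abort_validation("`m` must be non-negative")
  dm <- if (!is.null(panel)) set_distance(x, panel) else hamming_matrix(x)
  if (!dm$extremes_defined) {
    abort_validation("decodability needs at least two barcodes")
  }
  pairs_below <- function(thr) {
    w <- which(upper.tri(dm$d) & dm$d < thr, arr.ind = TRUE)
    tibble::tibble(
      id1 = dm$ids[w[, 1]], id2 = dm$ids[w[, 2]],
      distance = as.integer(dm$d[w])
    )
  }
  structure(
    list(
      m = as.integer(m),
      d_min = dm$d_min,
      no_merge = m < dm$d_min,
      strict_guarantee = dm$d_min >= 2 * m + 1,
      no_merge_violations = pairs_below(m + 1),
      strict_violations = pairs_below(2 * m + 1)
    ),
    class = "bc_decodability"
  )
}

#' @export
print.bc_distmat <- function(x, ...) {
  cat(sprintf("<distance matrix> %d barcodes", length(x$ids)))
  if (x$extremes_defined) {
    cat(sprintf(", d_min = %d, d_max = %d\n", x$d_min, x$d_max))
  } else {
    cat(" (extremes undefined for < 2 barcodes)\n")
  }
  invisible(x)
}

#' @export
print.bc_decodability <- function(x, ...) {
  cat(sprintf("<decodability at m = %d> d_min = %d\n", x$m, x$d_min))
  cat(sprintf(
    "  no-merge condition (m < d_min):        %s\n",
    if (x$no_merge) "holds" else
      sprintf("VIOLATED (%d pair(s) within m)", nrow(x$no_merge_violations))
  ))
  cat(sprintf(
    "  unique-nearest guarantee (d_min >= 2m+1): %s\n",
    if (x$strict_guarantee) "holds" else
      sprintf("not guaranteed (%d pair(s) closer than 2m+1)",
              nrow(x$strict_violations))
  ))
  invisible(x)
}
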