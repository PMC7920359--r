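# Mismatch-tolerant barcode decoding and a seeded read simulator.
# Demultiplexing compares the barcode read of each fragment against the
# table of known barcodes and assigns the closest one within a mismatch
# cap (platform default 2). Reads farther than the cap from every
# barcode, or tied between two barcodes within the cap, are "undecoded"
# and unusable downstream. The simulator draws reads from a weighted set
# under a substitution error model, so undecoded and misassignment rates
# can be quantified without sequencer output; per-cycle error rates rise
# toward the end of a run — where barcodes sit — which the "ramp" model
# reflects.

#' Define a substitution error model
#'
#' Per-position substitution probabilities for simulated barcode reads.
#' `uniform` applies one rate `q` at every position; `ramp` interpolates
#' linearly from `q_start` at position 1 to `q_end` at position L,
#' mirroring the rising per-cycle error rate over a run. A substituted
#' base is drawn uniformly from the three alternatives.
#'
#' @param kind `"uniform"` or `"ramp"`.
#' @param q Substitution probability per position (uniform model).
#' @param q_start,q_end Endpoint probabilities (ramp model),
#'   `q_start <= q_end`.
#' @return A `bc_error_model`.
#' @examples
#' error_model("uniform", q = 0.01)
#' error_model("ramp", q_start = 0.005, q_end = 0.03)
#' @export
error_model <- function(kind = c("uniform", "ramp"), q = 0.01,
                        q_start = 0.005, q_end = 0.03) {
  kind <- match.arg(kind)
  if (kind == "uniform") {
    if (q < 0 || q >= 1) abort_validation("`q` must lie in [0, 1)")
    em <- list(kind = kind, q = q)
  } else {
    if (q_start < 0 || q_end >= 1 || q_start > q_end) {
      abort_validation("ramp model needs 0 <= q_start <= q_end < 1")
    }
    em <- list(kind = kind, q_start = q_start, q_end = q_end)
  }
  structure(em, class = "bc_error_model")
}

# Per-position substitution rates for a given barcode length.
position_rates <- function(em, L) {
  stopifnot(inherits(em, "bc_error_model"))
  if (em$kind == "uniform") {
    rep(em$q, L)
  } else if (L == 1) {
    em$q_start
  } else {
    em$q_start + (em$q_end - em$q_start) * (seq_len(L) - 1) / (L - 1)
  }
}

# Distance of every read (rows of char matrix X) to every member
# sequence (rows of S): n x k integer matrix.
read_member_distances <- function(X, S) {
  n <- nrow(X)
  D <- matrix(0L, n, nrow(S))
  for (j in seq_len(nrow(S))) {
    D[, j] <- as.integer(
      rowSums(X != matrix(S[j, ], n, ncol(S), byrow = TRUE))
    )
  }
  D
}

decode_from_distances <- function(D, ids, m) {
  dmin <- do.call(pmin, as.data.frame(D))
  ties <- rowSums(D == dmin) > 1L
  within <- dmin <= m
  assigned <- ifelse(within & !ties, ids[max.col(-D, ties.method = "first")],
                     "UNDECODED")
  tibble::tibble(
    assigned = assigned,
    distance = ifelse(within, as.integer(dmin), NA_integer_),
    ambiguous = within & ties
  )
}

#' Decode barcode reads against a set
#'
#' Assigns each read to the unique member at minimal Hamming distance,
#' provided that distance does not exceed the mismatch cap `m`. A read
#' with no member within `m` is `UNDECODED`; so is a read with two or
#' more members tied at the minimal distance within `m`
#' (`ambiguous = TRUE`) — a tie is never broken arbitrarily, since
#' assigning it would risk connecting samples with similar barcodes.
#'
#' By default only the set's members are scanned; `scan_panel = TRUE`
#' decodes against the whole panel instead (shrinking the comparison
#' list is not what rescues undecoded reads, but both modes are useful).
#'
#' @param reads Character vector of ACGT reads, each of the panel's
#'   barcode length.
#' @param set A `bc_set`.
#' @param panel The `bc_panel`.
#' @param m Mismatch cap (non-negative integer; platform default 2).
#' @param scan_panel Scan all panel barcodes instead of only the set's
#'   members.
#' @return A tibble with one row per read: `read`, `assigned` (member id
#'   or `"UNDECODED"`), `distance` (NA when nothing is within `m`),
#'   `ambiguous`.
#' @export
decode_reads <- function(reads, set, panel, m = 2, scan_panel = FALSE) {
  if (m < 0) abort_validation("`m` must be non-negative")
  r <- if (scan_panel) {
    resolve_set(bc_set(bc_panel(panel)$id), panel)
  } else {
    resolve_set(set, panel)
  }
  reads <- toupper(as.character(reads))
  if (any(nchar(reads) != r$L)) {
    abort_validation(sprintf(
      "read length %d does not match barcode length %d",
      nchar(reads[which(nchar(reads) != r$L)[1]]), r$L
    ))
  }
  X <- seq_matrix(reads)
  res <- decode_from_distances(read_member_distances(X, r$S), r$ids, m)
  tibble::tibble(read = reads, res)
}

#' @rdname decode_reads
#' @param read A single read (convenience scalar form).
#' @export
decode_read <- function(read, set, panel, m = 2, scan_panel = FALSE) {
  out <- decode_reads(read, set, panel, m = m, scan_panel = scan_panel)
  list(assigned = out$assigned, distance = out$distance,
       ambiguous = out$ambiguous)
}

#' Simulate barcode reads from a weighted set
#'
#' Draws `n` reads from the set's members with probability proportional
#' to the normalised weights, then applies independent per-position
#' substitutions according to the error model. Fully reproducible for a
#' given seed.
#'
#' @param set A `bc_set`.
#' @param panel The `bc_panel`.
#' @param n Number of reads.
#' @param em A `bc_error_model` (default uniform q = 0.01).
#' @param seed Optional integer seed.
#' @return A tibble with columns `truth` (source member id), `read`, and
#'   `n_errors` (substitutions actually applied).
#' @export
simulate_reads <- function(set, panel, n, em = error_model(), seed = NULL) {
  if (n < 1) abort_validation("`n` must be at least 1")
  sim <- simulate_read_matrix(set, panel, n, em, seed)
  tibble::tibble(
    truth = sim$ids[sim$truth_idx],
    read = apply(sim$X, 1, paste0, collapse = ""),
    n_errors = sim$n_errors
  )
}

# Internal matrix-form simulator shared with run_mismatch_sweep():
# returns list(ids, truth_idx, X char matrix, n_errors).
simulate_read_matrix <- function(set, panel, n, em, seed) {
  r <- resolve_set(set, panel)
  rates <- position_rates(em, r$L)
  with_optional_seed(seed, {
    truth_idx <- sample.int(length(r$ids), n, replace = TRUE, prob = r$w)
    X <- r$S[truth_idx, , drop = FALSE]
    hit <- matrix(stats::runif(n * r$L), n, r$L) <
      matrix(rates, n, r$L, byrow = TRUE)
    if (any(hit)) {
      cur <- match(X[hit], BASES)
      step <- sample.int(3L, sum(hit), replace = TRUE)
      X[hit] <- BASES[(cur - 1L + step) %% 4L + 1L]
    }
    list(ids = r$ids, truth_idx = truth_idx, X = X,
         n_errors = as.integer(rowSums(hit)))
  })
}

#' Write simulated reads as FASTQ
#'
#' Standard 4-line records with constant quality, for interoperability
#' with external demultiplexers.
#' @param sim Tibble from [simulate_reads()].
#' @param path Output FASTQ path.
#' @param quality_char Constant per-base quality character.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(sim, path, quality_char = "I") {
  qual <- strrep(quality_char, nchar(sim$read))
  writeLines(paste0(
    "@read", seq_len(nrow(sim)), "_", sim$truth, "\n",
    sim$read, "\n+\n", qual
  ), path)
  invisible(path)
}

#' Summarise decode results against truth labels
#'
#' @param decoded Tibble from [decode_reads()].
#' @param truth Character vector of true source ids, same length.
#' @return A one-row tibble: `n_reads`, `n_correct`, `n_misassigned`,
#'   `n_undecoded` and the corresponding fractions (summing to 1).
#' @export
sim_stats <- function(decoded, truth) {
  stopifnot(nrow(decoded) == length(truth))
  n <- nrow(decoded)
  undec <- decoded$assigned == "UNDECODED"
  correct <- !undec & decoded$assigned == truth
  mis <- !undec & !correct
  tibble::tibble(
    n_reads = n,
    n_correct = sum(correct),
    n_misassigned = sum(mis),
    n_undecoded = sum(undec),
    frac_correct = sum(correct) / n,
    frac_misassigned = sum(mis) / n,
    frac_undecoded = sum(undec) / n
  )
}

#' Sweep the mismatch cap over one simulated read pool
#'
#' Simulates one pool of reads, then decodes the same reads at each
#' mismatch cap in `m_values` — a decode-only sweep, so differences
#' between rows reflect the cap alone. `pct_rescued` gives the reduction
#' of the undecoded count relative to the first cap, as a percentage of
#' that baseline (the "% rescued data" reading of a mismatch sweep).
#' Raising the cap can only shrink the undecoded pool, but past
#' `d_min/2` it starts trading undecoded reads for misassigned ones.
#'
#' @param set A `bc_set`.
#' @param panel The `bc_panel`.
#' @param n Number of reads simulated once and reused.
#' @param em A `bc_error_model`.
#' @param seed Optional integer seed.
#' @param m_values Mismatch caps to evaluate (non-empty).
#' @param scan_panel Decode against the whole panel instead of the set.
#' @return A tibble with one row per `m`: the [sim_stats()] columns plus
#'   `m` and `pct_rescued`.
#' @export
run_mismatch_sweep <- function(set, panel, n, em = error_model(),
                               seed = NULL, m_values = c(2, 3, 4),
                               scan_panel = FALSE) {
  if (length(m_values) == 0) abort_validation("`m_values` must be non-empty")
  sim <- simulate_read_matrix(set, panel, n, em, seed)
  scan <- if (scan_panel) {
    resolve_set(bc_set(bc_panel(panel)$id), panel)
  } else {
    resolve_set(set, panel)
  }
  D <- read_member_distances(sim$X, scan$S)
  truth <- sim$ids[sim$truth_idx]
  out <- purrr::map_dfr(m_values, function(m) {
    dec <- decode_from_distances(D, scan$ids, m)
    dplyr::bind_cols(tibble::tibble(m = as.integer(m)), sim_stats(dec, truth))
  })
  base_undec <- out$n_undecoded[1]
  out$pct_rescued <- if (base_undec > 0) {
    100 * (base_undec - out$n_undecoded) / base_undec
  } else {
    rep(0, nrow(out))
  }
  out
}
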