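# Fixtures and independent oracles used across the suite. Oracles are
# deliberately naive (double loops, full enumeration) and never share
# code with the implementation they check.

# Four homopolymer barcodes: every column is a permutation of ACGT, so
# the set is exactly balanced at equal weights and every pairwise
# distance equals L.
quartet_panel <- function(L = 10) {
  bc_panel(data.frame(
    id = c("polyA", "polyC", "polyG", "polyT"),
    seq = vapply(c("A", "C", "G", "T"), strrep, character(1), L)
  ))
}

# A 4-barcode panel whose columns are balanced permutations except for
# `n_skewed` leading columns of "AACG" (A overrepresented, T absent):
# at equal weights exactly those positions violate any corridor around
# 0.25 that excludes 0.5.
skewed_quartet_panel <- function(L = 10, n_skewed = 3) {
  cols <- c(
    rep(list(c("A", "A", "C", "G")), n_skewed),
    rep(list(c("A", "C", "G", "T")), L - n_skewed)
  )
  m <- do.call(cbind, cols)
  bc_panel(data.frame(
    id = paste0("S", 1:4),
    seq = apply(m, 1, paste0, collapse = "")
  ))
}

random_seqs <- function(n, L) {
  repeat {
    s <- vapply(
      seq_len(n),
      function(i) paste0(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""),
      character(1)
    )
    if (!anyDuplicated(s)) return(s)
  }
}

random_panel_df <- function(n, L, prefix = "R") {
  bc_panel(data.frame(id = paste0(prefix, seq_len(n)), seq = random_seqs(n, L)))
}

# Oracle: pairwise Hamming distances by character-by-character double loop.
brute_hamming <- function(panel) {
  n <- nrow(panel)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- strsplit(panel$seq[i], "")[[1]]
      b <- strsplit(panel$seq[j], "")[[1]]
      d[i, j] <- sum(a != b)
    }
  }
  d
}

# Oracle: classify every (position, base) cell of a fraction matrix by
# direct comparison, then aggregate positions; returns n_outside and
# per-position status.
brute_classify <- function(m, crit) {
  L <- nrow(m)
  pos_status <- character(L)
  for (p in seq_len(L)) {
    worst <- "inside"
    for (b in 1:4) {
      f <- m[p, b]
      st <- if (f < crit$lower - crit$border_tol ||
                  f > crit$upper + crit$border_tol) {
        "outside"
      } else if (abs(f - crit$lower) <= crit$border_tol ||
                   abs(f - crit$upper) <= crit$border_tol) {
        "border"
      } else {
        "inside"
      }
      if (st == "outside") worst <- "outside"
      if (st == "border" && worst == "inside") worst <- "border"
    }
    pos_status[p] <- worst
  }
  list(per_position = pos_status, n_outside = sum(pos_status == "outside"))
}

# Oracle: decode one read by exhaustive scan over member sequences.
brute_decode <- function(read, member_ids, member_seqs, m) {
  r <- strsplit(read, "")[[1]]
  d <- vapply(member_seqs, function(s) sum(strsplit(s, "")[[1]] != r),
              integer(1))
  dmin <- min(d)
  hits <- which(d == dmin)
  if (dmin > m || length(hits) > 1) {
    list(assigned = "UNDECODED", ambiguous = dmin <= m && length(hits) > 1)
  } else {
    list(assigned = member_ids[hits], ambiguous = FALSE)
  }
}

# Oracle: full enumeration of a selection problem. Returns a tibble of
# every combination with its best score over weight assignments,
# ordered like complete_set() orders candidates.
brute_complete <- function(current_ids, current_w, k, pool, new_weights,
                           crit, panel) {
  combos <- utils::combn(pool, k, simplify = FALSE)
  rows <- lapply(combos, function(ids) {
    perms <- if (length(unique(new_weights)) == 1) {
      list(seq_len(k))
    } else {
      all_perms(k)
    }
    best <- NULL
    for (p in perms) {
      s <- bc_set(c(current_ids, ids), c(current_w, new_weights[p]))
      fm <- compute_fraction_matrix(s, panel)
      sc <- score_set(fm, crit)
      if (is.null(best) || lex_less(sc, best)) best <- sc
    }
    tibble::tibble(
      ids = paste(sort(ids), collapse = ","),
      n_outside = best[["n_outside"]],
      max_deviation = best[["max_deviation"]],
      rms = best[["rms"]]
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$n_outside, out$max_deviation, out$rms, out$ids), ]
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in all_perms(k - 1L)) {
    for (pos in 0:(k - 1L)) out[[length(out) + 1L]] <- append(p, k, after = pos)
  }
  out
}

lex_less <- function(a, b, tol = 1e-12) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - tol) return(TRUE)
    if (a[i] > b[i] + tol) return(FALSE)
  }
  FALSE
}
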