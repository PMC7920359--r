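# Set completion: which barcodes from a candidate pool can be added to a
# working set, at user-specified proportions, so that the combined pool
# still satisfies a balance criterion. Small problems are enumerated
# exhaustively; large ones fall back to a deterministic greedy beam
# search, flagged as non-exhaustive. Candidates are ranked by a
# lexicographic score (outside positions, worst deviation, RMS
# deviation from 0.25), so "passes and is closest to perfectly
# balanced" sorts first.

#' Score a fraction matrix for ranking
#'
#' Lexicographic quality score: number of positions outside the
#' criterion corridor, then the maximum cell deviation `|f - 0.25|`,
#' then the root-mean-square deviation from 0.25. Lower is better; a
#' perfectly balanced matrix scores `(0, 0, 0)`.
#'
#' @param fm A `bc_fractions` object.
#' @param crit A `bc_criterion` (defaults to the shipped strong
#'   criterion).
#' @return Named numeric vector `c(n_outside, max_deviation, rms)`.
#' @export
score_set <- function(fm, crit = default_criteria()$strong) {
  m <- fraction_values(fm)
  score_matrix(m, crit)
}

# Matrix-level scorer used in the inner search loop (no tibble
# construction).
score_matrix <- function(m, crit) {
  status <- classify_cells(m, crit)
  n_outside <- sum(apply(status == "outside", 1, any))
  dev <- abs(m - 0.25)
  c(
    n_outside = n_outside,
    max_deviation = max(dev),
    rms = sqrt(mean(dev^2))
  )
}

# TRUE if score a is strictly better (lexicographically smaller) than b.
score_less <- function(a, b, tol = 1e-12) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - tol) return(TRUE)
    if (a[i] > b[i] + tol) return(FALSE)
  }
  FALSE
}

#' Define a set-completion problem
#'
#' @param current The working `bc_set` (may be `NULL` / empty to build a
#'   set from scratch).
#' @param k Number of new barcodes to add.
#' @param new_weights `k` positive proportions for the added barcodes,
#'   on the same scale as the current set's weights; `NULL` means 1
#'   each.
#' @param pool Candidate barcode ids to choose from; must be disjoint
#'   from the current members.
#' @param criterion A `bc_criterion` the completed set must satisfy.
#' @param max_results Maximum number of ranked candidates to return.
#' @return A `bc_selection_problem`.
#' @export
selection_problem <- function(current, k, pool, new_weights = NULL,
                              criterion = default_criteria()$strong,
                              max_results = 10) {
  current <- if (is.null(current)) NULL else bc_set(current)
  k <- as.integer(k)
  if (k < 0) abort_validation("`k` must be non-negative")
  pool <- unique(as.character(pool))
  if (k > length(pool)) {
    abort_validation("`k` exceeds the candidate pool size")
  }
  if (!is.null(current) && any(pool %in% current$id)) {
    abort_validation("`pool` must be disjoint from the current members")
  }
  new_weights <- new_weights %||% rep(1, k)
  new_weights <- as.numeric(new_weights)
  if (length(new_weights) != k || any(new_weights <= 0)) {
    abort_validation("`new_weights` must be k positive values")
  }
  stopifnot(inherits(criterion, "bc_criterion"))
  if (max_results < 1) abort_validation("`max_results` must be positive")
  structure(
    list(
      current = current, k = k, pool = pool, new_weights = new_weights,
      criterion = criterion, max_results = as.integer(max_results)
    ),
    class = "bc_selection_problem"
  )
}

# Precompute per-barcode one-hot count matrices (L x 4) for fast
# incremental fraction updates during the search.
onehot_counts <- function(panel, ids) {
  idx <- match(ids, panel$id)
  if (anyNA(idx)) {
    abort_validation(sprintf(
      "pool barcode '%s' not found in panel", ids[which(is.na(idx))[1]]
    ))
  }
  S <- seq_matrix(panel$seq[idx])
  lapply(seq_along(ids), function(i) {
    vapply(BASES, function(b) as.numeric(S[i, ] == b), numeric(ncol(S)))
  })
}

# Best score over weight-to-barcode assignments for a chosen combo.
# Unequal weights change the fraction matrix depending on which barcode
# receives which weight; all k! pairings are tried for k <= 5, else a
# deterministic greedy pairing. Returns list(score, perm).
best_assignment <- function(W0, w0, counts, combo_idx, new_weights, crit) {
  k <- length(combo_idx)
  wtot <- w0 + sum(new_weights)
  if (k == 0) {
    return(list(score = score_matrix(W0 / w0, crit), perm = integer(0)))
  }
  distinct_w <- length(unique(new_weights)) > 1
  if (!distinct_w || k == 1) {
    W <- W0
    for (j in seq_len(k)) W <- W + new_weights[j] * counts[[combo_idx[j]]]
    return(list(score = score_matrix(W / wtot, crit), perm = seq_len(k)))
  }
  if (k <= 5) {
    perms <- permutations_of(k)
    best <- NULL
    for (p in perms) {
      W <- W0
      for (j in seq_len(k)) W <- W + new_weights[p[j]] * counts[[combo_idx[j]]]
      sc <- score_matrix(W / wtot, crit)
      if (is.null(best) || score_less(sc, best$score)) {
        best <- list(score = sc, perm = p)
      }
    }
    return(best)
  }
  # greedy pairing: place weights in decreasing order, each on the
  # barcode that minimises the running score
  ord <- order(new_weights, decreasing = TRUE)
  W <- W0
  free <- seq_len(k)
  perm <- integer(k)
  for (wi in ord) {
    best_j <- free[1]
    best_sc <- NULL
    for (j in free) {
      sc <- score_matrix((W + new_weights[wi] * counts[[combo_idx[j]]]) / wtot,
                         crit)
      if (is.null(best_sc) || score_less(sc, best_sc)) {
        best_sc <- sc
        best_j <- j
      }
    }
    W <- W + new_weights[wi] * counts[[combo_idx[best_j]]]
    perm[best_j] <- wi
    free <- setdiff(free, best_j)
  }
  list(score = score_matrix(W / wtot, crit), perm = perm)
}

permutations_of <- function(k) {
  if (k == 1) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}

#' Search a pool for barcode additions that keep a set balanced
#'
#' Evaluates combinations of `k` barcodes from the candidate pool added
#' to the current set at the requested proportions, and returns the
#' combinations whose completed set passes the criterion, ranked by
#' [score_set()] (ties broken by lexicographic ids). When the number of
#' combinations is at most `exhaustive_cap` the search is complete;
#' otherwise a deterministic greedy beam search explores the pool and
#' the result is flagged `exhaustive = FALSE`. With unequal
#' `new_weights` the weight-to-barcode pairing is optimised per
#' combination (all pairings for k <= 5).
#'
#' @param problem A `bc_selection_problem`.
#' @param panel The `bc_panel` containing current members and pool.
#' @param exhaustive_cap Maximum combination count enumerated
#'   exhaustively.
#' @param beam_width Beam width of the fallback greedy search.
#' @return A `bc_selection`: list with `candidates` (tibble: `added`
#'   list-column, `weights` list-column in id order, `n_outside`,
#'   `max_deviation`, `rms`, `pass`), `exhaustive`, `n_evaluated`, and
#'   `diagnostics` (best failing combination) when nothing passes.
#' @export
complete_set <- function(problem, panel, exhaustive_cap = 1e5,
                         beam_width = 64) {
  stopifnot(inherits(problem, "bc_selection_problem"))
  panel <- bc_panel(panel)
  crit <- problem$criterion
  k <- problem$k

  # weighted counts of the current set (un-normalised)
  if (is.null(problem$current) || nrow(problem$current) == 0) {
    L <- panel_length(panel)
    W0 <- matrix(0, L, 4, dimnames = list(NULL, BASES))
    w0 <- 0
  } else {
    r <- resolve_set(problem$current, panel)
    wraw <- bc_set(problem$current)$weight
    W0 <- Reduce(`+`, purrr::map2(
      onehot_counts(panel, r$ids), wraw, function(C, w) w * C
    ))
    w0 <- sum(wraw)
  }

  if (k == 0) {
    if (w0 == 0) abort_validation("nothing to analyze: empty set and k = 0")
    fm <- as_bc_fractions(W0 / w0, total_weight = w0)
    v <- evaluate_criterion(fm, crit)
    sc <- score_set(fm, crit)
    cand <- tibble::tibble(
      added = list(character(0)), weights = list(numeric(0)),
      n_outside = sc[["n_outside"]], max_deviation = sc[["max_deviation"]],
      rms = sc[["rms"]], pass = v$pass
    )
    return(structure(
      list(candidates = cand[cand$pass, ], exhaustive = TRUE,
           n_evaluated = 1L, verdict = v,
           diagnostics = if (v$pass) NULL else cand),
      class = "bc_selection"
    ))
  }

  counts <- onehot_counts(panel, problem$pool)
  n_pool <- length(problem$pool)
  n_comb <- choose(n_pool, k)
  exhaustive <- n_comb <= exhaustive_cap

  evaluate_combo <- function(idx) {
    ba <- best_assignment(W0, w0, counts, idx, problem$new_weights, crit)
    list(idx = idx, score = ba$score, perm = ba$perm)
  }

  results <- list()
  if (exhaustive) {
    combos <- utils::combn(n_pool, k, simplify = FALSE)
    results <- lapply(combos, evaluate_combo)
    n_evaluated <- length(combos)
  } else {
    # deterministic greedy beam search over partial combinations
    beams <- list(integer(0))
    n_evaluated <- 0L
    for (step in seq_len(k)) {
      expanded <- list()
      seen <- character(0)
      for (b in beams) {
        for (j in seq_len(n_pool)) {
          if (j %in% b) next
          cand <- sort(c(b, j))
          key <- paste(cand, collapse = ",")
          if (key %in% seen) next
          seen <- c(seen, key)
          # partial sets take the first `step` weights
          ba <- best_assignment(W0, w0, counts, cand,
                                problem$new_weights[seq_len(step)], crit)
          n_evaluated <- n_evaluated + 1L
          expanded[[length(expanded) + 1L]] <-
            list(idx = cand, score = ba$score, perm = ba$perm)
        }
      }
      ord <- order_by_score(expanded, problem$pool)
      beams <- lapply(
        expanded[ord[seq_len(min(beam_width, length(expanded)))]],
        `[[`, "idx"
      )
    }
    results <- lapply(beams, evaluate_combo)
    n_evaluated <- n_evaluated + length(beams)
  }

  ord <- order_by_score(results, problem$pool)
  results <- results[ord]
  rows <- purrr::map_dfr(results, function(r) {
    ids <- problem$pool[r$idx]
    tibble::tibble(
      added = list(ids),
      weights = list(problem$new_weights[r$perm]),
      n_outside = r$score[["n_outside"]],
      max_deviation = r$score[["max_deviation"]],
      rms = r$score[["rms"]],
      pass = r$score[["n_outside"]] <= crit$max_outside
    )
  })
  passing <- rows[rows$pass, ]
  passing <- passing[seq_len(min(nrow(passing), problem$max_results)), ]
  structure(
    list(
      candidates = passing,
      exhaustive = exhaustive,
      n_evaluated = n_evaluated,
      diagnostics = if (nrow(passing) == 0 && nrow(rows) > 0) {
        rows[1, ]
      } else {
        NULL
      }
    ),
    class = "bc_selection"
  )
}

# Stable ordering of search results: by lexicographic score, ties by the
# sorted added-id string.
order_by_score <- function(results, pool_ids) {
  if (length(results) == 0) return(integer(0))
  scores <- do.call(rbind, lapply(results, `[[`, "score"))
  labels <- vapply(
    results,
    function(r) paste(sort(pool_ids[r$idx]), collapse = ","),
    character(1)
  )
  do.call(order, c(unname(as.data.frame(scores)), list(labels)))
}

#' Full balance report for a set
#'
#' One-stop analysis: the fraction matrix, a verdict per criterion, the
#' minimum pairwise distance among the members, and the decodability
#' summary at the default mismatch cap. Weights omitted from the set
#' mean equal proportions.
#'
#' @param set A `bc_set` (or bare character vector of ids, taken at
#'   equal weights).
#' @param panel The `bc_panel`.
#' @param criteria Named list of `bc_criterion` (default: strong and
#'   lite).
#' @param m Mismatch cap for the decodability summary.
#' @return A `bc_report`: list with `set`, `fractions`, `verdicts`
#'   (named list), `distance` (`bc_distmat` of members, when >= 2) and
#'   `decodability`.
#' @export
analyze_set <- function(set, panel, criteria = default_criteria(), m = 2) {
  if (is.character(set)) set <- bc_set(set)
  set <- bc_set(set)
  if (inherits(criteria, "bc_criterion")) criteria <- list(criteria)
  fm <- compute_fraction_matrix(set, panel)
  verdicts <- lapply(criteria, function(cr) evaluate_criterion(fm, cr))
  names(verdicts) <- vapply(criteria, `[[`, character(1), "name")
  dm <- if (nrow(set) >= 2) set_distance(set, panel) else NULL
  dec <- if (nrow(set) >= 2) decodability_check(set, m = m, panel = panel) else NULL
  structure(
    list(set = set, fractions = fm, verdicts = verdicts,
         distance = dm, decodability = dec),
    class = "bc_report"
  )
}

#' @export
print.bc_selection <- function(x, ...) {
  cat(sprintf(
    "<set completion> %s search, %d combination(s) evaluated, %d passing\n",
    if (x$exhaustive) "exhaustive" else "beam", x$n_evaluated,
    nrow(x$candidates)
  ))
  if (nrow(x$candidates)) {
    top <- utils::head(x$candidates, 5)
    purrr::pwalk(top, function(added, weights, n_outside, max_deviation,
                               rms, pass) {
      cat(sprintf(
        "  + {%s}  outside=%d  max|f-0.25|=%.3f  rms=%.4f\n",
        paste(added, collapse = ", "), n_outside, max_deviation, rms
      ))
    })
  } else if (!is.null(x$diagnostics)) {
    d <- x$diagnostics
    cat(sprintf(
      "  no passing combination; best failing: {%s} with %d outside position(s)\n",
      paste(d$added[[1]], collapse = ", "), d$n_outside
    ))
  }
  invisible(x)
}

#' @export
print.bc_report <- function(x, ...) {
  cat(sprintf("<set report> %d member(s)\n", nrow(x$set)))
  for (v in x$verdicts) print(v)
  if (!is.null(x$distance)) {
    cat(sprintf("  member d_min = %d, d_max = %d\n",
                x$distance$d_min, x$distance$d_max))
  }
  if (!is.null(x$decodability)) {
    cat(sprintf(
      "  decodability at m = %d: no-merge %s, unique-nearest %s\n",
      x$decodability$m,
      if (x$decodability$no_merge) "holds" else "violated",
      if (x$decodability$strict_guarantee) "holds" else "not guaranteed"
    ))
  }
  invisible(x)
}
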