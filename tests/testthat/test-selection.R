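test_that("score_set is the lexicographic (outside, max dev, rms) triple", {
  qp <- quartet_panel(10)
  fm <- compute_fraction_matrix(bc_set(qp$id), qp)
  expect_equal(unname(score_set(fm)), c(0, 0, 0))

  # recomputation from raw fractions agrees
  p <- skewed_quartet_panel(10, n_skewed = 2)
  fm2 <- compute_fraction_matrix(bc_set(p$id), p)
  sc <- score_set(fm2, default_criteria()$strong)
  m <- fraction_values(fm2)
  expect_equal(sc[["n_outside"]],
               brute_classify(m, default_criteria()$strong)$n_outside)
  expect_equal(sc[["max_deviation"]], max(abs(m - 0.25)))
  expect_equal(sc[["rms"]], sqrt(mean((abs(m - 0.25))^2)))

  # the smaller single-cell deviation scores better
  pa <- skewed_quartet_panel(10, n_skewed = 1)
  fa <- compute_fraction_matrix(bc_set(pa$id, c(1, 1, 1, 1.2)), pa)
  fb <- compute_fraction_matrix(bc_set(pa$id, c(1, 1, 1, 2)), pa)
  expect_true(lex_less(score_set(fa, default_criteria()$lite),
                       score_set(fb, default_criteria()$lite)))
})

test_that("completing a homopolymer trio ranks the exact completer first", {
  p <- quartet_panel(10)
  extra <- make_random_panel(5, L = 10, min_distance = 1, seed = 30,
                             id_prefix = "N")
  stopifnot(!any(extra$seq %in% p$seq))
  panel <- bc_panel(rbind(as.data.frame(p), as.data.frame(extra)))
  problem <- selection_problem(
    bc_set(c("polyA", "polyC", "polyG")),
    k = 1, pool = c(extra$id, "polyT")
  )
  res <- complete_set(problem, panel)
  expect_true(res$exhaustive)
  expect_equal(res$n_evaluated, 6)
  expect_equal(res$candidates$added[[1]], "polyT")
  expect_equal(res$candidates$n_outside[1], 0)
  expect_equal(res$candidates$max_deviation[1], 0)
})

test_that("k = 0 reduces to a verdict on the current set", {
  p <- quartet_panel(10)
  res <- complete_set(
    selection_problem(bc_set(p$id), k = 0, pool = character(0)), p
  )
  expect_true(res$exhaustive)
  expect_equal(nrow(res$candidates), 1)
  expect_true(res$candidates$pass[1])
  expect_true(res$verdict$pass)

  res_bad <- complete_set(
    selection_problem(bc_set("polyA"), k = 0, pool = character(0)), p
  )
  expect_equal(nrow(res_bad$candidates), 0)
  expect_false(is.null(res_bad$diagnostics))
})

test_that("selection problems validate pool disjointness and weights", {
  p <- quartet_panel(10)
  expect_error(
    selection_problem(bc_set("polyA"), k = 1, pool = c("polyA", "polyT")),
    "disjoint"
  )
  expect_error(
    selection_problem(bc_set("polyA"), k = 3, pool = c("polyC", "polyT")),
    "pool"
  )
  expect_error(
    selection_problem(bc_set("polyA"), k = 1, pool = "polyT",
                      new_weights = c(-1)),
    "positive"
  )
})

test_that("exhaustive search equals naive enumeration on random problems", {
  withr::local_seed(47)
  crit <- criterion("custom", 0.1, 0.4, 0.01, 1)
  for (i in 1:12) {
    panel <- random_panel_df(sample(8:14, 1), 8)
    cur_n <- sample(2:4, 1)
    cur_ids <- sample(panel$id, cur_n)
    cur_w <- sample(1:5, cur_n, replace = TRUE)
    pool <- sample(setdiff(panel$id, cur_ids),
                   sample(4:min(12, nrow(panel) - cur_n), 1))
    k <- sample(1:min(3, length(pool)), 1)
    new_w <- if (stats::runif(1) < 0.5) rep(1, k) else sample(1:4, k, TRUE)
    problem <- selection_problem(
      bc_set(cur_ids, cur_w), k = k, pool = pool, new_weights = new_w,
      criterion = crit, max_results = 1000
    )
    res <- complete_set(problem, panel)
    expect_true(res$exhaustive)
    oracle <- brute_complete(cur_ids, cur_w, k, pool, new_w, crit, panel)
    expect_equal(res$n_evaluated, nrow(oracle))
    passing_oracle <- oracle[oracle$n_outside <= crit$max_outside, ]
    got <- res$candidates
    expect_equal(nrow(got), nrow(passing_oracle))
    if (nrow(got) > 0) {
      got_ids <- vapply(got$added, function(x) paste(sort(x), collapse = ","),
                        character(1))
      expect_equal(got_ids, passing_oracle$ids)
      expect_equal(got$n_outside, passing_oracle$n_outside)
      expect_equal(got$max_deviation, passing_oracle$max_deviation,
                   tolerance = 1e-12)
    }
  }
})

test_that("beam search is deterministic and never beats exhaustive search", {
  withr::local_seed(53)
  panel <- random_panel_df(12, 8)
  cur <- bc_set(panel$id[1:2])
  pool <- panel$id[3:12]
  crit <- criterion("custom", 0.05, 0.45, 0.01, 2)
  problem <- selection_problem(cur, k = 3, pool = pool, criterion = crit,
                               max_results = 500)
  ex <- complete_set(problem, panel)
  # forcing the beam path on the same problem
  bm1 <- complete_set(problem, panel, exhaustive_cap = 10, beam_width = 16)
  bm2 <- complete_set(problem, panel, exhaustive_cap = 10, beam_width = 16)
  expect_false(bm1$exhaustive)
  expect_identical(bm1$candidates, bm2$candidates)
  if (nrow(bm1$candidates) > 0 && nrow(ex$candidates) > 0) {
    best_ex <- unlist(ex$candidates[1, c("n_outside", "max_deviation", "rms")])
    best_bm <- unlist(bm1$candidates[1, c("n_outside", "max_deviation", "rms")])
    expect_false(lex_less(best_bm, best_ex))
  }
})

test_that("a balanced quartet can join any balanced passing set at any ratio", {
  base <- make_balanced_set(8, L = 10, seed = 61)
  quartet <- make_balanced_set(4, L = 10, seed = 62, id_prefix = "Q")
  stopifnot(!any(quartet$seq %in% base$seq))
  panel <- bc_panel(rbind(as.data.frame(base), as.data.frame(quartet)))
  for (ratio in c(0.25, 1, 3)) {
    problem <- selection_problem(
      bc_set(base$id), k = 4, pool = quartet$id,
      new_weights = rep(ratio, 4)
    )
    res <- complete_set(problem, panel)
    expect_equal(nrow(res$candidates), 1)
    expect_equal(res$candidates$max_deviation[1], 0, tolerance = 1e-12)
    expect_true(res$candidates$pass[1])
  }
})

test_that("failure diagnostics expose the best near-miss", {
  # pool of skewed barcodes only: nothing balances a single homopolymer
  p <- skewed_quartet_panel(10, n_skewed = 5)
  problem <- selection_problem(
    bc_set(p$id[1]), k = 1, pool = p$id[2:4]
  )
  res <- complete_set(problem, p)
  expect_equal(nrow(res$candidates), 0)
  expect_false(is.null(res$diagnostics))
  expect_gt(res$diagnostics$n_outside, 0)
})

test_that("analyze_set combines fractions, verdicts, distances, decodability", {
  p <- make_balanced_set(8, L = 10, seed = 63)
  rep <- analyze_set(bc_set(p$id), p)
  expect_named(rep$verdicts, c("strong", "lite"))
  expect_true(all(vapply(rep$verdicts, `[[`, logical(1), "pass")))
  expect_s3_class(rep$fractions, "bc_fractions")
  expect_false(is.null(rep$distance))
  expect_equal(rep$decodability$m, 2L)

  # bare id vector means equal weights
  rep2 <- analyze_set(p$id, p)
  expect_equal(rep2$set$weight, rep(1, 8))
  expect_equal(fraction_values(rep2$fractions),
               fraction_values(rep$fractions))
})
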