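test_that("fraction matrix matches hand-counted weighted occurrences", {
  # equal homopolymer quartet: all fractions exactly 0.25
  qp <- quartet_panel(10)
  fm <- compute_fraction_matrix(bc_set(qp$id), qp)
  expect_true(all(fm$fraction == 0.25))
  expect_equal(attr(fm, "L"), 10)

  # two 2-mers AC and AG at weights 1:3:
  # position 1: A = 1; position 2: C = 1/4, G = 3/4, A = T = 0
  toy <- bc_panel(data.frame(id = c("ac", "ag"), seq = c("AC", "AG")))
  m <- fraction_values(compute_fraction_matrix(bc_set(c("ac", "ag"),
                                                      c(1, 3)), toy))
  expect_equal(unname(m[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(m[2, ]), c(0, 0.25, 0.75, 0))
})

test_that("fractions are column-stochastic and weight-scale invariant", {
  withr::local_seed(5)
  for (i in 1:20) {
    p <- random_panel_df(sample(2:12, 1), sample(4:10, 1))
    k <- sample(2:nrow(p), 1)
    ids <- sample(p$id, k)
    w <- stats::runif(k, 0.1, 10)
    fm <- compute_fraction_matrix(bc_set(ids, w), p)
    m <- fraction_values(fm)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(rowSums(m)), rep(1, nrow(m)), tolerance = 1e-12)
    # rescaling all weights changes nothing
    m2 <- fraction_values(compute_fraction_matrix(bc_set(ids, w * 37.5), p))
    expect_equal(m, m2, tolerance = 1e-12)
  }
})

test_that("disjoint balanced quartets stay balanced at any mixing ratio", {
  qp <- quartet_panel(10)
  q2 <- make_balanced_set(4, L = 10, seed = 21, id_prefix = "X")
  stopifnot(!any(q2$seq %in% qp$seq))
  both <- bc_panel(rbind(as.data.frame(qp), as.data.frame(q2)))
  for (ratio in list(c(1, 1), c(1, 4), c(9, 5))) {
    s <- bc_set(both$id, c(rep(ratio[1], 4), rep(ratio[2], 4)))
    fm <- compute_fraction_matrix(s, both)
    expect_true(all(abs(fm$fraction - 0.25) < 1e-12))
  }
})

test_that("reweighting a balanced quartet with non-constant columns unbalances it", {
  p <- make_balanced_set(4, L = 10, seed = 3)
  fm_eq <- compute_fraction_matrix(bc_set(p$id), p)
  expect_true(all(fm_eq$fraction == 0.25))
  fm_uneq <- compute_fraction_matrix(bc_set(p$id, c(1, 4, 1, 4)), p)
  expect_gt(max(abs(fm_uneq$fraction - 0.25)), 0.1)
  expect_false(evaluate_criterion(fm_uneq, default_criteria()$strong)$pass)
})

test_that("criterion verdicts match the brute-force cell classifier", {
  withr::local_seed(17)
  for (i in 1:30) {
    p <- random_panel_df(sample(2:10, 1), sample(4:10, 1))
    ids <- sample(p$id, sample(2:nrow(p), 1))
    fm <- compute_fraction_matrix(bc_set(ids, stats::runif(length(ids), 0.2, 5)), p)
    crit <- criterion("custom",
      lower = stats::runif(1, 0.05, 0.2),
      upper = stats::runif(1, 0.3, 0.45),
      border_tol = stats::runif(1, 0, 0.02),
      max_outside = sample(0:3, 1)
    )
    v <- evaluate_criterion(fm, crit)
    oracle <- brute_classify(fraction_values(fm), crit)
    expect_equal(v$per_position$status, oracle$per_position)
    expect_equal(v$n_outside, oracle$n_outside)
    expect_equal(v$pass, oracle$n_outside <= crit$max_outside)
    expect_equal(v$n_inside + v$n_border + v$n_outside, attr(fm, "L"))
  }
})

test_that("single-barcode set fails the strong criterion at every position", {
  qp <- quartet_panel(10)
  fm <- compute_fraction_matrix(bc_set("polyA"), qp)
  v <- evaluate_criterion(fm, default_criteria()$strong)
  expect_equal(v$n_outside, 10)
  expect_false(v$pass)
  expect_equal(v$max_deviation, 0.75)
})

test_that("the violation cap controls pass/fail around 3 outside positions", {
  p <- skewed_quartet_panel(10, n_skewed = 3)
  fm <- compute_fraction_matrix(bc_set(p$id), p)
  for (cap in 0:4) {
    v <- evaluate_criterion(fm, criterion("strong", 0.15, 0.35, 0.01, cap))
    expect_equal(v$n_outside, 3)
    expect_equal(v$pass, cap >= 3)
  }
  # offending cells are the overrepresented A (0.5) and missing T (0)
  v <- evaluate_criterion(fm, default_criteria()$strong)
  expect_equal(sort(unique(v$offending$position)), 1:3)
  expect_setequal(unique(v$offending$base), c("A", "T"))
})

test_that("default criteria nest correctly and round-trip through YAML", {
  crits <- default_criteria()
  expect_lt(crits$lite$lower, crits$strong$lower)
  expect_gt(crits$lite$upper, crits$strong$upper)
  expect_equal(crits$strong$max_outside, 0)
  expect_equal(crits$lite$max_outside, 0)
  expect_equal(default_criteria(max_outside = 2)$strong$max_outside, 2)

  path <- withr::local_tempfile(fileext = ".yaml")
  custom <- criterion("custom", 0.18, 0.32, 0.005, 1)
  write_criterion(custom, path)
  expect_equal(read_criterion(path), custom)
})

test_that("criterion validation rejects corridors not containing 0.25", {
  expect_error(criterion(lower = 0.3, upper = 0.4), "0.25")
  expect_error(criterion(lower = 0.1, upper = 0.2), "0.25")
  expect_error(criterion(border_tol = -0.01), "non-negative")
  expect_error(criterion(max_outside = -1), "non-negative")
})

test_that("derive_corridor_from_sets takes the envelope of reference fractions", {
  qp <- quartet_panel(10)
  # perfectly balanced reference -> degenerate corridor [0.25, 0.25]
  cr <- derive_corridor_from_sets(bc_set(qp$id), qp)
  expect_equal(cr$lower, 0.25)
  expect_equal(cr$upper, 0.25)
  expect_equal(cr$border_tol, 0) # clamped for the degenerate corridor

  # a degenerate corridor still classifies sensibly: balanced matrix is
  # all border (on the bound), an unbalanced one is outside
  fm <- compute_fraction_matrix(bc_set(qp$id), qp)
  v <- evaluate_criterion(fm, cr)
  expect_equal(v$n_outside, 0)
  expect_true(v$pass)

  # toy reference with fractions {0, 0.25, 0.5}: envelope = min/max
  p <- skewed_quartet_panel(8, n_skewed = 2)
  cr2 <- derive_corridor_from_sets(bc_set(p$id), p)
  vals <- compute_fraction_matrix(bc_set(p$id), p)$fraction
  expect_equal(cr2$lower, min(vals))
  expect_equal(cr2$upper, max(vals))
  expect_error(derive_corridor_from_sets(list(), qp), "at least one")
})

test_that("make_balanced_set passes any corridor containing 0.25 with zero violations", {
  withr::local_seed(31)
  for (i in 1:5) {
    p <- make_balanced_set(sample(c(4, 8, 12), 1), L = sample(c(6, 10), 1),
                           seed = sample.int(1e6, 1))
    fm <- compute_fraction_matrix(bc_set(p$id), p)
    crit <- criterion("custom",
      lower = stats::runif(1, 0, 0.24),
      upper = stats::runif(1, 0.26, 1),
      border_tol = 0.005
    )
    v <- evaluate_criterion(fm, crit)
    expect_equal(v$n_outside, 0)
    expect_equal(v$n_border, 0)
    expect_true(v$pass)
  }
})

test_that("tidy and glance expose fractions and verdicts as tibbles", {
  qp <- quartet_panel(6)
  fm <- compute_fraction_matrix(bc_set(qp$id), qp)
  td <- generics::tidy(fm)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("position", "base", "fraction"))
  expect_equal(nrow(td), 6 * 4)
  gl <- generics::glance(fm)
  expect_equal(gl$max_deviation, 0)
  v <- evaluate_criterion(fm, default_criteria()$lite)
  expect_equal(nrow(generics::tidy(v)), 6)
  expect_true(generics::glance(v)$pass)
})
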