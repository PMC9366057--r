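test_that("fisher_z_test matches the transform formula and handles edges", {
  # exactly zero sample correlation -> z = 0, p = 1
  x0 <- cbind(x = c(1, -1, 1, -1, 1, -1, 1, -1),
              y = c(1, 1, -1, -1, 1, 1, -1, -1))
  r0 <- fisher_z_test(x0, "x", "y")
  expect_equal(r0$partial_r, 0)
  expect_equal(r0$z_stat, 0)
  expect_equal(r0$p_value, 1)

  # sample correlation exactly 0.5 at n = 100: z = atanh(0.5) * sqrt(97)
  x5 <- exact_corr_pair(100, 0.5, seed = 3)
  r5 <- fisher_z_test(x5, "x", "y")
  expect_equal(r5$partial_r, 0.5, tolerance = 1e-10)
  expect_equal(r5$z_stat, atanh(0.5) * sqrt(97), tolerance = 1e-8)
  expect_lt(r5$p_value, 1e-6)

  # numerically saturated correlation
  xs <- cbind(x = 1:30, y = 2 * (1:30) + 3)
  rs <- fisher_z_test(xs + 0, "x", "y")
  expect_true(rs$saturated)
  expect_equal(rs$p_value, 0)

  # preconditions
  expect_error(fisher_z_test(x0[1:3, ], "x", "y"), "insufficient")
  expect_error(fisher_z_test(x0, "x", "x"), "differ")
})

test_that("conditioning removes common-cause dependence (x <- z -> y)", {
  n <- 2000
  marg_rej <- cond_rej <- 0L
  reps <- 60
  for (s in seq_len(reps)) {
    set.seed(s)
    z <- rnorm(n)
    x <- 0.8 * z + rnorm(n, sd = 0.6)
    y <- 0.8 * z + rnorm(n, sd = 0.6)
    dat <- cbind(x = x, y = y, z = z)
    if (fisher_z_test(dat, "x", "y")$p_value < 0.05) marg_rej <- marg_rej + 1L
    if (fisher_z_test(dat, "x", "y", "z")$p_value < 0.05) cond_rej <- cond_rej + 1L
  }
  expect_equal(marg_rej, reps)               # marginally dependent
  expect_lte(cond_rej / reps, 0.15)          # conditional rejection ~ alpha
})

test_that("discover_neighbors finds Markov-blanket members on a chain", {
  # A -> B -> C, strong coefficients: B's neighbors are {A, C}
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    a <- rnorm(5000)
    b <- 0.9 * a + rnorm(5000, sd = 0.5)
    cc <- 0.9 * b + rnorm(5000, sd = 0.5)
    nb <- discover_neighbors(cbind(A = a, B = b, C = cc), "B")
    if (setequal(nb, c("A", "C"))) hits <- hits + 1L
  }
  expect_gte(hits, 18L)

  # single-variable data
  expect_identical(discover_neighbors(matrix(rnorm(50), ncol = 1,
                                             dimnames = list(NULL, "A")), "A"),
                   character(0))
})

test_that("discover_neighbors false-positive rate is alpha-calibrated", {
  # all-independent columns: expected neighbor count ~ alpha * (p - 1)
  p <- 6; alpha <- 0.05
  sizes <- replicate(120, {
    x <- matrix(rnorm(2000 * p), ncol = p,
                dimnames = list(NULL, LETTERS[1:p]))
    length(discover_neighbors(x, "A", alpha = alpha))
  })
  expect_lt(mean(sizes), 3 * alpha * (p - 1) + 0.05)
})

test_that("build_skeleton: AND rule, calibration, and small-n guard", {
  set.seed(77)
  # independent columns: few edges at alpha = 0.05
  counts <- replicate(30, {
    x <- matrix(rnorm(2000 * 5), ncol = 5, dimnames = list(NULL, LETTERS[1:5]))
    nrow(build_skeleton(x, alpha = 0.05)$edges)
  })
  expect_lt(mean(counts), 0.05 * choose(5, 2) + 0.3)

  # 13 columns, 10 rows: conditioning quickly infeasible, but no crash
  x10 <- matrix(rnorm(10 * 13), ncol = 13, dimnames = list(NULL, mmpi_scales()))
  expect_s3_class(build_skeleton(x10, alpha = 0.05), "bn_skeleton")

  # recovery: preset healthy network skeleton at n = 5000, averaged F1
  pre <- mmpi2_preset()
  true_pairs <- apply(pre$healthy$dag$arcs, 1,
                      function(e) paste(sort(e), collapse = "-"))
  f1s <- vapply(1:5, function(s) {
    x <- ancestral_sample(pre$healthy, 5000, seed = 120 + s)
    sk <- build_skeleton(x)
    learned_pairs <- apply(sk$edges, 1,
                           function(e) paste(sort(e), collapse = "-"))
    tp <- length(intersect(learned_pairs, true_pairs))
    2 * tp / (length(learned_pairs) + length(true_pairs))
  }, numeric(1))
  expect_gte(mean(f1s), 0.9)
})

test_that("hill_climb reaches the enumerated optimum on small problems", {
  # one variable -> empty dag
  x1 <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "A"))
  expect_identical(nrow(hill_climb(x1)$arcs), 0L)

  # two correlated columns: arc found, score equals best of the 3 DAGs
  x <- ancestral_sample(toy_xy_network(), 1000, seed = 21)
  d2 <- hill_climb(x)
  expect_identical(nrow(d2$arcs), 1L)
  best2 <- max(vapply(oracle_enumerate_dags(c("X", "Y")),
                      function(d) bic_score(d, x), numeric(1)))
  expect_equal(bic_score(d2, x), best2, tolerance = 1e-8)

  # 3-node instances: greedy equals the exhaustive maximum (25 DAGs)
  all3 <- NULL
  for (s in 1:10) {
    net <- random_gbn(3, seed = 300 + s, expected_arcs = 2)
    x3 <- ancestral_sample(net, 400, seed = 600 + s)
    if (is.null(all3)) all3 <- oracle_enumerate_dags(colnames(x3))
    hc <- hill_climb(x3)
    best <- max(vapply(all3, function(d) bic_score(d, x3), numeric(1)))
    expect_equal(bic_score(hc, x3), best, tolerance = 1e-8)
  }
})

test_that("hill_climb honors the skeleton constraint and is deterministic", {
  net <- random_gbn(5, seed = 4, expected_arcs = 5)
  x <- ancestral_sample(net, 800, seed = 5)
  skel <- build_skeleton(x)
  hc <- hill_climb(moment_stats(x), constraint = skel)
  allowed <- apply(skel$edges, 1, function(e) paste(sort(e), collapse = "-"))
  used <- apply(hc$arcs, 1, function(e) paste(sort(e), collapse = "-"))
  expect_true(all(used %in% allowed))

  # on 3-node instances the constrained optimum is also exhaustive over
  # skeleton-respecting DAGs
  for (s in 1:5) {
    net3 <- random_gbn(3, seed = 40 + s, expected_arcs = 2)
    x3 <- ancestral_sample(net3, 500, seed = 50 + s)
    sk3 <- build_skeleton(x3)
    ok3 <- apply(sk3$edges, 1, function(e) paste(sort(e), collapse = "-"))
    cands <- Filter(function(d) {
      prs <- apply(d$arcs, 1, function(e) paste(sort(e), collapse = "-"))
      all(prs %in% ok3)
    }, oracle_enumerate_dags(colnames(x3)))
    best <- max(vapply(cands, function(d) bic_score(d, x3), numeric(1)))
    hc3 <- hill_climb(moment_stats(x3), constraint = sk3)
    expect_equal(bic_score(hc3, x3), best, tolerance = 1e-8)
  }

  # determinism: identical input, identical output
  expect_identical(hill_climb(x), hill_climb(x))
})

test_that("learn_structure output is skeleton-consistent, acyclic, stable", {
  pre <- mmpi2_preset()
  x <- ancestral_sample(pre$schizophrenia, 5000, seed = 9)
  d1 <- learn_structure(x)
  d2 <- learn_structure(x)
  expect_identical(d1$arcs, d2$arcs)
  expect_silent(topological_order(d1))  # acyclic by construction
  expect_lte(shd_cpdag(d1, pre$schizophrenia$dag), 4)

  # independent columns: near-empty graph
  set.seed(11)
  xi <- matrix(rnorm(2000 * 13), ncol = 13, dimnames = list(NULL, mmpi_scales()))
  expect_lte(nrow(learn_structure(xi)$arcs),
             ceiling(choose(13, 2) * 0.05 * 2) + 2)
})

test_that("structure recovery improves with sample size", {
  pre <- mmpi2_preset()
  med_shd <- vapply(c(500, 2000, 8000), function(n) {
    shds <- vapply(1:5, function(s) {
      x <- ancestral_sample(pre$healthy, n, seed = 1000 * s + n)
      shd_cpdag(learn_structure(x), pre$healthy$dag)
    }, numeric(1))
    median(shds)
  }, numeric(1))
  expect_true(all(diff(med_shd) <= 0))
})
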