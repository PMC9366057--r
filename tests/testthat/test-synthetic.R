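test_that("make_random_dag hits its arc-count target and edge cases", {
  expect_identical(nrow(make_random_dag(5, 0, seed = 1)$arcs), 0L)
  expect_identical(nrow(make_random_dag(5, 10, seed = 1)$arcs), 10L)

  counts <- vapply(1:300, function(s)
    nrow(make_random_dag(6, 5, seed = s)$arcs), numeric(1))
  npairs <- choose(6, 2)
  se <- sqrt(npairs * (5 / npairs) * (1 - 5 / npairs) / 300)
  expect_lt(abs(mean(counts) - 5), 3 * se)

  # acyclic by construction (topological_order would error otherwise)
  for (s in 1:10) expect_silent(topological_order(make_random_dag(8, 14, seed = s)))
})

test_that("make_random_network is seed-reproducible with sane correlations", {
  d <- make_random_dag(6, 8, seed = 2)
  n1 <- make_random_network(d, seed = 3)
  n2 <- make_random_network(d, seed = 3)
  expect_equal(n1$cpds, n2$cpds)

  # empty dag -> all orphans
  n0 <- make_random_network(new_dag(LETTERS[1:4]), seed = 4)
  expect_true(all(vapply(n0$cpds, function(cp) length(cp$parents) == 0, TRUE)))

  # implied correlations finite and inside (-1, 1)
  for (s in 1:10) {
    net <- random_gbn(7, seed = 500 + s, expected_arcs = 10)
    rr <- cov2cor(to_joint_mvn(net)$sigma)
    off <- rr[upper.tri(rr)]
    expect_true(all(is.finite(off)) && all(abs(off) < 1))
  }
})

test_that("ancestral_sample: determinism, canonical columns, degenerate case", {
  net <- random_gbn(5, seed = 8)
  expect_identical(ancestral_sample(net, 50, seed = 9),
                   ancestral_sample(net, 50, seed = 9))
  expect_identical(colnames(ancestral_sample(net, 3, seed = 1)), net$dag$nodes)

  # all-zero sigma, no parents: n identical rows of intercepts
  d <- new_dag(c("A", "B"))
  g <- new_gbn(d, list(A = list(parents = character(0), beta = numeric(0),
                                intercept = 2, sigma = 0),
                       B = list(parents = character(0), beta = numeric(0),
                                intercept = -1, sigma = 0)))
  xs <- ancestral_sample(g, 4, seed = 1)
  expect_equal(unname(xs), matrix(rep(c(2, -1), each = 4), 4))
})

test_that("mmpi2_preset hits its published calibration targets", {
  pre <- mmpi2_preset()
  ch <- cov2cor(to_joint_mvn(pre$healthy)$sigma)
  cs <- cov2cor(to_joint_mvn(pre$schizophrenia)$sigma)
  expect_equal(ch["Pt", "D"], 0.74, tolerance = 0.02)
  expect_equal(ch["Pd", "Ma"], 0.61, tolerance = 0.02)
  expect_equal(ch["F", "Hs"], 0.55, tolerance = 0.02)
  expect_equal(cs["Pt", "D"], 0.29, tolerance = 0.02)
  expect_equal(cs["Pd", "Ma"], 0.41, tolerance = 0.02)
  expect_equal(cs["F", "Hs"], 0.63, tolerance = 0.02)

  # marginal moments match the calibration table exactly
  mom <- mmpi_tscore_moments()
  jh <- to_joint_mvn(pre$healthy)
  js <- to_joint_mvn(pre$schizophrenia)
  expect_equal(jh$mean[["Pt"]], 57.81, tolerance = 1e-6)
  expect_equal(js$mean[["Pt"]], 54.00, tolerance = 1e-6)
  expect_equal(unname(jh$mean), unname(mom[, "mean_healthy"]), tolerance = 1e-9)
  expect_equal(sqrt(diag(js$sigma)), setNames(mom[, "sd_schizophrenia"],
                                              mmpi_scales()), tolerance = 1e-9)

  # named arcs present with the declared orientations
  has_arc <- function(net, from, to)
    any(net$dag$arcs[, 1] == from & net$dag$arcs[, 2] == to)
  for (a in list(c("L", "K"), c("K", "Hy"), c("Hs", "Hy"), c("Pt", "Sc"),
                 c("F", "Sc"), c("D", "Si"), c("Pd", "Pt"))) {
    expect_true(has_arc(pre$healthy, a[1], a[2]))
    expect_true(has_arc(pre$schizophrenia, a[1], a[2]))
  }
  expect_true(has_arc(pre$healthy, "F", "Hs"))      # strong in healthy
  expect_true(has_arc(pre$schizophrenia, "Hs", "Sc"))  # patient-specific
  expect_false(has_arc(pre$healthy, "Hs", "Sc"))
  expect_identical(nrow(pre$healthy$dag$arcs), 10L)

  # rescaling marginals leaves the correlation structure untouched:
  # standardized and rescaled networks imply identical correlations
  expect_equal(cov2cor(jh$sigma), cov2cor(cov2cor(jh$sigma)), tolerance = 1e-12)
})

test_that("make_two_group_study is reproducible with sensible demographics", {
  cfg <- study_config(n_per_group = 120)
  c1 <- make_two_group_study(cfg, seed = 5)
  c2 <- make_two_group_study(cfg, seed = 5)
  expect_identical(c1$profiles, c2$profiles)
  expect_identical(c1$demographics, c2$demographics)
  expect_identical(table(c1$labels), table(factor(rep(0:1, each = 120))))

  expect_true(all(c1$demographics$age >= 16 & c1$demographics$age <= 70))
  expect_true(all(c1$demographics$education >= 0))
  expect_true(all(c1$demographics$gender %in% 0:1))

  # zero confounding: pre-matching SMDs small on average
  smds <- vapply(1:10, function(s) {
    co <- make_two_group_study(study_config(n_per_group = 200), seed = 600 + s)
    abs(standardized_mean_diff(co$demographics$age, co$labels))
  }, numeric(1))
  expect_lt(mean(smds), 0.1)

  # identical networks for both groups: classifier sits at chance
  pre <- mmpi2_preset()
  cfg_null <- study_config(n_per_group = 150,
                           networks = list(healthy = pre$healthy,
                                           schizophrenia = pre$healthy))
  null_co <- make_two_group_study(cfg_null, seed = 9)
  er <- evaluate_rsscv(null_co, iterations = 5, seed = 10)
  expect_lt(abs(er$accuracy_mean - 0.5), 0.1)
})
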