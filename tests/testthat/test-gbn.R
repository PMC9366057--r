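test_that("fit_parameters matches lm() and recovers generating parameters", {
  # degenerate constant node
  d1 <- new_dag("X")
  g1 <- fit_parameters(d1, matrix(50, 20, 1, dimnames = list(NULL, "X")))
  expect_equal(g1$cpds$X$intercept, 50)
  expect_equal(g1$cpds$X$sigma, 0)

  # Y = 2X + 1 + N(0,1): ML fit equals OLS (independent lm oracle), and
  # recovers truth within standard-error-based tolerances at n = 10,000
  x <- ancestral_sample(toy_xy_network(), 10000, seed = 42)
  fit <- fit_parameters(toy_xy_network()$dag, x)
  lmfit <- lm(x[, "Y"] ~ x[, "X"])
  expect_equal(unname(fit$cpds$Y$beta), unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(fit$cpds$Y$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  expect_equal(fit$cpds$Y$sigma^2,
               mean(residuals(lmfit)^2), tolerance = 1e-10)  # ML denominator n
  expect_lt(abs(fit$cpds$Y$beta - 2), 0.05)
  expect_lt(abs(fit$cpds$Y$intercept - 1), 0.6)
  expect_lt(abs(fit$cpds$Y$sigma - 1), 0.05)

  # reversed arc fits fine and gives the identical total log-likelihood
  rev_dag <- new_dag(c("X", "Y"), rbind(c("Y", "X")))
  fit_rev <- fit_parameters(rev_dag, x)
  ll <- function(g) sum(log_density(g, x))
  expect_equal(ll(fit), ll(fit_rev), tolerance = 1e-8)
})

test_that("fit_parameters is exact on noiseless data and flags bad designs", {
  dag <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  set.seed(7)
  a <- rnorm(200)
  b <- 1.5 * a - 2
  cc <- 0.5 * b + 3
  x <- cbind(A = a, B = b, C = cc)
  g <- fit_parameters(dag, x)
  expect_equal(unname(g$cpds$B$beta), 1.5, tolerance = 1e-10)
  expect_equal(g$cpds$B$sigma, 0, tolerance = 1e-10)
  expect_equal(unname(g$cpds$C$beta), 0.5, tolerance = 1e-10)
  expect_equal(g$cpds$C$sigma, 0, tolerance = 1e-6)

  # collinear parents -> singular design error naming the node
  dag2 <- new_dag(c("A", "B", "C"), rbind(c("A", "C"), c("B", "C")))
  x2 <- cbind(A = a, B = 2 * a, C = cc)
  expect_error(fit_parameters(dag2, x2), "singular.*'C'")
  expect_error(fit_parameters(dag, x[0, , drop = FALSE]), "zero rows|more rows")
})

test_that("log_density equals the closed-form joint MVN density", {
  # standard normal at its mode
  g <- new_gbn(new_dag("X"), list(X = list(parents = character(0),
                                           beta = numeric(0),
                                           intercept = 0, sigma = 1)))
  expect_equal(log_density(g, c(X = 0)), -0.5 * log(2 * pi), tolerance = 1e-12)

  # random networks, p up to 13: factorized density == joint MVN oracle
  for (p in c(2, 5, 13)) {
    net <- random_gbn(p, seed = p * 17, expected_arcs = 2 * p)
    j <- to_joint_mvn(net)
    set.seed(p)
    xs <- matrix(rnorm(100 * p, sd = 2), 100, p,
                 dimnames = list(NULL, net$dag$nodes))
    expect_equal(log_density(net, xs),
                 oracle_mvn_logdens(j$mean, j$sigma, xs), tolerance = 1e-8)
  }

  # location equivariance: shifting profile and intercepts together
  net <- toy_xy_network()
  shifted <- net
  # translate the joint by +10 on every node: c_j -> c_j + 10(1 - sum beta_j)
  shifted$cpds$X$intercept <- net$cpds$X$intercept + 10
  shifted$cpds$Y$intercept <- net$cpds$Y$intercept + 10 * (1 - net$cpds$Y$beta[["X"]])
  pr <- c(X = 0.3, Y = 1.7)
  expect_equal(log_density(net, pr), log_density(shifted, pr + 10),
               tolerance = 1e-12)
})

test_that("sigma = 0 handling: -Inf off the deterministic value, error on it", {
  dag <- new_dag(c("X", "Y"), rbind(c("X", "Y")))
  g <- new_gbn(dag, list(
    X = list(parents = character(0), beta = numeric(0), intercept = 0, sigma = 1),
    Y = list(parents = "X", beta = c(X = 2), intercept = 0, sigma = 0)))
  expect_identical(log_density(g, c(X = 1, Y = 3)), -Inf)
  expect_error(log_density(g, c(X = 1, Y = 2)), "degenerate")
})

test_that("to_joint_mvn gives the closed-form joint and matches sampling", {
  j <- to_joint_mvn(toy_xy_network())
  expect_equal(unname(j$mean), c(0, 1), tolerance = 1e-12)
  expect_equal(unname(j$sigma), matrix(c(1, 2, 2, 5), 2), tolerance = 1e-12)

  # empty-arc network: diagonal covariance
  d <- new_dag(c("A", "B"))
  g <- new_gbn(d, list(A = list(parents = character(0), beta = numeric(0),
                                intercept = 1, sigma = 2),
                       B = list(parents = character(0), beta = numeric(0),
                                intercept = -1, sigma = 0.5)))
  expect_equal(unname(to_joint_mvn(g)$sigma),
               diag(c(4, 0.25)), tolerance = 1e-12)

  # ancestral sampling moments agree with the joint within 3 MC SEs
  net <- random_gbn(6, seed = 5, expected_arcs = 8)
  j2 <- to_joint_mvn(net)
  n <- 200000
  xs <- ancestral_sample(net, n, seed = 6)
  se_mean <- sqrt(diag(j2$sigma) / n)
  expect_true(all(abs(colMeans(xs) - j2$mean) < 3 * se_mean + 1e-12))
  emp_cov <- cov(xs) * (n - 1) / n
  # covariance entries: normal-theory SE ~ sqrt((s_ii s_jj + s_ij^2)/n)
  se_cov <- sqrt((outer(diag(j2$sigma), diag(j2$sigma)) + j2$sigma^2) / n)
  expect_true(all(abs(emp_cov - j2$sigma) < 3.5 * se_cov + 1e-12))
})

test_that("BIC: penalty dominates null arcs, score-equivalent, decomposable", {
  # independent columns: empty graph beats X->Y in nearly every replicate
  wins <- 0L
  for (s in 1:50) {
    set.seed(s)
    x <- cbind(X = rnorm(2000), Y = rnorm(2000))
    empty <- new_dag(c("X", "Y"))
    arc <- new_dag(c("X", "Y"), rbind(c("X", "Y")))
    if (bic_score(empty, x) > bic_score(arc, x)) wins <- wins + 1L
  }
  expect_gte(wins, 48L)

  # Markov-equivalent 2-node DAGs score identically
  x <- ancestral_sample(toy_xy_network(), 500, seed = 9)
  expect_equal(bic_score(new_dag(c("X", "Y"), rbind(c("X", "Y"))), x),
               bic_score(new_dag(c("X", "Y"), rbind(c("Y", "X"))), x),
               tolerance = 1e-8)

  # equivalence classes on 3 nodes: all members share one score
  set.seed(31)
  x3 <- cbind(A = rnorm(300), B = rnorm(300), C = rnorm(300))
  x3[, "B"] <- 0.8 * x3[, "A"] + rnorm(300, sd = 0.7)
  x3[, "C"] <- -0.5 * x3[, "B"] + rnorm(300, sd = 0.9)
  chain1 <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  chain2 <- new_dag(c("A", "B", "C"), rbind(c("B", "A"), c("B", "C")))
  chain3 <- new_dag(c("A", "B", "C"), rbind(c("C", "B"), c("B", "A")))
  s1 <- bic_score(chain1, x3)
  expect_equal(s1, bic_score(chain2, x3), tolerance = 1e-8)
  expect_equal(s1, bic_score(chain3, x3), tolerance = 1e-8)
  collider <- new_dag(c("A", "B", "C"), rbind(c("A", "B"), c("C", "B")))
  expect_false(isTRUE(all.equal(s1, bic_score(collider, x3), tolerance = 1e-8)))

  # adding an arc never decreases the unpenalized log-likelihood term
  ll_term <- function(dag) {
    g <- fit_parameters(dag, x3)
    sum(log_density(g, x3))
  }
  expect_gte(ll_term(collider) + 1e-9,
             ll_term(new_dag(c("A", "B", "C"), rbind(c("A", "B")))))

  # decomposability: total equals sum over families; an arc edit touches
  # only the child family's contribution
  st <- moment_stats(x3)
  full <- bic_score(chain1, st)
  no_bc <- bic_score(new_dag(c("A", "B", "C"), rbind(c("A", "B"))), st)
  str_ <- arc_strength(chain1, x3)
  expect_equal(full - no_bc, unname(str_["B->C"]), tolerance = 1e-10)
})

test_that("arc strength signs track true coupling", {
  # strongly coupled pair -> strictly positive strength
  set.seed(12)
  a <- rnorm(2000)
  x <- cbind(X = a, Y = 0.95 * a + rnorm(2000, sd = sqrt(1 - 0.95^2)))
  d <- new_dag(c("X", "Y"), rbind(c("X", "Y")))
  expect_gt(arc_strength(d, x)["X->Y"], 0)

  # keys exist only for arcs in the dag
  expect_identical(names(arc_strength(d, x)), "X->Y")

  # independent pair forced as an arc -> negative strength almost always
  neg <- 0L
  for (s in 1:50) {
    set.seed(100 + s)
    xi <- cbind(X = rnorm(2000), Y = rnorm(2000))
    if (arc_strength(d, xi)["X->Y"] < 0) neg <- neg + 1L
  }
  expect_gte(neg, 48L)
})
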