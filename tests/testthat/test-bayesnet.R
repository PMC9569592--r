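# Bayesian-network scoring, structure learning, parameters, inference.

test_that("AIC score matches the closed form on a single binary node", {
  d <- data.frame(a = factor(rep(c("x", "y"), c(6, 4))))
  expect_equal(aic_score(bn_dag("a"), d), 6 * log(0.6) + 4 * log(0.4) - 1,
               tolerance = 1e-12)
})

test_that("the network score decomposes into family scores", {
  set.seed(31)
  d <- data.frame(a = factor(sample(c("x", "y"), 300, TRUE)),
                  b = factor(sample(c("p", "q", "r"), 300, TRUE)),
                  c = factor(sample(c("u", "v"), 300, TRUE)))
  dag <- bn_dag(c("a", "b", "c"), rbind(c("a", "b"), c("c", "b")))
  by_family <- fusionlab:::family_score("a", character(0), d) +
    fusionlab:::family_score("b", c("a", "c"), d) +
    fusionlab:::family_score("c", character(0), d)
  expect_equal(aic_score(dag, d), by_family, tolerance = 1e-12)
})

test_that("an edge between independent high-arity columns lowers the score", {
  for (s in 1:5) {
    set.seed(100 + s)
    d <- data.frame(a = factor(sample(c("x", "y", "z"), 2000, TRUE)),
                    b = factor(sample(c("p", "q", "r", "t"), 2000, TRUE)))
    empty <- aic_score(bn_dag(c("a", "b")), d)
    with_edge <- aic_score(bn_dag(c("a", "b"), rbind(c("a", "b"))), d)
    expect_lt(with_edge, empty)
  }
})

test_that("tabu search attains the exhaustive-enumeration optimum on 3 nodes", {
  dags3 <- all_dags(c("a", "b", "c"))
  expect_length(dags3, 25)
  set.seed(1)
  for (rep in 1:3) {
    a <- sample(c("x", "y"), 1500, TRUE)
    b <- ifelse(runif(1500) < 0.8, a, sample(c("x", "y"), 1500, TRUE))
    d <- data.frame(a = factor(a), b = factor(b),
                    c = factor(sample(c("p", "q", "r"), 1500, TRUE)))
    learned <- learn_structure(d)
    expect_equal(attr(learned, "score"), best_exhaustive_score(d),
                 tolerance = 1e-9)
  }
})

test_that("strong pairwise dependence is recovered as an adjacency", {
  set.seed(8)
  a <- sample(c("x", "y"), 2000, TRUE)
  b <- ifelse(runif(2000) < 0.85, a, sample(c("x", "y"), 2000, TRUE))
  d <- data.frame(a = factor(a), b = factor(b))
  learned <- learn_structure(d)
  expect_equal(dag_skeleton(learned), "a~b")
})

test_that("a constant dataset yields an empty graph with a warning", {
  d <- data.frame(a = factor(rep("x", 50), levels = c("x", "y")),
                  b = factor(rep("p", 50), levels = c("p", "q")))
  expect_warning(dag <- learn_structure(d), "constant")
  expect_equal(nrow(dag_edges(dag)), 0)
})

test_that("CPTs are Dirichlet posterior means and strictly positive", {
  # root binary node, counts (0, 10), iss = 1 -> (0.5/11, 10.5/11)
  d <- data.frame(a = factor(rep("y", 10), levels = c("x", "y")))
  net <- estimate_parameters(bn_dag("a"), d, iss = 1)
  expect_equal(as.vector(net$cpts$a), c(0.5 / 11, 10.5 / 11),
               tolerance = 1e-12)

  # no data at a parent configuration -> uniform from the prior alone
  d2 <- data.frame(a = factor(c("x", "x"), levels = c("x", "y")),
                   b = factor(c("p", "q"), levels = c("p", "q")))
  net2 <- estimate_parameters(bn_dag(c("a", "b"), rbind(c("a", "b"))), d2[0, ],
                              iss = 1)
  expect_true(all(abs(net2$cpts$b - 0.5) < 1e-12))

  # iss -> 0 recovers maximum-likelihood frequencies when counts positive
  d3 <- data.frame(a = factor(rep(c("x", "y"), c(3, 7))))
  net3 <- estimate_parameters(bn_dag("a"), d3, iss = 1e-10)
  expect_equal(as.vector(net3$cpts$a), c(0.3, 0.7), tolerance = 1e-9)

  # every column of a conditional CPT sums to one
  set.seed(2)
  d4 <- data.frame(a = factor(sample(c("x", "y"), 60, TRUE)),
                   b = factor(sample(c("p", "q", "r"), 60, TRUE)))
  net4 <- estimate_parameters(bn_dag(c("a", "b"), rbind(c("a", "b"))), d4)
  expect_equal(unname(colSums(net4$cpts$b)), c(1, 1), tolerance = 1e-9)
  expect_true(all(net4$cpts$b > 0))
})

test_that("the Markov blanket covers parents, children and spouses", {
  dag <- bn_dag(c("a", "b", "c", "d", "e"),
                rbind(c("a", "c"), c("c", "d"), c("b", "d")))
  expect_equal(markov_blanket(dag, "c"), c("a", "b", "d"))
  expect_equal(markov_blanket(dag, "e"), character(0))
})

test_that("likelihood weighting matches exact enumeration on a fixed net", {
  net <- make_clinical_net(seed = 42)
  for (ev in list(list(), list(bethesda = "VI"),
                  list(bethesda = "III", age_band = ">60"))) {
    exact <- query_risk(net, ev, method = "exact")
    lw <- query_risk(net, ev, n_draws = 1e5, seed = 3, method = "lw")
    expect_lt(abs(lw - exact), 0.01)
  }
})

test_that("evidence outside the risk Markov blanket is ignored with warning", {
  net <- make_clinical_net(seed = 42)
  base <- query_risk(net, list(bethesda = "VI"), method = "exact")
  expect_warning(
    with_sex <- query_risk(net, list(bethesda = "VI", sex = "F"),
                           method = "exact"),
    "Markov blanket"
  )
  expect_equal(with_sex, base, tolerance = 1e-12)
})

test_that("an isolated risk node answers with its marginal CPT entry", {
  d <- data.frame(risk = factor(rep(c("benign", "malignant"), c(30, 10))),
                  sex = factor(sample(rep(c("F", "M"), 20))))
  net <- estimate_parameters(bn_dag(c("risk", "sex")), d, iss = 1)
  marginal <- as.vector(net$cpts$risk["malignant"])
  expect_warning(q <- query_risk(net, list(sex = "F"), method = "exact"),
                 "Markov blanket")
  expect_equal(q, marginal, tolerance = 1e-12)
  expect_equal(query_risk(net, list(), n_draws = 2e4, seed = 1), marginal,
               tolerance = 0.02)
})

test_that("rejected inputs carry informative messages", {
  d <- data.frame(a = factor(c("x", "y")))
  expect_error(aic_score(bn_dag("a"), d[0, , drop = FALSE]), "empty")
  expect_error(learn_structure(d["a"]), "2 columns")
  expect_error(estimate_parameters(bn_dag("a"), d, iss = 0), "iss")
  net <- make_clinical_net(seed = 42)
  expect_error(query_risk(net, list(bethesda = "IX")), "not a level")
})
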