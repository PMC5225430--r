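# CRF potentials, brute-force distribution, message passing, training,
# baselines.

test_that("clique potential counts pairwise patterns as documented", {
  # triangle A<B<C in one clique
  g <- graph_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  g <- classify_edges(g, "CCC")
  tr <- build_clique_tree(enumerate_maximal_cliques(g))
  X <- matrix(0, 3, 2)
  inst <- build_instance(g, tr, X)

  zero <- crf_parameters(lambda1 = c(0, 0), omega = rep(0, 4))
  for (lab in list(c(0, 0, 0), c(1, 0, 1), c(1, 1, 1))) {
    expect_identical(clique_log_potential(inst, 1, lab, zero), 0)
  }

  om <- c(`00` = 1, `01` = 20, `10` = 300, `11` = 4000)
  p <- crf_parameters(lambda1 = c(0, 0), omega = om)
  # labels (0,1,1): connections AB=01, AC=01, BC=11
  expect_equal(clique_log_potential(inst, 1, c(0, 1, 1), p),
               20 + 20 + 4000)
  # ordered patterns: (1,0,0) gives AB=10, AC=10, BC=00
  expect_equal(clique_log_potential(inst, 1, c(1, 0, 0), p),
               300 + 300 + 1)
  # 3-residue clique enumerates 2^3 = 8 joint labelings
  expect_identical(nrow(inst$conf[[1]]), 8L)
  # a 3-clique has 3 edges
  expect_identical(nrow(inst$pair), 3L)
})

test_that("brute force: normalisation, uniform limit, logistic closed form", {
  set.seed(6)
  # zero parameters, N = 3 -> uniform 1/8
  r <- random_instance(n = 3, m = 2)
  zero <- crf_parameters(lambda1 = c(0, 0), omega = rep(0, 4))
  bf <- brute_force_distribution(r$instance, zero)
  expect_equal(bf$prob, rep(1 / 8, 8), tolerance = 1e-12)

  # sums to 1 for random parameters
  for (trial in 1:20) {
    r <- random_instance(n = sample(3:10, 1), m = 3)
    bf <- brute_force_distribution(r$instance, r$params)
    expect_equal(sum(bf$prob), 1, tolerance = 1e-12)
  }

  # single-residue logistic form: P(y=1) = 1/(1+exp(-t)). A two-residue
  # instance with omega = 0 factorises, so check residue 1 of a chain.
  r <- random_instance(n = 2, m = 3, coupled = FALSE)
  t1 <- sum(r$params$lambda1 * r$instance$features[1, ])
  bf <- brute_force_distribution(r$instance, r$params)
  p1 <- sum(bf$prob[bf$labelings[, 1] == 1])
  expect_equal(p1, 1 / (1 + exp(-t1)), tolerance = 1e-12)

  big <- random_instance(n = 17, m = 2)
  expect_error(brute_force_distribution(big$instance, big$params),
               "size error")
})

test_that("sum-product marginals equal brute force on random instances", {
  set.seed(17)
  for (trial in 1:50) {
    r <- random_instance(n = sample(4:12, 1), m = 3,
                         neighbor_cutoff = sample(c(4.0, 4.5, 5.0, 5.5), 1))
    bf <- brute_force_distribution(r$instance, r$params)
    expect_equal(infer_marginals(r$instance, r$params),
                 colSums(bf$labelings * bf$prob), tolerance = 1e-9)
  }
  # zero parameters: every marginal 0.5
  r <- random_instance(n = 8, m = 2)
  zero <- crf_parameters(lambda1 = c(0, 0), omega = rep(0, 4))
  expect_equal(infer_marginals(r$instance, zero), rep(0.5, 8))
})

test_that("max-product MAP equals the brute-force argmax with tie rule", {
  set.seed(18)
  for (trial in 1:50) {
    r <- random_instance(n = sample(4:12, 1), m = 3)
    bf <- brute_force_distribution(r$instance, r$params)
    expect_identical(infer_map(r$instance, r$params), oracle_map(bf))
  }
  # ferromagnetic omega with zero node terms: all-1 by the tie rule
  r <- random_instance(n = 7, m = 2)
  ferro <- crf_parameters(lambda1 = c(0, 0), omega = c(5, 0, 0, 5))
  expect_identical(infer_map(r$instance, ferro), rep(1L, 7))
  # single dominant node term decides a 2-residue chain
  m2 <- structure_model(1:2, rep("ALA", 2), rbind(c(0, 0, 0), c(3.8, 0, 0)))
  X <- rbind(c(1, 0), c(0, 0))
  inst <- gmq_instance(m2, X, 1.0, ss = "CC")
  neg <- crf_parameters(lambda1 = c(-3, 0), omega = rep(0, 4))
  expect_identical(infer_map(inst, neg)[1], 0L)
})

test_that("disconnected components factorise", {
  # two separate chains as one instance: compare with isolated computation
  set.seed(19)
  smA <- generate_toy_structure(4, "CCCC", seed = 1)
  smB <- generate_toy_structure(4, "CCCC", seed = 2)
  coords <- rbind(smA$coords, sweep(smB$coords, 2, c(500, 0, 0), "+"))
  # build a graph by hand with no edges between the halves
  gA <- classify_edges(build_graph(smA, 4.5), "CCCC")
  gB <- classify_edges(build_graph(smB, 4.5), "CCCC")
  eB <- gB$edges; eB$i <- eB$i + 4L; eB$j <- eB$j + 4L
  g <- structure(list(n = 8L, residue_index = 1:8,
                      edges = rbind(gA$edges, eB)),
                 class = "ResidueGraph")
  g <- triangulate(g)
  tr <- build_clique_tree(enumerate_maximal_cliques(g))
  X <- matrix(rnorm(16), 8, 2)
  p <- crf_parameters(lambda1 = rnorm(2), omega = rnorm(4))
  inst <- build_instance(g, tr, X)
  joint <- infer_marginals(inst, p)

  instA <- build_instance(gA,
                          build_clique_tree(enumerate_maximal_cliques(gA)),
                          X[1:4, ])
  instB <- build_instance(gB, build_clique_tree(enumerate_maximal_cliques(gB)),
                          X[5:8, ])
  expect_equal(joint, c(infer_marginals(instA, p),
                        infer_marginals(instB, p)), tolerance = 1e-9)
})

test_that("full-batch gradient at zero equals observed minus uniform", {
  # 2-residue chain, one clique {1,2}; by hand: at theta = 0 marginals are
  # 1/2 and each pairwise pattern has probability 1/4.
  m2 <- structure_model(1:2, rep("ALA", 2), rbind(c(0, 0, 0), c(3.8, 0, 0)))
  X <- rbind(c(2, -1), c(0.5, 3))
  inst <- gmq_instance(m2, X, 1.0, ss = "CC", labels = c(1L, 0L))
  zero <- crf_parameters(lambda1 = c(0, 0), omega = rep(0, 4))
  g <- gmq:::crf_gradient(inst, zero)
  expect_equal(g$lambda, X[1, ] - 0.5 * (X[1, ] + X[2, ]),
               ignore_attr = TRUE)
  # observed pattern is 10; uniform expectation is 1/4 per pattern
  expect_equal(g$omega, c(0, 0, 1, 0) - rep(1 / 4, 4))
  expect_equal(g$loglik, log(1 / 4))
})

test_that("SGD: degenerate all-1 dataset increases P(all-1) monotonically", {
  set.seed(40)
  insts <- lapply(1:3, function(i) {
    sm <- generate_toy_structure(6, "CCCCCC", seed = i)
    X <- matrix(rnorm(12), 6, 2)
    gmq_instance(sm, X, 4.5, ss = "CCCCCC", labels = rep(1L, 6))
  })
  fit <- train_sgd(insts, learning_rate = 0.01, epochs = 8, seed = 2,
                   l2_penalty = 0)
  expect_true(all(diff(fit$meta$loglik_trace) > 0))
  expect_length(fit$meta$loglik_trace, 8)
})

test_that("training log-likelihood is non-decreasing for a small rate", {
  set.seed(41)
  spec <- synthetic_spec(n_models = 5, n_residues = 8, seed = 3)
  ds <- sample_crf_dataset(spec)
  fit <- train_sgd(ds$instances, learning_rate = 0.005, epochs = 10,
                   seed = 4, l2_penalty = 0)
  expect_true(all(diff(fit$meta$loglik_trace) > -1e-8))
})

test_that("label symmetry: flipping labels mirrors the model", {
  set.seed(42)
  r <- random_instance(n = 7, m = 3)
  p <- r$params
  p_flip <- crf_parameters(lambda1 = -p$lambda1,
                           omega = p$omega[c(4, 3, 2, 1)], w = p$w)
  expect_lt(max(abs(infer_marginals(r$instance, p_flip) -
                      (1 - infer_marginals(r$instance, p)))), 1e-9)
})

test_that("w[CC] = 0 disconnects coil-only cuts", {
  # two helices joined by an extended coil linker, placed so that the only
  # edges across the linker midpoint are coil-coil
  ss <- "HHHHHCCCCHHHHH"
  helix <- function(t) cbind(1.5 * t, 2.3 * cos(t * 100 * pi / 180),
                             2.3 * sin(t * 100 * pi / 180))
  h1 <- helix(0:4)
  coil <- sweep(cbind(3.8 * (1:4), 0, 0), 2, h1[5, ], "+")
  h2 <- sweep(helix(0:4), 2,
              coil[4, ] + c(3.8, 0, 0) - as.numeric(helix(0)), "+")
  sm <- structure_model(1:14, rep("ALA", 14), rbind(h1, coil, h2))
  set.seed(13)
  X <- matrix(rnorm(14 * 2), 14, 2)
  g <- classify_edges(triangulate(build_graph(sm, 4.5)), ss)
  tr <- build_clique_tree(enumerate_maximal_cliques(g))
  inst <- build_instance(g, tr, X)
  w0 <- setNames(c(1, 1, 1, 1, 0), c("HH", "BB", "HB", "CHB", "CC"))
  p <- crf_parameters(lambda1 = rnorm(2), omega = rnorm(4), w = w0)
  full <- infer_marginals(inst, p)
  # isolated computation: cut the chain between the two CC-bridged coil
  # residues 7|8 and recompute each half separately
  cut <- 7L
  halves <- list(1:cut, (cut + 1L):14L)
  cross <- inst$pair[(inst$pair$i <= cut) != (inst$pair$j <= cut), ]
  expect_true(all(cross$class == "CC"))   # the cut is coil-only
  iso <- unlist(lapply(halves, function(idx) {
    ghalf <- gmq:::subgraph_keep(g, idx)
    thalf <- build_clique_tree(enumerate_maximal_cliques(ghalf))
    infer_marginals(build_instance(ghalf, thalf, X[idx, , drop = FALSE]), p)
  }))
  expect_equal(full, iso, tolerance = 1e-9)
})

test_that("linear baseline: 1.0 A graph identity and logistic limit", {
  sm <- generate_toy_structure(8, "CCCCCCCC", seed = 21)
  X <- matrix(rnorm(16), 8, 2)
  # graph identity: cutoff 1.0 equals chain + (i,i+2) closure
  g <- build_graph(sm, 1.0)
  expect_true(all(g$edges$j - g$edges$i <= 2))
  # omega = 0: marginals are independent logistic decisions
  p <- crf_parameters(lambda1 = c(1.2, -0.7), omega = rep(0, 4))
  pr <- predict_linear_baseline(sm, X, p, ss = "CCCCCCCC")
  expect_equal(pr$p1, 1 / (1 + exp(-as.numeric(X %*% p$lambda1))),
               tolerance = 1e-9)
  pr2 <- predict_linear_baseline(sm, X, p, ss = "CCCCCCCC")
  expect_identical(pr$map, pr2$map)   # deterministic
})

test_that("logistic regression matches IRLS and glm, handles degeneracies", {
  set.seed(50)
  X <- matrix(rnorm(100), 50, 2)
  y <- as.integer(runif(50) < 1 / (1 + exp(-(0.5 + X %*% c(1, -2)))))
  fit <- logistic_fit(X, y)
  expect_equal(fit$coef, oracle_logistic_irls(X, y), tolerance = 1e-4)
  gl <- glm(y ~ X, family = binomial())
  expect_equal(fit$coef, unname(coef(gl)), tolerance = 1e-4)

  # perfect separation: warns, training accuracy 1
  Xs <- matrix(c(-2, -1, 1, 2), 4, 1)
  ys <- c(0L, 0L, 1L, 1L)
  expect_warning(res <- logistic_regression_baseline(Xs, ys, Xs),
                 "separation")
  expect_identical(res$labels, ys)

  # zero-information features: intercept-only limit = prevalence
  X0 <- matrix(0, 40, 2)
  y0 <- rep(c(0L, 1L, 1L, 1L), 10)
  res0 <- logistic_regression_baseline(X0, y0, X0[1:2, , drop = FALSE])
  expect_equal(res0$p1, rep(0.75, 2), tolerance = 1e-6)
})

test_that("parameter files round-trip bit-exactly", {
  set.seed(60)
  p <- crf_parameters(lambda1 = rnorm(5) * pi, omega = rnorm(4) / 3,
                      w = setNames(c(0.9, 0.8, 1, 0.1, 0),
                                   c("HH", "BB", "HB", "CHB", "CC")),
                      ca_cutoff = 5, neighbor_cutoff = 4.5,
                      meta = list(seed = 7L, epochs = 50,
                                  learning_rate = 0.05, note = "unit"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_crf_parameters(p, path)
  q <- read_crf_parameters(path)
  expect_identical(q$lambda1, p$lambda1)
  expect_identical(q$omega, p$omega)
  expect_identical(unname(q$w), unname(p$w))
  expect_identical(q$meta$learning_rate, p$meta$learning_rate)
  expect_identical(q$meta$note, p$meta$note)
})
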