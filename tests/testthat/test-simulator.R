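test_that("degenerate and pure-birth simulations match closed-form expectations", {
  # no events at all: exactly the two root lineages survive
  tr0 <- simulate_tree(10, 1e-12, 0, seed = 1)
  expect_equal(tr0$n_tips, 2L)
  expect_equal(tr0$root_age, 10)
  expect_equal(branching_ages(tr0), 10)

  # Yule expectation: mean tip count ~ 2 exp(lambda * T)
  ns <- vapply(1:400, function(i) simulate_tree(10, 0.1, 0, seed = 1000 + i)$n_tips,
               numeric(1))
  expected <- 2 * exp(0.1 * 10)
  se <- sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - expected), 3 * se + 0.2)

  # truth record carries the generating parameters
  expect_equal(attr(tr0, "truth")$lambda, rep(1e-12, 1))
  expect_error(simulate_tree(10, 0.1, 0), "seed")
})

test_that("simulated trees satisfy every time-tree invariant", {
  for (s in 1:5) {
    tr <- simulate_tree(25, c(0.3, 0.15), c(0.1, 0.05), epochs = 2, rho = 0.7,
                        seed = 50 + s)
    expect_s3_class(tr, "time_tree")   # as_time_tree already validated it
    expect_gte(tr$n_tips, 2L)
    expect_equal(tr$root_age, 25, tolerance = 1e-8)
  }
})

test_that("forward-simulated reconstructed branching times follow the analytic CDF", {
  lam <- 0.3; mu <- 0.1; T <- 10
  ts <- simulate_branching_times(T, lam, mu, reps = 3000, seed = 99)
  g <- epoch_grid(c(0, T), lam, mu, 1)
  kt <- suppressWarnings(ks.test(ts, function(t) speciation_time_cdf(g, t)))
  expect_gt(kt$p.value, 0.01)
})

test_that("uniform pruning keeps a binomial tip count and a subset of node ages", {
  big <- simulate_tree(18, 0.35, 0.05, seed = 7)
  expect_gt(big$n_tips, 100)
  # rho = 1 is the identity
  same <- prune_uniform(big, 1, seed = 1)
  expect_equal(same$phylo, big$phylo)

  pr <- prune_uniform(big, 0.5, seed = 2)
  n <- big$n_tips
  bounds <- qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(pr$n_tips, bounds[1])
  expect_lte(pr$n_tips, bounds[2])
  # retained node ages are a subset of the original speciation ages
  dists <- vapply(branching_ages(pr), function(a) {
    min(abs(branching_ages(big) - a))
  }, numeric(1))
  expect_lt(max(dists), 1e-8)
  # pruning commutes with tip relabeling
  perm <- big
  set.seed(3)
  new_labels <- sample(perm$phylo$tip.label)
  names(new_labels) <- perm$phylo$tip.label
  perm$phylo$tip.label <- unname(new_labels[perm$phylo$tip.label])
  pr2 <- prune_uniform(perm, 0.5, seed = 2)
  expect_equal(sort(unname(new_labels[attr(pr, "kept_tips")])),
               sort(attr(pr2, "kept_tips")))
})

test_that("environment-linked simulation realizes the requested correlation", {
  env <- synthetic_cenozoic_co2()
  neg <- 0L
  for (s in 1:10) {
    tr <- simulate_env_tree(env, root_age = 40, epochs = 10, lambda0 = 0.17,
                            mu0 = 0.05, beta = -0.005, sigma = 0.02,
                            model = "gmrf", seed = 400 + s)
    truth <- attr(tr, "truth")
    # realized log-rate increments against environmental differences
    cc <- cor(diff(log(truth$lambda)), truth$delta[-1])
    neg <- neg + (cc < 0)
  }
  expect_gte(neg, 9L)
  # beta = 0, sigma = 0: constant-rate trajectories
  tr0 <- simulate_env_tree(env, root_age = 30, epochs = 10, lambda0 = 0.15,
                           mu0 = 0.03, beta = 0, sigma = 0, seed = 5)
  expect_equal(attr(tr0, "truth")$lambda, rep(0.15, 10))
})

test_that("empirical-sampling simulation preserves topology, counts, and clade bounds", {
  base <- simulate_tree(30, 0.2, 0.04, seed = 21)
  ct <- random_clade_table(base, n_clades = 4, total_missing = 5L * base$n_tips,
                           seed = 22)
  res <- simulate_empirical_sampling(base, ct, lambda = 0.2, mu = 0.04, seed = 23)
  expect_equal(res$tree$n_tips, base$n_tips)
  expect_true(ape::all.equal.phylo(res$tree$phylo, base$phylo,
                                   use.edge.length = FALSE))
  expect_equal(res$clades$missing, ct$missing)
  expect_equal(attr(res$clades, "rho"), attr(ct, "rho"))
  # node times were redrawn
  expect_false(isTRUE(all.equal(sort(branching_ages(res$tree)),
                                sort(branching_ages(base)))))
  # zero missing everywhere: the redraw keeps the topology and the table
  ct0 <- ct
  ct0$missing <- rep(0L, nrow(ct0))
  res0 <- simulate_empirical_sampling(base, ct0, lambda = 0.2, mu = 0.04, seed = 24)
  expect_equal(attr(res0$clades, "m_total"), base$n_tips)
})

test_that("redrawn divergence times reproduce the direct-simulation age law", {
  # node ages of a fixed 4-tip balanced topology, redrawn by the ranked
  # inverse-CDF scheme, against ages from direct Gillespie simulation
  lam <- 0.25; mu <- 0.08; T <- 10
  direct <- c()
  for (i in 1:1500) {
    tr <- simulate_tree(T, lam, mu, seed = 3000 + i, max_attempts = 50)
    if (tr$n_tips != 4) next
    phy <- tr$phylo
    root_kids <- phy$edge[phy$edge[, 1] == 5L, 2]
    if (all(root_kids > 4L)) direct <- c(direct, branching_ages(tr, TRUE))
  }
  phy0 <- ape::read.tree(text = "((A:2,B:2):8,(C:5,D:5):5);")
  g <- epoch_grid(c(0, T), lam, mu, 1)
  set.seed(9)
  redraw <- replicate(1500, branching_ages(
    as_time_tree(epochdiv:::redraw_divergence_times(phy0, g)), TRUE))
  kt <- suppressWarnings(ks.test(direct, c(redraw)))
  expect_gt(kt$p.value, 0.01)
})

test_that("the fixture suite is deterministic and self-consistent", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixture_suite(d1, seed = 77)
  f2 <- make_fixture_suite(d2, seed = 77)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
  # trees pass the validators and the clade tables resolve
  for (nm in c("small", "medium", "large")) {
    tr <- read_time_tree(file.path(d1, sprintf("fixture_tree_%s.nwk", nm)))
    expect_s3_class(tr, "time_tree")
  }
  tr <- read_time_tree(file.path(d1, "fixture_tree_large.nwk"))
  ct <- read_clade_table(file.path(d1, "fixture_clades_large.csv"))
  res <- resolve_clades(tr, ct)
  expect_equal(attr(res, "rho"), tr$n_tips / (tr$n_tips + sum(ct$missing)))
  env <- read_env_series(file.path(d1, "synthetic_co2.csv"))
  expect_true(all(diff(env$age_mya) > 0))
  truth <- jsonlite::read_json(file.path(d1, "fixture_truth.json"))
  expect_named(truth, c("small", "large", "medium"))
})
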