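test_that("net rate exponent is the piecewise integral of mu - lambda", {
  g <- epoch_grid(c(0, 10), 0.2, 0.1)
  expect_equal(net_rate_exponent(g, 0, 10), -1.0)

  # lambda = mu: zero for any interval
  ge <- epoch_grid(c(0, 4, 10), c(0.3, 0.7), c(0.3, 0.7))
  expect_equal(net_rate_exponent(ge, 1.3, 8.1), 0)

  # additive across an epoch boundary
  g2 <- epoch_grid(c(0, 4, 10), c(0.3, 0.1), c(0.05, 0.4))
  expect_equal(
    net_rate_exponent(g2, 1, 9),
    net_rate_exponent(g2, 1, 4) + net_rate_exponent(g2, 4, 9),
    tolerance = 1e-12
  )
  expect_error(net_rate_exponent(g2, -1, 5), "within the grid span")
})

test_that("survival probability matches the constant-rate closed form", {
  lam <- 0.2; mu <- 0.1; T <- 10
  for (rho in c(1, 0.5, 0.25)) {
    g <- epoch_grid(c(0, T), lam, mu, rho)
    expect_equal(survival_probability(g, T), rho)        # only sampling remains
    expect_equal(survival_probability(g, 0),
                 nee_survival(T, lam, mu, rho), tolerance = 1e-10)
    tt <- seq(0, T, length.out = 11)
    expect_equal(survival_probability(g, tt),
                 nee_survival(T - tt, lam, mu, rho), tolerance = 1e-10)
  }
  # no extinction, complete sampling: certain survival
  g0 <- epoch_grid(c(0, 10), 0.3, 0, 1)
  expect_equal(survival_probability(g0, c(0, 3, 10)), c(1, 1, 1))
})

test_that("survival and speciation CDF are invariant to epoch refinement", {
  lam <- 0.25; mu <- 0.18; T <- 12
  tt <- seq(0, T, length.out = 9)
  for (rho in c(1, 0.6)) {
    g1 <- epoch_grid(c(0, T), lam, mu, rho)
    gK <- epoch_grid(seq(0, T, length.out = 41), rep(lam, 40), rep(mu, 40), rho)
    expect_equal(survival_probability(gK, tt), survival_probability(g1, tt),
                 tolerance = 1e-10)
    expect_equal(speciation_time_cdf(gK, tt), speciation_time_cdf(g1, tt),
                 tolerance = 1e-10)
  }
})

test_that("speciation-time CDF has the right boundaries and monotonicity", {
  g <- epoch_grid(c(0, 3, 6, 10), c(0.3, 0.15, 0.4), c(0.05, 0.2, 0.1), 1)
  expect_equal(speciation_time_cdf(g, 0), 0)
  expect_equal(speciation_time_cdf(g, 10), 1)   # rho = 1
  tt <- seq(0, 10, length.out = 200)
  expect_true(all(diff(speciation_time_cdf(g, tt)) >= -1e-12))

  # critical lambda = mu epochs produce no NaN anywhere
  gc <- epoch_grid(c(0, 5, 10), c(0.2, 0.4), c(0.2, 0.4), 0.7)
  expect_false(any(is.nan(speciation_time_cdf(gc, tt))))
  expect_false(any(is.nan(survival_probability(gc, tt))))
})

test_that("no NaN or infinity across a wide rate sweep including lambda = mu", {
  set.seed(42)
  T <- 10
  tt <- c(0, 2.5, 5, 9.99, 10)
  for (rep in 1:60) {
    lam <- exp(runif(3, log(1e-6), log(10)))
    mu <- exp(runif(3, log(1e-6), log(10)))
    if (rep %% 3 == 0) mu[2] <- lam[2]               # exact degeneracy
    rho <- runif(1, 0.01, 1)
    g <- epoch_grid(c(0, 3, 7, T), lam, mu, rho)
    P <- survival_probability(g, tt)
    Fv <- speciation_time_cdf(g, tt)
    expect_true(all(is.finite(P)) && all(P > 0 & P <= 1))
    expect_true(all(is.finite(Fv)) && all(Fv >= 0 & Fv <= 1))
    ld <- tree_log_density(toy_tree_4(), g)
    expect_false(is.nan(ld))
  }
})

test_that("tree density matches independent constant-rate implementations", {
  trees <- list(toy_tree_4(), toy_tree_3(T = 10), toy_tree_5())
  # scale toy trees to a 10-My span? use their own spans
  for (tr in trees) {
    T <- tr$root_age
    for (pars in list(c(0.2, 0.1, 1), c(0.35, 0.3, 1), c(0.2, 0.1, 0.5))) {
      lam <- pars[1]; mu <- pars[2]; rho <- pars[3]
      ours <- tree_log_density(tr, epoch_grid(c(0, T), lam, mu, rho))
      expect_equal(ours, nee_log_density(tr, lam, mu, rho), tolerance = 1e-8)
    }
    # pure birth against the Yule closed form
    lam <- 0.17
    expect_equal(tree_log_density(tr, epoch_grid(c(0, T), lam, 0, 1)),
                 yule_log_density(tr, lam), tolerance = 1e-8)
  }
})

test_that("tree density is invariant to refining epochs with equal rates", {
  tr <- toy_tree_4()
  for (k in c(10, 100)) {
    expect_equal(
      tree_log_density(tr, epoch_grid(seq(0, 10, length.out = k + 1),
                                      rep(0.2, k), rep(0.1, k), 0.8)),
      tree_log_density(tr, epoch_grid(c(0, 10), 0.2, 0.1, 0.8)),
      tolerance = 1e-10
    )
  }
  expect_error(tree_log_density(tr, epoch_grid(c(0, 8), 0.2, 0.1)), "span")
})

test_that("tree density integrates to the analytic tip-number probability", {
  # For a 3-tip tree the density, summed over the 3 labeled topologies and
  # integrated over the free node time, must equal P(N = 3) of the
  # conditioned process: (n-1) * (q0/rho)^2 * (1 - q0/rho) * ... with
  # q0 = P(0) exp(r(0,T)).
  cases <- list(
    epoch_grid(c(0, 8), 0.25, 0.12, 1),
    epoch_grid(c(0, 8), 0.25, 0.12, 0.6),
    epoch_grid(c(0, 3, 6, 8), c(0.3, 0.15, 0.4), c(0.05, 0.2, 0.1), 1)
  )
  for (g in cases) {
    T <- 8
    f <- function(a) {
      vapply(a, function(ai) exp(tree_log_density(toy_tree_3(ai, T), g)), numeric(1))
    }
    I3 <- 3 * integrate(f, 1e-8, T - 1e-8, rel.tol = 1e-8, subdivisions = 400L)$value
    q0 <- survival_probability(g, 0) * exp(net_rate_exponent(g, 0, T))
    Pn3 <- 2 * (q0 / g$rho)^2 * (1 - q0 / g$rho)
    expect_equal(I3, Pn3, tolerance = 1e-3)
  }
})

test_that("empirical sampling density collapses, decreases in k, and matches quadrature", {
  tr <- toy_tree_3(a = 2.5, T = 9)
  g <- epoch_grid(c(0, 9), 0.22, 0.09, 1)

  # no missing species: exact collapse to the plain tree density
  cl0 <- resolve_clades(tr, tibble::tibble(clade = "AB", taxonA = "A",
                                           taxonB = "B", missing = 0L))
  expect_identical(empirical_sampling_log_density(tr, g, cl0),
                   tree_log_density(tr, g))

  # quadrature oracle built from the constant-rate closed forms: the
  # missing speciation time is integrated over [crown age, present]
  lam <- 0.22; mu <- 0.09
  oracle_one <- function(tr, c_age, k_miss, m) {
    n <- tr$n_tips
    dens <- integrate(function(u) lam * nee_p1(u, lam, mu), 0, c_age,
                      rel.tol = 1e-12)$value / (1 - nee_q(tr$root_age, lam, mu))
    nee_log_density(tr, lam, mu, 1) + lgamma(m) - lgamma(n) +
      k_miss * log(dens) - lgamma(k_miss + 1)
  }
  for (k_miss in c(1L, 2L, 3L)) {
    cl <- resolve_clades(tr, tibble::tibble(clade = "AB", taxonA = "A",
                                            taxonB = "B", missing = k_miss))
    expect_equal(empirical_sampling_log_density(tr, g, cl),
                 oracle_one(tr, 2.5, k_miss, 3 + k_miss), tolerance = 1e-6)
  }

  # two clades on a 5-tip tree
  tr5 <- toy_tree_5()
  g5 <- epoch_grid(c(0, 12), 0.22, 0.09, 1)
  cl5 <- resolve_clades(tr5, tibble::tibble(
    clade = c("AB", "CD"), taxonA = c("A", "C"), taxonB = c("B", "D"),
    missing = c(2L, 1L)
  ))
  dens_of <- function(c_age) {
    integrate(function(u) lam * nee_p1(u, lam, mu), 0, c_age,
              rel.tol = 1e-12)$value / (1 - nee_q(12, lam, mu))
  }
  oracle5 <- nee_log_density(tr5, lam, mu, 1) + lgamma(8) - lgamma(5) +
    2 * log(dens_of(1.5)) - lgamma(3) + 1 * log(dens_of(4)) - lgamma(2)
  expect_equal(empirical_sampling_log_density(tr5, g5, cl5), oracle5,
               tolerance = 1e-6)

  # doubling a missing count strictly decreases the log density
  cl1 <- resolve_clades(tr, tibble::tibble(clade = "AB", taxonA = "A",
                                           taxonB = "B", missing = 2L))
  cl2 <- resolve_clades(tr, tibble::tibble(clade = "AB", taxonA = "A",
                                           taxonB = "B", missing = 4L))
  expect_lt(empirical_sampling_log_density(tr, g, cl2),
            empirical_sampling_log_density(tr, g, cl1))

  # a grid with rho < 1 is rejected: clade terms already carry the
  # missing species
  expect_error(
    empirical_sampling_log_density(tr, epoch_grid(c(0, 9), 0.22, 0.09, 0.5), cl1),
    "rho = 1"
  )
})

test_that("crown versus stem windows give different, ordered clade terms", {
  tr <- toy_tree_5()
  g <- epoch_grid(c(0, 12), 0.2, 0.05, 1)
  cl <- resolve_clades(tr, tibble::tibble(clade = "AB", taxonA = "A",
                                          taxonB = "B", missing = 3L))
  crown <- empirical_sampling_log_density(tr, g, cl, clade_age = "crown")
  stem <- empirical_sampling_log_density(tr, g, cl, clade_age = "stem")
  # the stem window [stem age, present] is wider, so each missing
  # speciation event is less constrained and the density is higher
  expect_gt(stem, crown)
})

test_that("density at truth beats clearly perturbed rates on prune-protocol trees", {
  wins <- 0L
  reps <- 30L
  lam <- 0.18; mu <- 0.03
  for (r in seq_len(reps)) {
    base <- simulate_tree(35, lam, mu, seed = 500 + r)
    ct <- random_clade_table(base, n_clades = 4,
                             total_missing = 4L * base$n_tips, seed = 600 + r)
    simres <- simulate_empirical_sampling(base, ct, lambda = lam, mu = mu,
                                          seed = 700 + r)
    g_true <- epoch_grid_ages(simres$tree$root_age, 1, lam, mu, 1)
    g_pert <- epoch_grid_ages(simres$tree$root_age, 1, lam * 1.5, mu + 0.05, 1)
    ll_t <- empirical_sampling_log_density(simres$tree, g_true, simres$clades)
    ll_p <- empirical_sampling_log_density(simres$tree, g_pert, simres$clades)
    wins <- wins + (ll_t > ll_p)
  }
  expect_gte(wins / reps, 0.95)
})
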