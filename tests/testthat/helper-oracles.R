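# Independent closed-form oracles used across the test files.  These are
# written directly from the published constant-rate formulas and share no
# code with the episodic machinery under test.

# Survival probability of one lineage over age z, constant rates, with
# sampling fraction rho at the present.
nee_survival <- function(z, lam, mu, rho = 1) {
  rho * (lam - mu) / (rho * lam + (lam * (1 - rho) - mu) * exp(-(lam - mu) * z))
}

# Probability of exactly one sampled descendant.
nee_p1 <- function(z, lam, mu, rho = 1) {
  nee_survival(z, lam, mu, rho)^2 * exp(-(lam - mu) * z) / rho
}

# Constant-rate reconstructed-tree log density, conditioned on two root
# lineages both surviving, with the labeled-history constant.
nee_log_density <- function(tree, lam, mu, rho = 1) {
  z <- branching_ages(tree)
  n <- tree$n_tips
  (n - 1) * log(2) - lgamma(n + 1) +
    2 * (log(nee_p1(z[1], lam, mu, rho)) - log(nee_survival(z[1], lam, mu, rho))) +
    sum(log(lam) + log(nee_p1(z[-1], lam, mu, rho)))
}

# Pure-birth closed form (mu = 0, rho = 1): every branch fails to
# speciate along its length, every node contributes lambda.
yule_log_density <- function(tree, lam) {
  z <- branching_ages(tree)
  n <- tree$n_tips
  (n - 1) * log(2) - lgamma(n + 1) - 2 * lam * z[1] + sum(log(lam) - lam * z[-1])
}

# q(t) = P exp(r) for constant rates, as a function of age z.
nee_q <- function(z, lam, mu, rho = 1) {
  nee_survival(z, lam, mu, rho) * exp(-(lam - mu) * z)
}

# Analytic log marginal likelihood of the conjugate normal-mean model
# y ~ N(theta, s^2), theta ~ N(mu0, tau0^2).
conjugate_log_evidence <- function(y, s, mu0, tau0) {
  n <- length(y)
  Sig <- diag(s^2, n) + tau0^2
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(Sig)$modulus) +
            as.numeric(t(y - mu0) %*% solve(Sig) %*% (y - mu0)))
}

# Conjugate normal-mean toy model plugged into the generic engine.
conjugate_model <- function(y, s = 1, mu0 = 0, tau0 = 2) {
  mcmc_model(
    par_init = function() c(theta = rnorm(1, mu0, tau0)),
    log_prior = function(th) dnorm(th[["theta"]], mu0, tau0, log = TRUE),
    log_lik = function(th) sum(dnorm(y, th[["theta"]], s, log = TRUE)),
    blocks = list(list(name = "theta", pars = "theta", type = "rw", scale = 0.5))
  )
}

# Fixed toy trees used across likelihood tests.
toy_tree_4 <- function() {
  as_time_tree(ape::read.tree(text = "((A:3,B:3):7,(C:6,D:6):4);"))
}

toy_tree_3 <- function(a = 2.5, T = 9) {
  as_time_tree(ape::read.tree(
    text = sprintf("((A:%g,B:%g):%g,C:%g);", a, a, T - a, T)
  ))
}

toy_tree_5 <- function() {
  as_time_tree(ape::read.tree(
    text = "(((A:1.5,B:1.5):4.5,(C:4,D:4):2):6,E:12);"
  ))
}
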