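#' Generate a clade-sampling table from a tree
#'
#' Picks disjoint named clades from the tree and distributes a total
#' count of missing species among them with a bias toward younger,
#' species-rich clades -- the pattern seen in densely nested groups where
#' the unsampled diversity concentrates in the derived lineages.
#'
#' @param tree a [time_tree][as_time_tree].
#' @param n_clades number of clades to name.
#' @param total_missing total missing species to distribute.
#' @param seed integer RNG seed.
#' @param youth_bias exponent on `1 / (1 + crown age)` used in the
#'   allocation weights (0 = no age bias).
#' @return A clade table resolved against `tree` (see
#'   [resolve_clades()]).
#' @export
random_clade_table <- function(tree, n_clades, total_missing, seed, youth_bias = 3) {
  set.seed(seed)
  phy <- tree$phylo
  n <- tree$n_tips
  nodes <- (n + 2L):(2L * n - 1L)        # internal nodes except the root
  tip_sets <- lapply(nodes, function(v) phangorn_free_descendants(phy, v))
  sizes <- lengths(tip_sets)
  ages <- tree$node_age[nodes]
  # named clades are species-rich groups (subfamilies, tribes) of
  # intermediate age, not shallow cherries and not the deepest splits
  ok <- sizes >= 3L & sizes <= max(3L, floor(n / 2)) &
    ages >= 0.1 * tree$root_age & ages <= 0.6 * tree$root_age
  if (sum(ok) < 2L) ok <- sizes >= 2L & sizes <= max(2L, floor(n / 2))
  nodes <- nodes[ok]; tip_sets <- tip_sets[ok]; sizes <- sizes[ok]
  picked <- integer(0)
  covered <- integer(0)
  for (i in sample.int(length(nodes))) {
    if (length(picked) >= n_clades) break
    if (!any(tip_sets[[i]] %in% covered)) {
      picked <- c(picked, i)
      covered <- c(covered, tip_sets[[i]])
    }
  }
  if (length(picked) < 2L) abort("Could not find enough disjoint clades; is the tree very unbalanced?")
  # missing diversity concentrates in the younger, species-rich clades,
  # the pattern seen in densely nested radiations
  ages <- tree$node_age[nodes[picked]]
  w <- sizes[picked] / (1 + ages)^youth_bias
  alloc <- as.integer(stats::rmultinom(1, total_missing, prob = w / sum(w)))
  tab <- tibble(
    clade = sprintf("clade_%02d", seq_along(picked)),
    taxonA = vapply(tip_sets[picked], function(s) phy$tip.label[min(s)], character(1)),
    taxonB = vapply(tip_sets[picked], function(s) phy$tip.label[max(s)], character(1)),
    missing = alloc
  )
  resolve_clades(tree, tab)
}

#' Write a deterministic suite of small test fixtures
#'
#' Produces plain-text fixtures for examples and tests: three simulated
#' reconstructed trees (targeting roughly 50, 200, and 500 tips:
#' constant-rate, environment-linked, and episodic), the synthetic
#' Cenozoic-like CO2 series, clade tables with clade-biased missing
#' counts, and JSON truth records of the generating parameters.  The
#' same seed yields byte-identical files.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer RNG seed.
#' @return Invisibly, a character vector of the files written.
#' @export
make_fixture_suite <- function(out_dir, seed = 20260101) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(x) files <<- c(files, x)
  env <- synthetic_cenozoic_co2(max_age = 60, by = 0.25)
  env_path <- file.path(out_dir, "synthetic_co2.csv")
  readr::write_csv(env, env_path); put(env_path)

  specs <- list(
    small = list(lambda = 0.14, mu = 0.05, root_age = 30, epochs = 1L,
                 window = c(35L, 90L)),
    medium = NULL,   # environment-linked, built below
    large = list(lambda = c(0.35, 0.3, 0.25, 0.12, 0.08, 0.06, 0.05, 0.05, 0.04, 0.04),
                 mu = rep(0.02, 10), root_age = 45, epochs = 10L,
                 window = c(350L, 800L))
  )
  sim_in_window <- function(f, s0, window) {
    s <- s0
    repeat {
      tr <- tryCatch(f(s), error = function(e) NULL)
      if (!is.null(tr) && tr$n_tips >= window[1] && tr$n_tips <= window[2]) return(tr)
      s <- s + 1L
    }
  }
  truths <- list()
  for (nm in c("small", "large")) {
    sp <- specs[[nm]]
    tr <- sim_in_window(function(s) {
      simulate_tree(sp$root_age, sp$lambda, sp$mu, epochs = sp$epochs, seed = s,
                    max_attempts = 300)
    }, seed + match(nm, names(specs)), sp$window)
    p <- file.path(out_dir, sprintf("fixture_tree_%s.nwk", nm))
    write_time_tree(tr, p); put(p)
    truths[[nm]] <- attr(tr, "truth")
    ct <- random_clade_table(tr, n_clades = if (nm == "small") 5 else 11,
                             total_missing = 9L * tr$n_tips,
                             seed = seed + 10L + match(nm, names(specs)))
    cp <- file.path(out_dir, sprintf("fixture_clades_%s.csv", nm))
    readr::write_csv(ct[c("clade", "taxonA", "taxonB", "missing")], cp); put(cp)
  }
  tr <- sim_in_window(function(s) {
    simulate_env_tree(env, root_age = 40, epochs = 10, lambda0 = 0.22,
                      mu0 = 0.055, beta = -0.005, sigma = 0.02,
                      model = "gmrf", seed = s, max_attempts = 300)
  }, seed + 5L, c(150L, 400L))
  p <- file.path(out_dir, "fixture_tree_medium.nwk")
  write_time_tree(tr, p); put(p)
  truths$medium <- attr(tr, "truth")

  tp <- file.path(out_dir, "fixture_truth.json")
  jsonlite::write_json(truths, tp, auto_unbox = TRUE, digits = NA)
  put(tp)
  invisible(files)
}
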