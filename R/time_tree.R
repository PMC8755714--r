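#' Time-calibrated ultrametric trees
#'
#' A `time_tree` wraps an [ape::phylo] object together with node ages
#' (Myr before present, 0 = present) validated against the invariants the
#' episodic birth-death machinery relies on: the tree is rooted with a
#' bifurcating root, fully binary, and ultrametric (every tip sits at the
#' present within a relative tolerance of the root age).
#'
#' Ages run backwards in time (root age = oldest). The likelihood functions
#' work in forward time measured from the root; [age_to_forward()] and
#' [forward_to_age()] convert between the two conventions.
#'
#' @param phy an [ape::phylo] object with branch lengths in Myr.
#' @param tol relative ultrametricity tolerance; tips may deviate from age 0
#'   by at most `tol * root_age`.
#'
#' @return An object of class `time_tree`: a list with elements `phylo`,
#'   `root_age`, `node_age` (ages of all nodes in `phylo` numbering, tips
#'   first), and `n_tips`.
#' @export
as_time_tree <- function(phy, tol = 1e-6) {
  if (!inherits(phy, "phylo")) {
    abort("`phy` must be an `ape::phylo` object.")
  }
  if (is.null(phy$edge.length)) {
    abort("Tree has no branch lengths; node ages cannot be computed.")
  }
  if (!ape::is.rooted(phy)) {
    abort("Tree must be rooted.")
  }
  n <- ape::Ntip(phy)
  if (n < 2) {
    abort("Tree must have at least two tips.")
  }
  root <- n + 1L
  if (sum(phy$edge[, 1] == root) != 2L) {
    abort("Root must have exactly two children (no polytomous or unrooted root).")
  }
  if (!ape::is.binary(phy)) {
    abort("Tree must be fully bifurcating.")
  }
  depth <- ape::node.depth.edgelength(phy)
  root_age <- max(depth[seq_len(n)])
  if (root_age <= 0) {
    abort("Tree has zero depth.")
  }
  age <- root_age - depth
  tip_age <- age[seq_len(n)]
  bad <- which(abs(tip_age) > tol * root_age)
  if (length(bad) > 0) {
    worst <- bad[which.max(abs(tip_age[bad]))]
    abort(sprintf(
      "Tree is not ultrametric: tip '%s' deviates from the present by %.6g Myr (tolerance %.3g).",
      phy$tip.label[worst], tip_age[worst], tol * root_age
    ))
  }
  age[seq_len(n)] <- 0
  internal_age <- age[(n + 1L):(2L * n - 1L)]
  if (any(internal_age <= 0)) {
    abort("Internal node ages must be strictly positive.")
  }
  # child age must be strictly below parent age
  parent_age <- age[phy$edge[, 1]]
  child_age <- age[phy$edge[, 2]]
  if (any(child_age >= parent_age)) {
    abort("Every child node must be younger than its parent (zero-length internal branch?).")
  }
  structure(
    list(phylo = phy, root_age = root_age, node_age = age, n_tips = n),
    class = "time_tree"
  )
}

#' Read a time-calibrated tree
#'
#' Reads a Newick or Nexus tree, interprets branch lengths as Myr, and
#' validates it as a [time_tree][as_time_tree].
#'
#' @param path path to the tree file.
#' @param format `"newick"` or `"nexus"`.
#' @param tol relative ultrametricity tolerance, see [as_time_tree()].
#' @return A `time_tree`.
#' @export
read_time_tree <- function(path, format = c("newick", "nexus"), tol = 1e-6) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(sprintf("Tree file not found: '%s'", path))
  }
  phy <- switch(format,
    newick = ape::read.tree(path),
    nexus = ape::read.nexus(path)
  )
  if (inherits(phy, "multiPhylo")) {
    phy <- phy[[1]]
  }
  as_time_tree(phy, tol = tol)
}

#' Write a time tree to Newick or Nexus
#'
#' Branch lengths are written with 15 significant digits so that a
#' write/read round trip preserves node ages to well below 1e-9 Myr.
#'
#' @param tree a `time_tree`.
#' @param path output path.
#' @param format `"newick"` or `"nexus"`.
#' @return `path`, invisibly.
#' @export
write_time_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  stopifnot(inherits(tree, "time_tree"))
  switch(format,
    newick = ape::write.tree(tree$phylo, file = path, digits = 15),
    nexus = ape::write.nexus(tree$phylo, file = path, digits = 15)
  )
  invisible(path)
}

#' Convert between ages and forward time
#'
#' Ages are Myr before present (0 = present, `root_age` = root). Forward
#' time runs from 0 at the root to `root_age` at the present; this is the
#' time axis the likelihood works on.
#'
#' @param age,t numeric vector of ages / forward times in Myr.
#' @param root_age the root age in Myr.
#' @return Numeric vector of the converted times.
#' @export
age_to_forward <- function(age, root_age) root_age - age

#' @rdname age_to_forward
#' @export
forward_to_age <- function(t, root_age) root_age - t

#' Internal-node ages of a time tree
#'
#' @param tree a `time_tree`.
#' @param drop_root drop the root age from the result?
#' @return Numeric vector of internal node ages in Myr (root first in
#'   `phylo` node order).
#' @export
branching_ages <- function(tree, drop_root = FALSE) {
  stopifnot(inherits(tree, "time_tree"))
  n <- tree$n_tips
  ages <- tree$node_age[(n + 1L):(2L * n - 1L)]
  if (drop_root) ages[-1L] else ages
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf(
    "<time_tree> %d tips, root age %.4f Myr\n", x$n_tips, x$root_age
  ))
  invisible(x)
}
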