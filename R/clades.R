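#' Read a clade-sampling table
#'
#' The empirical taxon-sampling model assigns a known count of missing
#' (unsampled but extant) species to named clades.  The on-disk format is
#' a 4-column CSV with header `clade,taxonA,taxonB,missing`: each clade is
#' identified by two sampled tip labels whose most recent common ancestor
#' defines it, which scales to arbitrarily large clades without listing
#' their members.
#'
#' @param path path to the CSV file.
#' @return A tibble with columns `clade`, `taxonA`, `taxonB`, `missing`.
#' @export
read_clade_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Clade table not found: '%s'", path))
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("clade", "taxonA", "taxonB", "missing")
  if (!all(need %in% names(tab))) {
    abort(sprintf("Clade table must have columns %s.", paste(need, collapse = ", ")))
  }
  tab <- tab[need]
  tab$missing <- as.integer(tab$missing)
  if (any(tab$missing < 0)) abort("Missing-species counts must be >= 0.")
  as_tibble(tab)
}

#' Resolve clade MRCA ages against a tree
#'
#' Locates each clade's most recent common ancestor in the tree, records
#' its crown and stem ages, and derives the sampling summary: `n` sampled
#' tips, `m = n + sum(missing)` total species, and the overall sampling
#' fraction `rho = n / m`.
#'
#' @param tree a [time_tree][as_time_tree].
#' @param clades a tibble with columns `clade`, `taxonA`, `taxonB`,
#'   `missing` (see [read_clade_table()]).
#' @return The input tibble with columns `mrca_node`, `mrca_age` (crown
#'   age) and `stem_age` added, and attributes `n_sampled`, `m_total`,
#'   `rho`.  For a clade whose MRCA is the root, the stem age is set to
#'   the root age.
#' @export
resolve_clades <- function(tree, clades) {
  stopifnot(inherits(tree, "time_tree"))
  need <- c("clade", "taxonA", "taxonB", "missing")
  if (!all(need %in% names(clades))) {
    abort(sprintf("Clade table must have columns %s.", paste(need, collapse = ", ")))
  }
  phy <- tree$phylo
  labels <- c(clades$taxonA, clades$taxonB)
  absent <- setdiff(unique(labels), phy$tip.label)
  if (length(absent) > 0) {
    abort(sprintf("Taxon labels not found in tree: %s",
                  paste(absent, collapse = ", ")))
  }
  n <- tree$n_tips
  root <- n + 1L
  mrca_node <- purrr::map2_int(clades$taxonA, clades$taxonB, function(a, b) {
    if (a == b) {
      abort(sprintf("Clade '%s': taxonA and taxonB must differ.",
                    clades$clade[clades$taxonA == a & clades$taxonB == b][1]))
    }
    as.integer(ape::getMRCA(phy, c(a, b)))
  })
  if (anyDuplicated(mrca_node)) {
    dup <- clades$clade[duplicated(mrca_node) | duplicated(mrca_node, fromLast = TRUE)]
    abort(sprintf("Clades resolve to the same MRCA node: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  parent_of <- function(node) {
    if (node == root) return(NA_integer_)
    phy$edge[phy$edge[, 2] == node, 1]
  }
  mrca_age <- tree$node_age[mrca_node]
  stem_age <- purrr::map_dbl(mrca_node, function(v) {
    p <- parent_of(v)
    if (is.na(p)) tree$root_age else tree$node_age[p]
  })
  out <- clades
  out$missing <- as.integer(out$missing)
  if (any(out$missing < 0)) abort("Missing-species counts must be >= 0.")
  out$mrca_node <- mrca_node
  out$mrca_age <- mrca_age
  out$stem_age <- stem_age
  m <- n + sum(out$missing)
  attr(out, "n_sampled") <- n
  attr(out, "m_total") <- m
  attr(out, "rho") <- n / m
  out
}

# internal: accept either a resolved table or resolve on the fly
validate_resolved_clades <- function(clades, tree) {
  if (is.null(attr(clades, "m_total")) || !("mrca_age" %in% names(clades))) {
    clades <- resolve_clades(tree, clades)
  }
  clades
}
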