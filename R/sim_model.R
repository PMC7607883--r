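# --- species-tree / species-network model objects -------------------------
#
# Branch lengths are in coalescent units (time / 2N). Node "ages" are
# measured backwards from the most recent tip. The constructors precompute
# the traversal tables the simulation kernel needs, so per-gene simulation
# does no tree bookkeeping.

.prep_sptree <- function(phy) {
  phy <- ape::reorder.phylo(phy, "cladewise")
  m <- length(phy$tip.label)
  if (m < 2L) stop("species tree needs at least 2 tips")
  if (!ape::is.rooted(phy)) stop("species tree must be rooted")
  if (!ape::is.binary(phy)) stop("species tree must be binary")
  if (is.null(phy$edge.length) || anyNA(phy$edge.length))
    stop("species tree needs branch lengths (coalescent units)")
  if (any(phy$edge.length < 0)) stop("negative branch length")
  depth <- ape::node.depth.edgelength(phy)
  age <- max(depth) - depth
  kids <- .children(phy)
  parent <- integer(m + phy$Nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  inner <- (m + 1L):(m + phy$Nnode)
  # topological level (edges from root), for breaking age ties so that a
  # child population is always merged before its parent (zero-length
  # internal branches make node ages coincide)
  lvl <- integer(m + phy$Nnode)
  for (i in seq_len(nrow(phy$edge)))   # ape edges are in preorder
    lvl[phy$edge[i, 2L]] <- lvl[phy$edge[i, 1L]] + 1L
  list(m = m, tips = phy$tip.label, age = age, kids = kids,
       parent = parent, root = m + 1L,
       merge_order = inner[order(age[inner], -lvl[inner])])
}

#' Construct a species tree in coalescent units
#'
#' @param x a rooted binary `phylo` or a newick string; branch lengths are
#'   coalescent units (time scaled by 2N). The root branch is implicitly
#'   infinite. Ultrametricity is not required.
#' @return an object of class `species_tree`.
#' @seealso [species_network()], [simulate_gene_trees()]
#' @export
species_tree <- function(x) {
  phy <- if (inherits(x, "phylo")) x else ape::read.tree(text = x)
  if (is.null(phy)) stop("could not parse species tree")
  structure(c(list(phy = phy), .prep_sptree(phy)), class = "species_tree")
}

#' @export
print.species_tree <- function(x, ...) {
  cat("Species tree (coalescent units),", x$m, "taxa:",
      paste(x$tips, collapse = ", "), "\n")
  invisible(x)
}

# locate the edge above the MRCA of `taxa` (or above a single tip);
# returns the child-node id identifying that edge
.edge_above <- function(prep, phy, taxa) {
  idx <- match(taxa, prep$tips)
  if (anyNA(idx)) stop("unknown taxa: ",
                       paste(taxa[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(idx)
  node <- ape::getMRCA(phy, taxa)
  if (node == prep$root) stop("edge above the root does not exist")
  node
}

#' Construct a one-reticulation species network
#'
#' Adds a single reticulation to a species tree: at time `t_hybrid`, every
#' gene lineage sitting on the *recipient* edge independently switches to
#' the *donor* edge's population with inheritance probability `gamma`
#' (instantaneous admixture, the standard network multispecies-coalescent
#' convention). Both edges must span `t_hybrid`.
#'
#' @param tree a `species_tree` (or anything [species_tree()] accepts).
#' @param recipient,donor character vectors of tip labels; each identifies
#'   the edge above the MRCA of those tips (a single label names a
#'   terminal edge).
#' @param gamma inheritance probability in `[0, 1]` of the minor (donor)
#'   parent.
#' @param t_hybrid age (coalescent units before present) of the
#'   reticulation.
#' @return an object of class `species_network` (inherits the species-tree
#'   fields).
#' @export
species_network <- function(tree, recipient, donor, gamma, t_hybrid) {
  if (!inherits(tree, "species_tree")) tree <- species_tree(tree)
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1)
    stop("gamma must be a probability in [0, 1]")
  rc <- .edge_above(tree, tree$phy, recipient)
  dc <- .edge_above(tree, tree$phy, donor)
  if (rc == dc) stop("recipient and donor edges must differ")
  span <- function(child) c(tree$age[child], tree$age[tree$parent[child]])
  rs <- span(rc); ds <- span(dc)
  eps <- 1e-12
  if (t_hybrid < rs[1] - eps || t_hybrid > rs[2] + eps)
    stop("t_hybrid outside the recipient edge's time span [",
         signif(rs[1], 4), ", ", signif(rs[2], 4), "]")
  if (t_hybrid < ds[1] - eps || t_hybrid > ds[2] + eps)
    stop("t_hybrid outside the donor edge's time span [",
         signif(ds[1], 4), ", ", signif(ds[2], 4), "]")
  out <- unclass(tree)
  out$recipient <- rc
  out$donor <- dc
  out$gamma <- gamma
  out$t_hybrid <- t_hybrid
  structure(out, class = c("species_network", "species_tree"))
}

#' @export
print.species_network <- function(x, ...) {
  cat("Species network (coalescent units),", x$m, "taxa, one reticulation\n")
  lab <- function(child) if (child <= x$m) x$tips[child]
         else paste0("MRCA(",
                     paste(x$tips[.tips_under(x, child)], collapse = ","), ")")
  cat("  recipient edge above", lab(x$recipient),
      "| donor edge above", lab(x$donor), "\n")
  cat("  gamma =", x$gamma, " t_hybrid =", x$t_hybrid, "\n")
  invisible(x)
}

.tips_under <- function(prep, node) {
  if (node <= prep$m) return(node)
  out <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= prep$m) out <- c(out, v) else stack <- c(stack, prep$kids[[v]])
  }
  out
}

#' The four-taxon species model of the Steganinae rooted-quartet problem
#'
#' Species tree `(((pair, other), dros), out)` with the pair divergence at
#' age `t_pair`, the internal branch controlling incomplete lineage
#' sorting of length `T`, and an optional reticulation in which the pair
#' representative's lineage joins the Drosophilinae representative's
#' ancestral population with probability `gamma` at age
#' `t_pair + T - T_prime` (so the minor parental tree has internal branch
#' `T_prime`; `T <= T_prime <= T + t_pair` is required).
#'
#' Defaults are calibrated by moment inversion of the published quartet
#' topology percentages (47.7 / 36.3 / 16.0), giving `T = 0.734` and
#' `gamma = 0.390` under `T_prime = T`. The quartet class distribution
#' depends only on `T`, `T_prime` and `gamma`, not on `t_pair` or
#' `outgroup_depth`.
#'
#' @param T internal branch length (coalescent units) of the major tree.
#' @param T_prime internal branch of the minor (introgression) parental
#'   tree; default `T`.
#' @param gamma inheritance probability; 0 gives a plain species tree.
#' @param taxa named labels `pair`, `other`, `dros`, `out`.
#' @param t_pair age of the pair divergence; default 1.
#' @param outgroup_depth length of the branch separating the ingroup root
#'   from the outgroup divergence; default 3.
#' @return a `species_network` (or `species_tree` when `gamma = 0`).
#' @export
quartet_network <- function(T = 0.734, T_prime = T, gamma = 0.390,
                            taxa = c(pair = "Pv", other = "Rb",
                                     dros = "Dm", out = "Eh"),
                            t_pair = 1, outgroup_depth = 3) {
  stopifnot(T >= 0, T_prime >= 0, t_pair > 0, outgroup_depth > 0)
  t2 <- t_pair + T
  t3 <- t2 + outgroup_depth
  nwk <- sprintf("(((%s:%.10g,%s:%.10g):%.10g,%s:%.10g):%.10g,%s:%.10g);",
                 taxa[["pair"]], t_pair, taxa[["other"]], t_pair, T,
                 taxa[["dros"]], t2, outgroup_depth, taxa[["out"]], t3)
  st <- species_tree(nwk)
  if (gamma == 0) return(st)
  if (T_prime < T || T_prime > T + t_pair)
    stop("need T <= T_prime <= T + t_pair for the reticulation to sit on ",
         "the pair representative's terminal edge")
  species_network(st, recipient = taxa[["pair"]], donor = taxa[["dros"]],
                  gamma = gamma, t_hybrid = t2 - T_prime)
}

#' Default 10-taxon drosophilid species tree (coalescent units)
#'
#' Topology `((Eh,Eg),((Rb,(Pv,Ci)),(Dm,(Dv,(Sl,(Cx,Ca))))))` matching
#' [drosophilid_groups()]. The Steganinae stem branch is 0.734 coalescent
#' units (the moment inversion of the published quartet frequencies);
#' remaining branches are set so that the simulated topology-class mix is
#' drosophilid-like: a compact Drosophilinae crown (subfamily paraphyly
#' rare), a long Pv+Ci stem (alternative Steganinae pairings rare), and a
#' deep outgroup.
#'
#' @return a `species_tree`.
#' @export
drosophilid_species_tree <- function() {
  species_tree(paste0(
    "((Eh:2,Eg:2):7.3,",
    "((Rb:5.566,(Pv:2.466,Ci:2.466):3.1):0.734,",
    "(Dm:1,(Dv:0.75,(Sl:0.5,(Cx:0.25,Ca:0.25):0.25):0.25):0.25):5.3):3);"))
}

#' Default 10-taxon drosophilid network with one reticulation
#'
#' [drosophilid_species_tree()] plus a reticulation from the ancestral
#' Drosophilinae lineage (donor) into the Phortica+Cacoxenus stem
#' (recipient) at the age of the Steganinae crown, mirroring the
#' four-taxon model of [quartet_network()].
#'
#' @param gamma inheritance probability; default 0.390.
#' @return a `species_network`.
#' @export
drosophilid_network <- function(gamma = 0.390) {
  species_network(drosophilid_species_tree(),
                  recipient = c("Pv", "Ci"),
                  donor = c("Dm", "Dv", "Sl", "Cx", "Ca"),
                  gamma = gamma, t_hybrid = 5.566)
}
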