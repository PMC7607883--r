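.full_classes <- c("A", "B", "C", "E", "F", "other_para_steg", "dros_para",
                   "unclassifiable")
.quartet_classes <- c("match", "mismatch_PD", "mismatch_RD")

# children lists from an edge matrix
.children <- function(tree) {
  N <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", N)
  e <- tree$edge
  for (i in seq_len(nrow(e))) kids[[e[i, 1L]]] <- c(kids[[e[i, 1L]]], e[i, 2L])
  kids
}

# the set of clades of a rooted tree, as sorted "|"-joined tip-label keys
.clade_keys <- function(tree) {
  m <- length(tree$tip.label)
  kids <- .children(tree)
  N <- m + tree$Nnode
  sets <- vector("list", N)
  # postorder: process nodes in an order where children come first
  po <- rev(.preorder_nodes(tree, kids))
  for (v in po) {
    sets[[v]] <- if (v <= m) tree$tip.label[v]
                 else sort(unlist(sets[kids[[v]]]))
  }
  vapply(sets[(m + 1L):N], paste, character(1), collapse = "|")
}

.preorder_nodes <- function(tree, kids = .children(tree)) {
  m <- length(tree$tip.label)
  root <- m + 1L
  out <- integer(m + tree$Nnode)
  stack <- root; n <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    n <- n + 1L; out[n] <- v
    stack <- c(stack, kids[[v]])
  }
  out[seq_len(n)]
}

.key <- function(taxa) paste(sort(taxa), collapse = "|")

#' Is a taxon set a clade of a rooted tree?
#'
#' `TRUE` iff some node's descendant leaf set equals `taxa` exactly.
#'
#' @param tree a rooted `phylo`.
#' @param taxa non-empty subset of the tree's leaves.
#' @return logical.
#' @export
is_clade <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"), length(taxa) >= 1L)
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (length(taxa) == 1L) return(TRUE)
  .key(taxa) %in% .clade_keys(tree)
}

#' Classify a rooted gene tree with respect to subfamily monophyly
#'
#' Labels, checked in order: `dros_para` if Drosophilinae is not a clade;
#' with Steganinae monophyletic, `A`/`E`/`F` by which Steganinae pair is a
#' clade (`A`: the species-tree pair; `E`: pair representative with the
#' basal candidate; `F`: the other pair member with the basal candidate);
#' with Steganinae paraphyletic, `B` when the pair clade groups with
#' Drosophilinae to the exclusion of the basal candidate, `C` when the
#' basal candidate groups with Drosophilinae to the exclusion of the pair,
#' otherwise `other_para_steg`. Trees whose outgroup was not monophyletic
#' may be reported `unclassifiable` via `nonmono`.
#'
#' @param tree a rooted `phylo` (root via [root_on_outgroup()] first).
#' @param groups a [taxon_groups()] object.
#' @param outgroup_monophyletic logical from the rooting step.
#' @param nonmono what to do when `outgroup_monophyletic` is `FALSE`:
#'   classify on the fallback rooting (`"classify"`, the default) or
#'   return `"unclassifiable"`.
#' @return one of `"A"`, `"B"`, `"C"`, `"E"`, `"F"`, `"other_para_steg"`,
#'   `"dros_para"`, `"unclassifiable"`.
#' @export
classify_topology <- function(tree, groups, outgroup_monophyletic = TRUE,
                              nonmono = c("classify", "unclassifiable")) {
  stopifnot(inherits(tree, "phylo"), inherits(groups, "taxon_groups"))
  nonmono <- match.arg(nonmono)
  need <- c(groups$steganinae, groups$drosophilinae, groups$outgroup)
  missing <- setdiff(need, tree$tip.label)
  if (length(missing)) stop("taxa missing from tree: ",
                            paste(missing, collapse = ", "))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!outgroup_monophyletic && nonmono == "unclassifiable")
    return("unclassifiable")
  keys <- .clade_keys(tree)
  has <- function(taxa) length(taxa) == 1L || .key(taxa) %in% keys
  dros <- groups$drosophilinae
  steg <- groups$steganinae
  pair <- groups$steg_pair
  basal <- groups$steg_other
  if (!has(dros)) return("dros_para")
  if (has(steg)) {
    if (has(pair)) return("A")
    if (has(c(pair[1], basal))) return("E")
    if (has(c(pair[2], basal))) return("F")
    return("unclassifiable")  # only reachable on non-binary trees
  }
  if (has(pair) && has(c(pair, dros))) return("B")
  if (has(pair) && has(c(basal, dros))) return("C")
  "other_para_steg"
}

# quartet class of a 4-leaf binary tree given representative labels,
# via the unrooted split: any cherry determines it.
.quartet_class4 <- function(tree, reps) {
  m <- 4L
  e <- tree$edge
  tipidx <- match(reps, tree$tip.label)
  if (anyNA(tipidx)) stop("missing representative taxa")
  is_tip_row <- e[, 2L] <= m
  par_of_tip <- e[is_tip_row, 1L][order(e[is_tip_row, 2L])]
  tab <- table(par_of_tip)
  cherry_par <- as.integer(names(tab)[tab >= 2L][1])
  cherry <- which(par_of_tip == cherry_par)[1:2]  # tip numbers
  side <- tree$tip.label[cherry]
  pair <- if (reps[["out"]] %in% side)
    setdiff(tree$tip.label, side) else side
  pair <- setdiff(pair, reps[["out"]])
  if (setequal(pair, c(reps[["pair"]], reps[["other"]]))) return("match")
  if (setequal(pair, c(reps[["pair"]], reps[["dros"]]))) return("mismatch_PD")
  if (setequal(pair, c(reps[["other"]], reps[["dros"]]))) return("mismatch_RD")
  stop("quartet does not contain the four representatives")
}

#' Reduce a gene tree to the four representative taxa and classify it
#'
#' Restricts the tree to the quartet representatives (suppressing
#' degree-two nodes), roots on the outgroup representative, and reports
#' which ingroup pair is sister: the species-tree pair (`"match"`), the
#' pair representative with the Drosophilinae representative
#' (`"mismatch_PD"`), or the basal candidate with the Drosophilinae
#' representative (`"mismatch_RD"`).
#'
#' @param tree a `phylo` containing the four representatives (more taxa
#'   are pruned away).
#' @param groups a [taxon_groups()] object.
#' @return one of `"match"`, `"mismatch_PD"`, `"mismatch_RD"`.
#' @export
prune_to_quartet <- function(tree, groups) {
  stopifnot(inherits(tree, "phylo"), inherits(groups, "taxon_groups"))
  reps <- groups$quartet
  missing <- setdiff(reps, tree$tip.label)
  if (length(missing)) stop("missing representative taxa: ",
                            paste(missing, collapse = ", "))
  if (length(tree$tip.label) > 4L)
    tree <- ape::keep.tip(tree, unname(reps))
  .quartet_class4(tree, reps)
}

# canonical (sorted-child, topology-only) newick of a rooted tree
.canonical_newick <- function(tree) {
  kids <- .children(tree)
  m <- length(tree$tip.label)
  render <- function(v) {
    if (v <= m) return(tree$tip.label[v])
    parts <- sort(vapply(kids[[v]], render, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(render(m + 1L), ";")
}

#' Census gene trees by topology class
#'
#' Roots every tree with [root_on_outgroup()], classifies it with either
#' the full 10-taxon classifier ([classify_topology()]) or the quartet
#' classifier ([prune_to_quartet()]), and tabulates counts and
#' frequencies. A per-gene table records each tree's class, whether its
#' outgroup was monophyletic, and (for the full classifier) the canonical
#' newick of the tree pruned to the quartet representatives plus the
#' Steganinae, as a detail column for sub-class granularity.
#'
#' @param trees a `phylo` or list of `phylo` objects (names are gene ids).
#' @param groups a [taxon_groups()] object.
#' @param classifier `"full"` or `"quartet"`.
#' @param nonmono passed to [classify_topology()].
#' @return an object of class `topology_census`: list with `counts`
#'   (named integer vector over all classes), `n_total`, `frequencies`,
#'   `classifier` and `genes` (per-gene data frame).
#' @export
census <- function(trees, groups, classifier = c("full", "quartet"),
                   nonmono = c("classify", "unclassifiable")) {
  classifier <- match.arg(classifier)
  nonmono <- match.arg(nonmono)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("g%04d", seq_along(trees))
  classes <- if (classifier == "full") .full_classes else .quartet_classes
  lab <- character(length(trees))
  og_mono <- logical(length(trees))
  detail <- character(length(trees))
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (classifier == "quartet") {
      lab[i] <- prune_to_quartet(tr, groups)
      og_mono[i] <- TRUE
      detail[i] <- NA_character_
    } else {
      rt <- root_on_outgroup(tr, groups$outgroup)
      og_mono[i] <- rt$outgroup_monophyletic
      lab[i] <- classify_topology(rt$tree, groups, rt$outgroup_monophyletic,
                                  nonmono = nonmono)
      keep <- unique(c(groups$steganinae, unname(groups$quartet)))
      detail[i] <- .canonical_newick(ape::keep.tip(rt$tree, keep))
    }
  }
  counts <- table(factor(lab, levels = classes))
  counts <- setNames(as.integer(counts), classes)
  n <- length(trees)
  structure(list(counts = counts, n_total = n,
                 frequencies = counts / n,
                 classifier = classifier,
                 genes = data.frame(gene_id = ids, class = lab,
                                    outgroup_monophyletic = og_mono,
                                    detail = detail,
                                    stringsAsFactors = FALSE)),
            class = "topology_census")
}

#' @export
print.topology_census <- function(x, ...) {
  cat("Topology census (", x$classifier, " classifier, n = ", x$n_total,
      ")\n", sep = "")
  shown <- x$counts[x$counts > 0 | names(x$counts) %in% .quartet_classes]
  for (cl in names(shown))
    cat(sprintf("  %-16s %6d  (%.1f%%)\n", cl, x$counts[[cl]],
                100 * x$frequencies[[cl]]))
  if (x$classifier == "full") {
    nm <- sum(!x$genes$outgroup_monophyletic)
    if (nm) cat("  [", nm, "tree(s) with non-monophyletic outgroup ]\n")
  }
  invisible(x)
}

#' Exact binomial test of mismatch-topology symmetry
#'
#' Under incomplete lineage sorting alone the two mismatch topologies are
#' equally probable; an excess of one signals another process such as
#' introgression. Two-sided exact binomial test of p = 1/2 (all outcome
#' probabilities not exceeding that of the observed outcome are summed).
#'
#' @param n_mismatch_major,n_mismatch_minor non-negative counts of the two
#'   mismatch classes (not both zero).
#' @return an object of class `htest` (see [stats::binom.test()]); the
#'   p-value is in `$p.value`.
#' @export
symmetry_test <- function(n_mismatch_major, n_mismatch_minor) {
  stopifnot(n_mismatch_major >= 0, n_mismatch_minor >= 0)
  if (n_mismatch_major + n_mismatch_minor == 0)
    stop("both mismatch counts are zero")
  ht <- binom.test(n_mismatch_major, n_mismatch_major + n_mismatch_minor,
                   p = 0.5)
  ht$data.name <- paste0("mismatch counts (", n_mismatch_major, ", ",
                         n_mismatch_minor, ")")
  ht
}

#' Stratify quartet topology frequencies by Muller element
#'
#' Builds the topologies-by-element contingency table and tests homogeneity
#' of topology proportions across chromosome arms with a chi-square test;
#' when any expected count is below 5 the p-value is computed by Monte
#' Carlo permutation (fixed seed, `B` replicates). Genes without a mapping
#' are reported and excluded from the test.
#'
#' @param labels per-gene quartet classes: a named character vector
#'   (names are gene ids) or a data frame with columns `gene_id`, `class`.
#' @param muller_map data frame with columns `gene_id`, `element`.
#' @param B Monte Carlo replicates; default 10000.
#' @param mc_seed seed for the Monte Carlo p-value; default 1.
#' @return a list with `table` (topologies x elements), `test` (`htest`),
#'   `monte_carlo` (logical), `n_unmapped`.
#' @export
stratify_by_muller <- function(labels, muller_map, B = 10000, mc_seed = 1) {
  if (is.data.frame(labels))
    labels <- setNames(labels$class, labels$gene_id)
  stopifnot(all(c("gene_id", "element") %in% names(muller_map)))
  el <- muller_map$element[match(names(labels), muller_map$gene_id)]
  unmapped <- is.na(el)
  if (all(unmapped)) stop("all genes unmapped to a Muller element")
  lab <- factor(labels[!unmapped], levels = .quartet_classes)
  el <- factor(el[!unmapped])
  if (nlevels(el) < 2L) stop("fewer than 2 Muller elements represented")
  tab <- table(topology = lab, element = el)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]  # avoid zero-row df inflation
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  mc <- any(expected < 5)
  test <- if (mc) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(mc_seed)
    suppressWarnings(chisq.test(tab, simulate.p.value = TRUE, B = B))
  } else chisq.test(tab, correct = FALSE)
  list(table = tab, test = test, monte_carlo = mc,
       n_unmapped = sum(unmapped))
}

#' Enumerate all rooted binary topologies over a leaf set
#'
#' Generates the `(2n - 3)!!` rooted binary trees by sequential leaf
#' insertion (every edge plus a new root position). All branch lengths are
#' set to 1. Useful for exhaustive classifier checks; n = 6 already gives
#' 945 trees.
#'
#' @param labels character vector of 2 or more leaf labels.
#' @return a list of rooted `phylo` objects.
#' @export
all_rooted_topologies <- function(labels) {
  stopifnot(length(labels) >= 2L)
  insert_all <- function(t, x) {
    if (!is.list(t)) return(list(list(t, x)))
    out <- list(list(t, x))  # above the root of this subtree
    for (side in 1:2) {
      for (sub in insert_all(t[[side]], x)) {
        t2 <- t
        t2[[side]] <- sub
        out <- c(out, list(t2))
      }
    }
    out
  }
  trees <- list(labels[1])
  for (x in labels[-1])
    trees <- unlist(lapply(trees, insert_all, x = x), recursive = FALSE)
  render <- function(t) {
    if (!is.list(t)) return(paste0(t, ":1"))
    paste0("(", render(t[[1]]), ",", render(t[[2]]), "):1")
  }
  lapply(trees, function(t) ape::read.tree(text = paste0(render(t), ";")))
}
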