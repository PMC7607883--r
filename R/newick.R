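#' Read gene trees from newick
#'
#' Thin validating wrapper around [ape::read.tree()]. Accepts a path to a
#' file holding one or more newick trees (one per line) or a literal newick
#' string. Internal node support labels are tolerated and retained in
#' `node.label` but never used by the topology classifiers.
#'
#' @param x path to a newick file or a newick string (must end in `;`).
#' @return for a single tree a `phylo`; for several a (multiPhylo-like)
#'   list of `phylo` objects.
#' @export
read_gene_trees <- function(x) {
  tr <- if (length(x) == 1L && grepl(";", x, fixed = TRUE) && !file.exists(x))
    ape::read.tree(text = x)
  else {
    if (!file.exists(x)) stop("newick file not found: ", x)
    ape::read.tree(x)
  }
  if (is.null(tr)) stop("could not parse newick input (unbalanced parentheses?)")
  trees <- if (inherits(tr, "phylo")) list(tr) else unclass(tr)
  for (t in trees) validate_gene_tree(t)
  if (length(trees) == 1L) trees[[1]] else trees
}

#' @rdname read_gene_trees
#' @export
read_newick <- function(x) {
  tr <- read_gene_trees(x)
  if (!inherits(tr, "phylo"))
    stop("expected a single newick tree, found ", length(tr))
  tr
}

validate_gene_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length)) stop("missing branch length on some edge")
    if (any(tree$edge.length < 0)) stop("negative branch length")
  }
  invisible(tree)
}

#' Write gene trees to newick
#'
#' Branch lengths are printed with 10 significant digits so that
#' `read -> write -> read` round-trips topology and branch lengths.
#'
#' @param trees a `phylo` or a list of `phylo` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_trees <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(t) ape::write.tree(t, digits = 10),
                character(1))
  writeLines(txt, path)
  invisible(path)
}
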