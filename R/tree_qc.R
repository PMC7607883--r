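#' Sum of branch lengths (SBL) of a gene tree
#'
#' The total of all edge lengths, a rooting-independent proxy for
#' annotation problems: frame-shifted or paralogous sequences inflate it.
#'
#' @param tree a `phylo` with branch lengths on every edge.
#' @return a non-negative number.
#' @export
sum_branch_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length))
    stop("missing branch length(s)")
  sum(tree$edge.length)
}

#' Root a gene tree on an outgroup
#'
#' If the outgroup taxa form a clade on the unrooted tree, the root is
#' placed on that clade's stem edge and the stem length is split equally
#' between the two root children. Otherwise the tree is rooted on the
#' terminal edge of the first outgroup taxon in `priority` order and
#' `outgroup_monophyletic` is `FALSE`.
#'
#' @param tree a `phylo` (rooted trees are unrooted first).
#' @param outgroup character vector of outgroup taxa.
#' @param priority tip order used for the fallback rooting; defaults to
#'   `outgroup` order.
#' @return a list with elements `tree` (rooted `phylo`) and
#'   `outgroup_monophyletic` (logical).
#' @export
root_on_outgroup <- function(tree, outgroup, priority = outgroup) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  unknown <- setdiff(outgroup, tips)
  if (length(unknown)) stop("outgroup taxa not in tree: ",
                            paste(unknown, collapse = ", "))
  if (length(outgroup) >= length(tips))
    stop("outgroup cannot contain all taxa")
  un <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  mono <- length(outgroup) == 1L ||
    ape::is.monophyletic(un, outgroup) ||
    ape::is.monophyletic(un, setdiff(tips, outgroup))
  og <- if (mono) outgroup else priority[priority %in% tips][1]
  rooted <- ape::root(un, outgroup = og, resolve.root = TRUE)
  # split the root (stem) edge length equally between the two basal edges
  if (!is.null(rooted$edge.length)) {
    rn <- length(rooted$tip.label) + 1L
    basal <- which(rooted$edge[, 1L] == rn)
    if (length(basal) == 2L)
      rooted$edge.length[basal] <- sum(rooted$edge.length[basal]) / 2
  }
  list(tree = rooted, outgroup_monophyletic = mono)
}

#' Variance of root-to-tip path lengths
#'
#' Sample variance (n - 1 denominator) of the distances from the root to
#' every leaf. Zero for ultrametric trees; large values indicate rate
#' heterogeneity or misannotation. Unlike [sum_branch_lengths()] this
#' depends on the rooting.
#'
#' @param tree a rooted `phylo`.
#' @return a non-negative number.
#' @export
root_to_tip_variance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  var(depths)
}

#' Flag abnormally long terminal branches (putative paralogs)
#'
#' Returns the taxa whose terminal branch exceeds `k` times the median
#' terminal branch length of the tree. The median (not the mean) is used
#' so the statistic is robust to the outlier being screened for.
#'
#' @param tree a `phylo` with >= 4 leaves and branch lengths.
#' @param k multiplier above the median; default 10.
#' @return character vector of flagged taxa (possibly empty).
#' @export
flag_long_terminal_branches <- function(tree, k = 10) {
  stopifnot(inherits(tree, "phylo"), k > 1)
  m <- length(tree$tip.label)
  if (m < 4L) stop("need at least 4 leaves")
  term <- tree$edge[, 2L] <= m
  len <- tree$edge.length[term]
  taxa <- tree$tip.label[tree$edge[term, 2L]]
  taxa[len > k * median(len)]
}

#' Compute per-gene QC records for a list of gene trees
#'
#' For each tree: SBL, root-to-tip variance (after [root_on_outgroup()];
#' trees with a non-monophyletic outgroup still get a variance from the
#' fallback rooting), and long-terminal-branch flags.
#'
#' @param trees a list of `phylo` objects (names become gene ids).
#' @param outgroup outgroup taxa for rooting.
#' @param long_branch_factor `k` for [flag_long_terminal_branches()].
#' @return a data frame with columns `gene_id`, `sbl`, `rtt_variance`,
#'   `outgroup_monophyletic`, `flagged_taxa` (comma-separated), `removed`,
#'   `removed_reason`.
#' @export
qc_gene_trees <- function(trees, outgroup, long_branch_factor = 10) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("g%04d", seq_along(trees))
  rows <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    rt <- root_on_outgroup(tr, outgroup)
    data.frame(
      gene_id = ids[i],
      sbl = sum_branch_lengths(tr),
      rtt_variance = root_to_tip_variance(rt$tree),
      outgroup_monophyletic = rt$outgroup_monophyletic,
      flagged_taxa = paste(
        flag_long_terminal_branches(tr, k = long_branch_factor),
        collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$removed <- FALSE
  out$removed_reason <- NA_character_
  out
}

#' Remove the top-quantile SBL / root-to-tip-variance outlier genes
#'
#' A gene is removed iff its descending rank in SBL is within the top
#' `1 - quantile` fraction, or likewise for root-to-tip variance (the
#' union of the two criteria). Exactly `ceiling((1 - quantile) * n)` genes
#' are taken per criterion (nearest-rank convention); when
#' `(1 - quantile) * n < 1` nothing is removed and a warning is issued.
#'
#' @param records data frame from [qc_gene_trees()] (needs `gene_id`,
#'   `sbl`, `rtt_variance`).
#' @param quantile retained fraction per criterion; default 0.95 removes
#'   the top 5% of each.
#' @return `records` with `removed` and `removed_reason` filled in
#'   (`"sbl"`, `"rtt_variance"` or `"sbl+rtt_variance"`).
#' @export
filter_outliers <- function(records, quantile = 0.95) {
  stopifnot(is.data.frame(records), quantile > 0, quantile < 1)
  n <- nrow(records)
  k_raw <- (1 - quantile) * n
  if (k_raw < 1 - 1e-9) {
    warning("too few records (", n, ") for a ", signif(1 - quantile, 3),
            " tail to remove any gene")
    records$removed <- FALSE
    records$removed_reason <- NA_character_
    return(records)
  }
  # guard against floating-point noise around integer tail sizes
  k <- ceiling(k_raw - 1e-9)
  top_sbl <- head(order(records$sbl, decreasing = TRUE), k)
  top_rtt <- head(order(records$rtt_variance, decreasing = TRUE), k)
  records$removed <- seq_len(n) %in% union(top_sbl, top_rtt)
  reason <- character(n)
  reason[top_sbl] <- "sbl"
  reason[top_rtt] <- ifelse(nzchar(reason[top_rtt]), "sbl+rtt_variance",
                            "rtt_variance")
  records$removed_reason <- ifelse(nzchar(reason), reason, NA_character_)
  records
}
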