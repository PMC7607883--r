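#' Define the taxon groups used by the topology classifiers
#'
#' Partitions the leaf set into the two subfamilies and the outgroup and
#' names the four quartet representatives. Within Steganinae,
#' `steg_pair` names the two genera expected to be sisters on the species
#' tree (Phortica-like and Cacoxenus-like); the remaining Steganinae
#' taxon (Rhinoleucophenga-like) is the candidate first-diverging lineage.
#'
#' @param steganinae,drosophilinae,outgroup disjoint character vectors
#'   covering all leaves.
#' @param steg_pair two Steganinae taxa forming the species-tree pair; the
#'   first is also the quartet representative of the pair clade.
#' @param quartet named character vector with entries `pair`
#'   (pair-clade representative), `other` (the remaining Steganinae
#'   taxon), `dros` (Drosophilinae representative) and `out` (outgroup
#'   representative).
#' @return an object of class `taxon_groups`.
#' @seealso [drosophilid_groups()] for the default 10-taxon configuration.
#' @export
taxon_groups <- function(steganinae, drosophilinae, outgroup,
                         steg_pair = steganinae[1:2],
                         quartet = c(pair = steg_pair[1],
                                     other = setdiff(steganinae, steg_pair)[1],
                                     dros = drosophilinae[1],
                                     out = outgroup[1])) {
  sets <- list(steganinae = steganinae, drosophilinae = drosophilinae,
               outgroup = outgroup)
  all_taxa <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_taxa))
    stop("steganinae, drosophilinae and outgroup must be disjoint")
  if (!all(steg_pair %in% steganinae) || length(steg_pair) != 2L)
    stop("steg_pair must name two Steganinae taxa")
  need <- c("pair", "other", "dros", "out")
  if (!all(need %in% names(quartet)))
    stop("quartet must have entries ", paste(need, collapse = ", "))
  quartet <- quartet[need]
  if (!quartet[["pair"]] %in% steg_pair ||
      !quartet[["other"]] %in% setdiff(steganinae, steg_pair) ||
      !quartet[["dros"]] %in% drosophilinae ||
      !quartet[["out"]] %in% outgroup)
    stop("quartet representatives inconsistent with the group sets")
  structure(list(steganinae = steganinae, drosophilinae = drosophilinae,
                 outgroup = outgroup, steg_pair = steg_pair,
                 steg_other = setdiff(steganinae, steg_pair),
                 quartet = quartet),
            class = "taxon_groups")
}

#' @export
print.taxon_groups <- function(x, ...) {
  cat("Taxon groups\n")
  cat("  Steganinae:   ", paste(x$steganinae, collapse = ", "),
      " (pair: ", paste(x$steg_pair, collapse = "+"), ")\n", sep = "")
  cat("  Drosophilinae:", paste(x$drosophilinae, collapse = ", "), "\n")
  cat("  Outgroup:     ", paste(x$outgroup, collapse = ", "), "\n")
  cat("  Quartet:      ", paste(names(x$quartet), x$quartet, sep = "=",
                                collapse = ", "), "\n")
  invisible(x)
}

#' Default 10-taxon drosophilid group configuration
#'
#' Three Steganinae (Rb = Rhinoleucophenga, Pv = Phortica, Ci = Cacoxenus),
#' five Drosophilinae (Dm, Dv, Sl, Cx, Ca) and two Ephydridae outgroup
#' taxa (Eh, Eg). The quartet representatives are Pv (pair clade), Rb,
#' Dm and Eh.
#'
#' @return a `taxon_groups` object.
#' @export
drosophilid_groups <- function() {
  taxon_groups(steganinae = c("Rb", "Pv", "Ci"),
               drosophilinae = c("Dm", "Dv", "Sl", "Cx", "Ca"),
               outgroup = c("Eh", "Eg"),
               steg_pair = c("Pv", "Ci"),
               quartet = c(pair = "Pv", other = "Rb", dros = "Dm",
                           out = "Eh"))
}
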