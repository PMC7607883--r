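# shared fixture builders (everything is generated in code)

fixture_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

fixture_busco_tsv <- function(ids, statuses) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("# BUSCO version is: test",
               paste(ids, statuses, "contig", sep = "\t")), path)
  path
}

# an ortholog_table built from raw per-taxon sequence vectors:
# seqs[[taxon]][gene] -> sequence, every gene Complete everywhere
fixture_ortholog_table <- function(seqs) {
  taxa <- names(seqs)
  genes <- names(seqs[[1]])
  tables <- lapply(taxa, function(tx)
    data.frame(busco_id = genes, status = "Complete", taxon = tx,
               stringsAsFactors = FALSE))
  names(tables) <- taxa
  collect_complete_orthologs(tables, seqs)
}

# relabelled 10-taxon worked-example topologies (branch lengths 1)
fig_tree_A <- function()
  read_gene_trees(paste0("((Eh:1,Eg:1):1,((Rb:1,(Pv:1,Ci:1):1):1,",
                         "(Dm:1,(Dv:1,(Sl:1,(Cx:1,Ca:1):1):1):1):1):1);"))
fig_tree_B <- function()
  read_gene_trees(paste0("((Eh:1,Eg:1):1,(Rb:1,((Pv:1,Ci:1):1,",
                         "(Dm:1,(Dv:1,(Sl:1,(Cx:1,Ca:1):1):1):1):1):1):1);"))

# independent clade test used as an oracle: ape::prop.part bipartitions
oracle_is_clade <- function(tree, taxa) {
  if (length(taxa) == 1L) return(taxa %in% tree$tip.label)
  parts <- ape::prop.part(tree)
  any(vapply(parts, function(i) setequal(tree$tip.label[i], taxa),
             logical(1)))
}

# brute-force topology classifier: tests every relevant subset for
# cladehood with the prop.part oracle, mirroring the published decision
# rules but none of the package's clade machinery
oracle_classify <- function(rooted, groups) {
  has <- function(s) oracle_is_clade(rooted, s)
  dros <- groups$drosophilinae
  pair <- groups$steg_pair
  basal <- groups$steg_other
  if (!has(dros)) return("dros_para")
  if (has(groups$steganinae)) {
    if (has(pair)) return("A")
    if (has(c(pair[1], basal))) return("E")
    if (has(c(pair[2], basal))) return("F")
    return("unclassifiable")
  }
  if (has(pair) && has(c(pair, dros))) return("B")
  if (has(pair) && has(c(basal, dros))) return("C")
  "other_para_steg"
}
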