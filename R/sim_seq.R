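# --- sequence evolution and desk-scale tree inference ---------------------

#' Evolve sequences along a gene tree under Jukes-Cantor
#'
#' The root sequence is uniform over `{A,C,G,T}` (or supplied via
#' `root_seq`); each site evolves independently with expected number of
#' substitutions `subst_rate * branch length`. A thin wrapper around
#' [phangorn::simSeq()].
#'
#' @param tree a `phylo` with finite branch lengths.
#' @param seq_length number of sites (>= 1).
#' @param subst_rate substitutions per site per coalescent unit;
#'   default 1.
#' @param root_seq optional root sequence (string over ACGT).
#' @return named character vector of upper-case sequences, one per tip.
#' @export
evolve_jc69 <- function(tree, seq_length, subst_rate = 1, root_seq = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (seq_length < 1) stop("seq_length must be >= 1")
  if (subst_rate < 0) stop("subst_rate must be non-negative")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)))
    stop("tree must have finite branch lengths")
  tr <- tree
  tr$edge.length <- tr$edge.length * subst_rate
  rootseq <- NULL
  if (!is.null(root_seq)) {
    root_seq <- toupper(root_seq)
    if (nchar(root_seq) != seq_length)
      stop("root_seq length must equal seq_length")
    rootseq <- tolower(strsplit(root_seq, "")[[1]])
  }
  sim <- phangorn::simSeq(tr, l = seq_length, rootseq = rootseq,
                          type = "DNA")
  mat <- as.character(sim)
  setNames(toupper(apply(mat, 1L, paste, collapse = "")), rownames(mat))
}

#' Random stop-codon-free coding sequence
#'
#' Samples codons uniformly from the 61 sense codons; optionally appends a
#' terminal stop codon. Used as a root sequence so that reading-frame
#' recovery has a well-defined ground truth.
#'
#' @param n_codons number of sense codons.
#' @param terminal_stop append a stop codon (default `TRUE`).
#' @return a nucleotide string of length `3 * n_codons (+ 3)`.
#' @export
random_coding_sequence <- function(n_codons, terminal_stop = TRUE) {
  stopifnot(n_codons >= 1)
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  sense <- setdiff(all_codons, .stop_codons)
  out <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  if (terminal_stop) out <- paste0(out, sample(.stop_codons, 1L))
  out
}

# replace internal stop codons (frame +1) with random sense codons:
# emulates purifying selection against nonsense mutations, which the
# codon-blind JC simulation lacks. The terminal codon is left alone.
.repair_stops <- function(sequence) {
  ncod <- nchar(sequence) %/% 3L
  cod <- .codons(substr(sequence, 1L, 3L * ncod))
  bad <- which(cod[-ncod] %in% .stop_codons)
  if (!length(bad)) return(sequence)
  bases <- c("A", "C", "G", "T")
  sense <- setdiff(as.vector(outer(outer(bases, bases, paste0), bases,
                                   paste0)), .stop_codons)
  cod[bad] <- sample(sense, length(bad), replace = TRUE)
  paste0(paste(cod, collapse = ""),
         substr(sequence, 3L * ncod + 1L, nchar(sequence)))
}

# JC-evolve a single sequence along one branch of d expected
# substitutions per site (exact endpoint distribution)
.jc_mutate <- function(sequence, d) {
  if (d <= 0) return(sequence)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  x <- strsplit(sequence, "")[[1]]
  hit <- runif(length(x)) < p & x != "N"
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    x[hit] <- vapply(x[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  }
  paste(x, collapse = "")
}

#' Neighbor-joining gene tree from aligned sequences
#'
#' Pairwise Jukes-Cantor distances
#' `d = -(3/4) log(1 - (4/3) p)` (`p` the mismatch fraction over sites
#' where neither sequence is N), then neighbor joining. Saturated pairs
#' (`p >= 3/4`) receive the cap distance. A desk-scale stand-in for
#' maximum-likelihood gene-tree inference in end-to-end tests.
#'
#' @param sequences named character vector of >= 3 equal-length sequences.
#' @param cap distance assigned to saturated pairs; default 5.
#' @return an unrooted `phylo`.
#' @export
infer_nj_tree <- function(sequences, cap = 5) {
  stopifnot(is.character(sequences), length(sequences) >= 3L,
            !is.null(names(sequences)))
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must have equal lengths")
  mat <- do.call(rbind, strsplit(tolower(sequences), ""))
  rownames(mat) <- names(sequences)
  bin <- ape::as.DNAbin(mat)
  d <- suppressWarnings(ape::dist.dna(bin, model = "JC69",
                                      pairwise.deletion = TRUE))
  d[!is.finite(d)] <- cap
  ape::nj(d)
}

#' Inject BUSCO-style artifacts into a per-gene sequence set
#'
#' Emulates the two annotation artifacts seen in BUSCO output: reading
#' frames starting at +2/+3 (one or two random bases prepended to a
#' sampled fraction of (gene, taxon) cells) and paralog substitution (for
#' a sampled fraction of genes, one random taxon's sequence is re-evolved
#' along an extra branch of `paralog_extra_subs` expected substitutions
#' per site, emulating a paralog an order of magnitude more divergent than
#' the true ortholog). Paralog cells are excluded from frame-shift
#' sampling. A ground-truth ledger records every injection; its
#' `recoverable` column marks frame-shifted cells whose original
#' translation was free of internal stops (only those have a
#' well-defined best offset).
#'
#' @param sequences named list `gene -> named character vector
#'   (taxon -> sequence)`.
#' @param frame_shift_fraction fraction of cells to frame-shift.
#' @param paralog_fraction fraction of genes receiving a paralog.
#' @param paralog_extra_subs extra expected substitutions per site for
#'   injected paralogs; default 1.5.
#' @return list with `sequences` (corrupted set) and `ledger` (data frame
#'   `gene_id`, `taxon`, `type`, `offset`, `recoverable`).
#' @export
inject_artifacts <- function(sequences, frame_shift_fraction,
                             paralog_fraction, paralog_extra_subs = 1.5) {
  stopifnot(frame_shift_fraction >= 0, frame_shift_fraction <= 1,
            paralog_fraction >= 0, paralog_fraction <= 1)
  genes <- names(sequences)
  led <- list()
  bases <- c("A", "C", "G", "T")
  paralog_genes <- genes[runif(length(genes)) < paralog_fraction]
  paralog_taxon <- setNames(character(length(paralog_genes)), paralog_genes)
  for (g in paralog_genes) {
    tx <- sample(names(sequences[[g]]), 1L)
    paralog_taxon[g] <- tx
    sequences[[g]][tx] <- .jc_mutate(sequences[[g]][tx], paralog_extra_subs)
    led[[length(led) + 1L]] <- data.frame(
      gene_id = g, taxon = tx, type = "paralog", offset = NA_integer_,
      recoverable = NA, stringsAsFactors = FALSE)
  }
  for (g in genes) {
    for (tx in names(sequences[[g]])) {
      if (g %in% paralog_genes && paralog_taxon[g] == tx) next
      if (runif(1L) >= frame_shift_fraction) next
      off <- sample(1:2, 1L)
      orig <- sequences[[g]][tx]
      stop_free <- .stop_profile(substr(orig, 1L,
                                        (nchar(orig) %/% 3L) * 3L))$internal == 0L
      sequences[[g]][tx] <- paste0(
        paste(sample(bases, off, replace = TRUE), collapse = ""), orig)
      led[[length(led) + 1L]] <- data.frame(
        gene_id = g, taxon = tx, type = "frame_shift", offset = off,
        recoverable = stop_free, stringsAsFactors = FALSE)
    }
  }
  ledger <- if (length(led)) do.call(rbind, led)
            else data.frame(gene_id = character(), taxon = character(),
                            type = character(), offset = integer(),
                            recoverable = logical(), stringsAsFactors = FALSE)
  list(sequences = sequences, ledger = ledger)
}
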