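#' Assemble the cross-species single-copy ortholog table
#'
#' Retains exactly the genes that are `Complete` in every taxon's BUSCO
#' table *and* have a sequence for every taxon; every other gene is
#' recorded with a removal reason (`not_complete_in:<taxon>` or
#' `missing_sequence:<taxon>`).
#'
#' @param busco_tables named list (one entry per taxon) of data frames from
#'   [read_busco_table()].
#' @param sequences named list (same taxa) of either data frames from
#'   [read_fasta()] or named character vectors `gene_id -> sequence`.
#' @return an object of class `ortholog_table`: a list with elements
#'   `taxa`, `genes` (retained gene ids), `seq` (list `gene -> named
#'   character vector by taxon`), `offsets` (frame offsets per cell, filled
#'   by [fix_table_frames()]), `removed` (data frame `gene_id`,
#'   `removed_reason`) and `qc` (per-gene CV table, filled by
#'   [cv_filter()]).
#' @export
collect_complete_orthologs <- function(busco_tables, sequences) {
  taxa <- names(busco_tables)
  if (is.null(taxa) || any(!nzchar(taxa)))
    stop("busco_tables must be a named list (names are taxa)")
  missing_seq_taxa <- setdiff(taxa, names(sequences))
  if (length(missing_seq_taxa))
    stop("taxon present in BUSCO tables but absent from sequence sets: ",
         paste(missing_seq_taxa, collapse = ", "))
  seq_map <- lapply(sequences[taxa], function(s) {
    if (is.data.frame(s)) setNames(s$sequence, s$gene_id) else s
  })
  status <- lapply(busco_tables, function(tb) setNames(tb$status, tb$busco_id))
  genes <- sort(unique(unlist(lapply(status, names))))
  removed <- character(0); removed_ids <- character(0)
  seq_list <- list()
  for (g in genes) {
    st <- vapply(taxa, function(tx) {
      s <- status[[tx]][g]
      if (is.na(s)) "Missing" else s
    }, character(1))
    if (any(st != "Complete")) {
      tx <- taxa[which(st != "Complete")[1]]
      removed_ids <- c(removed_ids, g)
      removed <- c(removed, paste0("not_complete_in:", tx))
      next
    }
    sq <- vapply(taxa, function(tx) {
      v <- seq_map[[tx]][g]
      if (is.null(v) || is.na(v)) NA_character_ else unname(v)
    }, character(1))
    if (anyNA(sq)) {
      tx <- taxa[which(is.na(sq))[1]]
      removed_ids <- c(removed_ids, g)
      removed <- c(removed, paste0("missing_sequence:", tx))
      next
    }
    seq_list[[g]] <- setNames(sq, taxa)
  }
  structure(list(
    taxa = taxa,
    genes = names(seq_list),
    seq = seq_list,
    offsets = list(),
    removed = data.frame(gene_id = removed_ids, removed_reason = removed,
                         stringsAsFactors = FALSE),
    qc = NULL
  ), class = "ortholog_table")
}

#' @export
print.ortholog_table <- function(x, ...) {
  cat("Ortholog table:", length(x$genes), "retained gene(s) x",
      length(x$taxa), "taxa\n")
  if (nrow(x$removed)) {
    reason <- sub(":.*$", "", x$removed$removed_reason)
    tab <- table(reason)
    cat("Removed:", nrow(x$removed), "gene(s) (",
        paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
  }
  invisible(x)
}

.drop_genes <- function(table, genes, reasons) {
  keep <- !(table$genes %in% genes)
  table$removed <- rbind(table$removed,
                         data.frame(gene_id = genes, removed_reason = reasons,
                                    stringsAsFactors = FALSE))
  table$seq <- table$seq[table$genes[keep]]
  table$genes <- table$genes[keep]
  table
}

#' Apply reading-frame correction to every cell of an ortholog table
#'
#' Runs [fix_frame()] on every (gene, taxon) sequence, records the chosen
#' offsets, and (by default) removes genes where some cell remained
#' `"unfixable"` (internal stop codons at every offset).
#'
#' @param table an `ortholog_table`.
#' @param reference_proteins optional named list `gene -> amino-acid
#'   string` used as the identity tie-break.
#' @param drop_unfixable remove genes with unfixable cells
#'   (`removed_reason = "unfixable_frame:<taxon>"`).
#' @return the updated `ortholog_table` (`offsets[[gene]]` holds the
#'   per-taxon offsets).
#' @export
fix_table_frames <- function(table, reference_proteins = NULL,
                             drop_unfixable = TRUE) {
  stopifnot(inherits(table, "ortholog_table"))
  unfix_gene <- character(0); unfix_reason <- character(0)
  for (g in table$genes) {
    ref <- if (is.null(reference_proteins)) NULL else reference_proteins[[g]]
    res <- lapply(table$seq[[g]], fix_frame, reference_protein = ref)
    table$seq[[g]] <- setNames(vapply(res, `[[`, character(1), "sequence"),
                               table$taxa)
    table$offsets[[g]] <- setNames(vapply(res, `[[`, numeric(1), "offset"),
                                   table$taxa)
    flagged <- vapply(res, function(r) !is.na(r$flag), logical(1))
    if (any(flagged)) {
      unfix_gene <- c(unfix_gene, g)
      unfix_reason <- c(unfix_reason,
                        paste0("unfixable_frame:",
                               table$taxa[which(flagged)[1]]))
    }
  }
  if (drop_unfixable && length(unfix_gene))
    table <- .drop_genes(table, unfix_gene, unfix_reason)
  table
}

#' Filter genes by the coefficient of variation of protein size
#'
#' Computes, per gene, the CV of [protein_length()] across taxa and removes
#' genes whose CV strictly exceeds `cv_threshold` (reason
#' `"cv_exceeded"`). Lengths should be computed on frame-fixed sequences,
#' so call [fix_table_frames()] first.
#'
#' @param table an `ortholog_table`.
#' @param cv_threshold removal threshold, a fraction in (0, 1);
#'   default 0.10.
#' @param sd_flavor `"sample"` (n-1 denominator, the default) or
#'   `"population"`.
#' @return the updated table; `table$qc` gains columns `gene_id`, `cv`,
#'   `mean_length`, `removed_reason`.
#' @export
cv_filter <- function(table, cv_threshold = 0.10,
                      sd_flavor = c("sample", "population")) {
  stopifnot(inherits(table, "ortholog_table"),
            cv_threshold > 0, cv_threshold < 1)
  sd_flavor <- match.arg(sd_flavor)
  if (length(table$taxa) < 2L)
    stop("CV undefined for a single taxon")
  cv <- mean_len <- setNames(numeric(length(table$genes)), table$genes)
  for (g in table$genes) {
    len <- vapply(table$seq[[g]], protein_length, integer(1))
    m <- mean(len)
    if (m == 0) stop("mean protein length is zero for gene ", g)
    s <- sd(len)
    if (sd_flavor == "population")
      s <- s * sqrt((length(len) - 1) / length(len))
    cv[g] <- s / m
    mean_len[g] <- m
  }
  removed <- names(cv)[cv > cv_threshold]
  qc <- data.frame(gene_id = names(cv), cv = unname(cv),
                   mean_length = unname(mean_len),
                   removed_reason = ifelse(names(cv) %in% removed,
                                           "cv_exceeded", NA_character_),
                   stringsAsFactors = FALSE)
  table$qc <- if (is.null(table$qc)) qc else rbind(table$qc, qc)
  if (length(removed))
    table <- .drop_genes(table, removed, rep("cv_exceeded", length(removed)))
  table
}

#' Write the per-gene curation report of an ortholog table as TSV
#'
#' One row per gene ever seen: per-taxon protein lengths, CV, frame
#' offsets and the removal reason (empty for retained genes).
#'
#' @param table an `ortholog_table` (after [cv_filter()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ortholog_qc <- function(table, path) {
  stopifnot(inherits(table, "ortholog_table"))
  rows <- lapply(table$genes, function(g) {
    len <- vapply(table$seq[[g]], protein_length, integer(1))
    off <- table$offsets[[g]]
    if (is.null(off)) off <- rep(NA_integer_, length(table$taxa))
    cv <- if (!is.null(table$qc)) table$qc$cv[match(g, table$qc$gene_id)]
          else NA_real_
    c(gene_id = g, setNames(as.list(len), paste0("len_", table$taxa)),
      cv = cv, setNames(as.list(off), paste0("offset_", table$taxa)),
      removed_reason = "")
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  if (nrow(table$removed)) {
    extra <- data.frame(gene_id = table$removed$gene_id)
    for (cn in setdiff(names(df), c("gene_id", "removed_reason")))
      extra[[cn]] <- NA
    extra$removed_reason <- table$removed$removed_reason
    df <- rbind(df, extra[names(df)])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
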