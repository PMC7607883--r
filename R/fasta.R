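#' Read a FASTA file of per-gene coding sequences
#'
#' Reads plain (wrapped or unwrapped) nucleotide FASTA. Headers are parsed as
#' `"gene<delim>taxon"`; with `delim = NULL` the whole header is taken as the
#' taxon and `gene_id` must be supplied by the caller. Sequences are
#' upper-cased and validated against the alphabet `{A,C,G,T,N}`.
#'
#' @param path path to a FASTA file.
#' @param delim single-character delimiter separating gene id and taxon in
#'   the header, or `NULL` for taxon-only headers.
#' @param gene_id gene id to use for every record when `delim` is `NULL`.
#' @return a `data.frame` with columns `gene_id`, `taxon`, `sequence`, one
#'   row per record in file order. An empty file returns a zero-row frame
#'   with a warning.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, delim = "|", gene_id = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  empty <- data.frame(gene_id = character(), taxon = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(empty)
  }
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!any(is_hdr)) {
    warning("no FASTA records in: ", path)
    return(empty)
  }
  if (!is_hdr[match(TRUE, nzchar(trimws(lines)))])
    stop("malformed FASTA: sequence data before first header in ", path)
  grp <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # records with no sequence lines at all
  all_grp <- as.character(seq_along(headers))
  seqs <- unname(seqs[all_grp])
  seqs[is.na(seqs)] <- ""
  seqs <- toupper(gsub("[ \t]", "", seqs))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in record(s): ",
         paste(headers[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("zero-length sequence for header(s): ",
         paste(headers[!nzchar(seqs)], collapse = ", "))
  if (is.null(delim)) {
    gid <- rep(gene_id, length(headers))
    taxon <- headers
  } else {
    pos <- regexpr(delim, headers, fixed = TRUE)
    if (any(pos < 0)) {
      i <- which(pos < 0)[1]
      line_no <- which(is_hdr)[i]
      stop("malformed FASTA header (no '", delim, "' delimiter) at line ",
           line_no, ": ", headers[i])
    }
    gid <- substr(headers, 1L, pos - 1L)
    taxon <- substr(headers, pos + nchar(delim), nchar(headers))
  }
  if (any(!nzchar(taxon)) || (!is.null(delim) && any(!nzchar(gid)))) {
    i <- which(!nzchar(taxon) | !nzchar(gid))[1]
    stop("empty gene id or taxon in header at line ", which(is_hdr)[i],
         ": ", headers[i])
  }
  data.frame(gene_id = gid, taxon = taxon, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records a `data.frame` with columns `gene_id`, `taxon`,
#'   `sequence` (as returned by [read_fasta()]), or a named character
#'   vector of sequences (names are taxa; headers are then taxon-only).
#' @param path output path.
#' @param delim delimiter joining gene id and taxon in headers; ignored for
#'   named-vector input.
#' @param width line width for sequence wrapping; `Inf` writes one line per
#'   sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, delim = "|", width = Inf) {
  if (is.character(records) && !is.null(names(records)))
    records <- data.frame(gene_id = NA_character_, taxon = names(records),
                          sequence = unname(records), stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "sequence") %in% names(records)))
  hdr <- if (!"gene_id" %in% names(records) || all(is.na(records$gene_id)))
    records$taxon else paste0(records$gene_id, delim, records$taxon)
  wrap <- function(s) {
    if (!is.finite(width) || nchar(s) <= width) return(s)
    n <- nchar(s)
    substring(s, seq(1, n, width), pmin(seq(1, n, width) + width - 1, n))
  }
  out <- unlist(lapply(seq_len(nrow(records)), function(i)
    c(paste0(">", hdr[i]), wrap(records$sequence[i]))))
  writeLines(out, path)
  invisible(path)
}
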