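.busco_statuses <- c("Complete", "Duplicated", "Fragmented", "Missing")

#' Read a BUSCO full-table summary
#'
#' Parses the tab-separated `full_table*.tsv` written by BUSCO (comment
#' lines start with `#`; first two columns are the BUSCO id and its
#' status). Ids reported several times (the `Duplicated` case) are
#' collapsed to a single row with status `Duplicated`.
#'
#' @param path path to the TSV.
#' @param taxon taxon (assembly) the table belongs to.
#' @return a `data.frame` with columns `busco_id`, `status`, `taxon`.
#' @export
read_busco_table <- function(path, taxon) {
  if (!file.exists(path)) stop("BUSCO table not found: ", path)
  stopifnot(is.character(taxon), length(taxon) == 1L, nzchar(taxon))
  raw <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "",
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("expected at least 2 tab-separated columns in ", path)
  df <- data.frame(busco_id = raw[[1]], status = raw[[2]], taxon = taxon,
                   stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$status), .busco_statuses)
  if (length(bad))
    stop("unknown BUSCO status token(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$busco_id)) {
    dup_ids <- unique(df$busco_id[duplicated(df$busco_id)])
    df <- df[!duplicated(df$busco_id), , drop = FALSE]
    df$status[df$busco_id %in% dup_ids] <- "Duplicated"
  }
  rownames(df) <- NULL
  df
}
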