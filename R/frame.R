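.stop_codons <- c("TAA", "TAG", "TGA")

# split a frame-trimmed CDS (length divisible by 3) into codons
.codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

# number of internal stop codons and whether the final codon is a stop.
# Codons containing N never count as stops.
.stop_profile <- function(seq) {
  cod <- .codons(seq)
  k <- length(cod)
  is_stop <- cod %in% .stop_codons
  list(internal = sum(is_stop[-k]), terminal = is_stop[k])
}

.translate <- function(seq) {
  # seqinr uses NCBI codes; ambiguous codons (with N) become X
  toupper(paste(seqinr::translate(seqinr::s2c(tolower(seq)), ambiguous = TRUE),
                collapse = ""))
}

# fraction of matching positions over the shorter of the two strings
.identity <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0)
  mean(substring(a, 1:n, 1:n) == substring(b, 1:n, 1:n))
}

#' Correct the reading frame of a BUSCO-extracted CDS
#'
#' BUSCO occasionally extracts coding sequences starting at frame +2 or +3
#' instead of +1. `fix_frame` tries the three possible offsets, trims
#' `offset` leading bases plus any trailing remainder (so the output length
#' is divisible by 3), and keeps the offset whose translation has the
#' fewest internal stop codons. Ties are broken by (i) presence of a
#' terminal stop codon, (ii) highest translation identity to
#' `reference_protein` when given, (iii) the smallest offset. If even the
#' best offset retains internal stops the record is flagged `"unfixable"`
#' so the gene can be removed downstream.
#'
#' @param sequence a nucleotide string over `{A,C,G,T,N}`, length >= 6.
#' @param reference_protein optional amino-acid string used as tie-break.
#' @return a list with elements `sequence` (trimmed CDS), `offset`
#'   (0, 1 or 2 leading bases dropped) and `flag` (`NA` or `"unfixable"`).
#' @examples
#' fix_frame("ATGGCTAAATAA")$offset            # already in frame: 0
#' fix_frame("GATGGCTAAATAA")$offset           # one spurious leading base: 1
#' @export
fix_frame <- function(sequence, reference_protein = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence))
    stop("non-ACGTN characters in sequence")
  if (nchar(sequence) < 6L) stop("sequence shorter than 6 bases")
  cand <- lapply(0:2, function(off) {
    sub <- substring(sequence, off + 1L)
    len <- (nchar(sub) %/% 3L) * 3L
    if (len < 3L) return(NULL)
    sub <- substr(sub, 1L, len)
    c(list(sequence = sub, offset = off), .stop_profile(sub))
  })
  cand <- Filter(Negate(is.null), cand)
  internal <- vapply(cand, `[[`, numeric(1), "internal")
  best <- which(internal == min(internal))
  if (length(best) > 1L) {
    term <- vapply(cand[best], `[[`, logical(1), "terminal")
    if (any(term) && !all(term)) best <- best[term]
  }
  if (length(best) > 1L && !is.null(reference_protein)) {
    ident <- vapply(cand[best], function(x)
      .identity(.translate(x$sequence), toupper(reference_protein)),
      numeric(1))
    best <- best[ident == max(ident)]
  }
  pick <- cand[[best[1L]]]  # candidates are ordered by offset
  list(sequence = pick$sequence, offset = pick$offset,
       flag = if (pick$internal > 0L) "unfixable" else NA_character_)
}

#' Protein length implied by a frame-trimmed CDS
#'
#' `floor(nchar(seq) / 3)`, minus one if the final codon is a stop codon.
#'
#' @param sequence nucleotide string (after [fix_frame()]).
#' @return integer protein length.
#' @export
protein_length <- function(sequence) {
  n <- nchar(sequence) %/% 3L
  if (n == 0L) return(0L)
  last <- substr(sequence, 3L * n - 2L, 3L * n)
  n - as.integer(last %in% .stop_codons)
}
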