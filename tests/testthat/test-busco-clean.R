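test_that("collect_complete_orthologs keeps the all-Complete intersection", {
  tables <- list(
    A = data.frame(busco_id = c("g1", "g2", "g3"),
                   status = c("Complete", "Complete", "Complete"),
                   taxon = "A"),
    B = data.frame(busco_id = c("g1", "g2", "g3"),
                   status = c("Complete", "Missing", "Complete"),
                   taxon = "B"))
  seqs <- list(A = c(g1 = "ATGAAA", g2 = "ATGAAA", g3 = "ATGCCC"),
               B = c(g1 = "ATGAAA", g2 = "ATGAAA", g3 = "ATGCCC"))
  tab <- collect_complete_orthologs(tables, seqs)
  expect_setequal(tab$genes, c("g1", "g3"))
  expect_equal(tab$removed$removed_reason[tab$removed$gene_id == "g2"],
               "not_complete_in:B")
})

test_that("a Complete gene with a missing sequence is removed as such", {
  tables <- list(A = data.frame(busco_id = "g1", status = "Complete",
                                taxon = "A"),
                 B = data.frame(busco_id = "g1", status = "Complete",
                                taxon = "B"))
  seqs <- list(A = c(g1 = "ATGAAA"), B = c(other = "ATGAAA"))
  tab <- collect_complete_orthologs(tables, seqs)
  expect_length(tab$genes, 0L)
  expect_equal(tab$removed$removed_reason, "missing_sequence:B")

  expect_error(collect_complete_orthologs(tables, seqs["A"]),
               "absent from sequence sets")
})

test_that("retained set matches a brute-force scan of a toy status matrix", {
  set.seed(7)
  taxa <- c("A", "B", "C")
  genes <- sprintf("g%d", 1:5)
  status <- matrix(sample(c("Complete", "Missing", "Fragmented"), 15,
                          replace = TRUE, prob = c(0.7, 0.2, 0.1)),
                   nrow = 5, dimnames = list(genes, taxa))
  status[1:2, ] <- "Complete"            # guarantee at least two retained
  tables <- lapply(taxa, function(tx)
    data.frame(busco_id = genes, status = status[, tx], taxon = tx))
  names(tables) <- taxa
  seqs <- lapply(taxa, function(tx)
    setNames(rep("ATGAAATTT", 5), genes))
  names(seqs) <- taxa
  tab <- collect_complete_orthologs(tables, seqs)
  expected <- genes[apply(status == "Complete", 1, all)]  # oracle
  expect_setequal(tab$genes, expected)

  # idempotence: re-collecting from the retained table changes nothing
  tables2 <- lapply(taxa, function(tx)
    data.frame(busco_id = tab$genes, status = "Complete", taxon = tx))
  names(tables2) <- taxa
  seqs2 <- lapply(taxa, function(tx)
    vapply(tab$seq, `[[`, character(1), tx))
  names(seqs2) <- taxa
  tab2 <- collect_complete_orthologs(tables2, seqs2)
  expect_equal(tab2$seq, tab$seq)
})

test_that("fix_frame recovers the reading frame and reports flags", {
  r0 <- fix_frame("ATGGCTAAATAA")
  expect_equal(r0$offset, 0L)
  expect_equal(r0$sequence, "ATGGCTAAATAA")
  expect_true(is.na(r0$flag))

  # offset 0 has an internal TAA; offsets 1 and 2 are stop-free; the
  # terminal-stop tie-break picks offset 1 (enumerated by hand)
  r1 <- fix_frame("GATGGCTAAATAA")
  expect_equal(r1$offset, 1L)
  expect_equal(r1$sequence, "ATGGCTAAATAA")

  # internal stop at every offset (verified by enumerating all three)
  r2 <- fix_frame("CTAACGTGACATAAACTG")
  expect_equal(r2$flag, "unfixable")

  expect_error(fix_frame("ATGXCTAAATAA"), "non-ACGTN")
  expect_error(fix_frame("ATG"), "shorter")
})

test_that("fix_frame is idempotent and respects the reference tie-break", {
  r <- fix_frame("GATGGCTAAATAA")
  expect_equal(fix_frame(r$sequence)$offset, 0L)

  # offsets 0..2 of this sequence are all stop-free with no terminal
  # stop; the reference protein equals the offset-2 translation
  s <- "CGAGGAAACGGGGC"
  expect_equal(fix_frame(s)$offset, 0L)            # smallest-offset default
  expect_equal(fix_frame(s, reference_protein = "RKRG")$offset, 2L)
})

test_that("N never counts as a stop codon", {
  # TNA at codon 2 must not be treated as a stop
  expect_true(is.na(fix_frame("ATGTNAAAATAA")$flag))
})

test_that("cv_filter applies the strict 10% threshold to protein-size CV", {
  mk <- function(len) strrep("ATG", len)
  tab <- fixture_ortholog_table(list(
    t1 = c(g1 = mk(100), g2 = mk(90), g3 = mk(95)),
    t2 = c(g1 = mk(100), g2 = mk(100), g3 = mk(100)),
    t3 = c(g1 = mk(100), g2 = mk(110), g3 = mk(105)),
    t4 = c(g1 = mk(100), g2 = mk(100), g3 = mk(120))))
  # per-gene lengths: g1 (100,100,100,100) CV 0
  #                   g2 (90,100,110,100)  CV ~0.0816 -> retained
  #                   g3 (95,100,105,120)  CV ~0.1029 -> removed
  out <- cv_filter(tab)
  expect_setequal(out$genes, c("g1", "g2"))
  expect_equal(out$removed$removed_reason[out$removed$gene_id == "g3"],
               "cv_exceeded")
  qc <- out$qc
  expect_equal(qc$cv[qc$gene_id == "g1"], 0)
  expect_equal(qc$cv[qc$gene_id == "g3"],
               sd(c(95, 100, 105, 120)) / mean(c(95, 100, 105, 120)))
})

test_that("CV exactly at the threshold is retained (strict inequality)", {
  mk <- function(len) strrep("ATG", len)
  tab <- fixture_ortholog_table(list(
    t1 = c(g1 = mk(90)), t2 = c(g1 = mk(100)), t3 = c(g1 = mk(110))))
  # sample sd 10, mean 100 -> CV exactly 0.100
  out <- cv_filter(tab)
  expect_equal(out$genes, "g1")
  expect_equal(out$qc$cv, 0.1)
})

test_that("cv_filter rejects degenerate single-taxon tables", {
  tab <- fixture_ortholog_table(list(t1 = c(g1 = strrep("ATG", 10))))
  expect_error(cv_filter(tab), "single taxon")
})

test_that("cv_filter removals are invariant to taxon order", {
  set.seed(11)
  lens <- replicate(6, sample(80:120, 4), simplify = FALSE)
  mk <- function(len) strrep("ATG", len)
  build <- function(order) {
    seqs <- lapply(order, function(i)
      setNames(vapply(lens, function(l) mk(l[i]), character(1)),
               sprintf("g%d", seq_along(lens))))
    names(seqs) <- paste0("t", order)
    fixture_ortholog_table(seqs)
  }
  out1 <- cv_filter(build(1:4))
  out2 <- cv_filter(build(4:1))
  expect_setequal(out1$genes, out2$genes)
})

test_that("protein length subtracts a terminal stop codon", {
  expect_equal(protein_length("ATGGCT"), 2L)
  expect_equal(protein_length("ATGGCTTAA"), 2L)
})

test_that("fix_table_frames records offsets and drops unfixable genes", {
  good <- "GATGAAACCCGGGTTTACATAA"     # frame +2
  tab <- fixture_ortholog_table(list(
    t1 = c(g1 = good, g2 = "CTAACGTGACATAAACTG"),
    t2 = c(g1 = substring(good, 2), g2 = "ATGAAACCCTAA")))
  out <- fix_table_frames(tab)
  expect_equal(out$genes, "g1")
  expect_equal(unname(out$offsets$g1), c(1, 0))
  expect_match(out$removed$removed_reason[out$removed$gene_id == "g2"],
               "unfixable_frame")
})
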