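test_that("is_clade matches node leaf sets exactly", {
  tr <- read_gene_trees("((A:1,B:1):1,C:1);")
  expect_true(is_clade(tr, c("A", "B")))
  expect_false(is_clade(tr, c("A", "C")))
  expect_true(is_clade(tr, "C"))
  expect_error(is_clade(tr, c("A", "Z")), "unknown")
})

test_that("is_clade agrees with bipartition enumeration on all rooted 5-leaf trees", {
  trees <- all_rooted_topologies(c("A", "B", "C", "D", "E"))
  expect_length(trees, 105L)
  subsets <- unlist(lapply(2:4, function(k)
    combn(c("A", "B", "C", "D", "E"), k, simplify = FALSE)),
    recursive = FALSE)
  for (tr in trees) {
    for (s in subsets) {
      expect_equal(is_clade(tr, s), oracle_is_clade(tr, s),
                   info = paste(ape::write.tree(tr), paste(s, collapse = "")))
    }
  }
})

test_that("classify_topology reproduces the worked 10-taxon examples", {
  g <- drosophilid_groups()
  rtA <- root_on_outgroup(fig_tree_A(), g$outgroup)
  expect_equal(classify_topology(rtA$tree, g), "A")
  rtB <- root_on_outgroup(fig_tree_B(), g$outgroup)
  expect_equal(classify_topology(rtB$tree, g), "B")
  # Drosophilinae split by construction
  trD <- read_gene_trees(paste0("((Eh:1,Eg:1):1,((Rb:1,(Ci:1,Dm:1):1):1,",
                                "(Pv:1,(Dv:1,(Sl:1,(Cx:1,Ca:1):1):1):1):1):1);"))
  rtD <- root_on_outgroup(trD, g$outgroup)
  expect_equal(classify_topology(rtD$tree, g), "dros_para")
  # the internal Drosophilinae arrangement is irrelevant for class A
  trA2 <- read_gene_trees(paste0("((Eh:1,Eg:1):1,((Rb:1,(Pv:1,Ci:1):1):1,",
                                 "(Ca:1,(Sl:1,(Dv:1,(Cx:1,Dm:1):1):1):1):1):1);"))
  expect_equal(classify_topology(root_on_outgroup(trA2, g$outgroup)$tree, g),
               "A")
  expect_error(classify_topology(ape::drop.tip(rtA$tree, "Rb"), g),
               "missing")
})

test_that("class C and the remaining-paraphyly pool are recognized", {
  g <- drosophilid_groups()
  trC <- read_gene_trees(paste0("((Eh:1,Eg:1):1,((Pv:1,Ci:1):1,(Rb:1,",
                                "(Dm:1,(Dv:1,(Sl:1,(Cx:1,Ca:1):1):1):1):1):1):1);"))
  expect_equal(classify_topology(root_on_outgroup(trC, g$outgroup)$tree, g),
               "C")
  # Steganinae paraphyletic with the pair itself broken
  trO <- read_gene_trees(paste0("((Eh:1,Eg:1):1,(Pv:1,((Ci:1,Rb:1):1,",
                                "(Dm:1,(Dv:1,(Sl:1,(Cx:1,Ca:1):1):1):1):1):1):1);"))
  expect_equal(classify_topology(root_on_outgroup(trO, g$outgroup)$tree, g),
               "other_para_steg")
})

test_that("prune_to_quartet reads the ingroup sister pair", {
  g <- drosophilid_groups()
  expect_equal(prune_to_quartet(read_gene_trees("(Eh,(Dm,(Pv,Rb)));"), g),
               "match")
  expect_equal(prune_to_quartet(read_gene_trees("(Eh,(Rb,(Pv,Dm)));"), g),
               "mismatch_PD")
  expect_equal(prune_to_quartet(read_gene_trees("(Eh,(Pv,(Rb,Dm)));"), g),
               "mismatch_RD")
  # pruning the full worked example keeps the match pairing
  expect_equal(prune_to_quartet(fig_tree_A(), g), "match")
  expect_error(prune_to_quartet(read_gene_trees("(Eh,(Dm,(Pv,Ci)));"), g),
               "missing")
})

test_that("census tabulates counts and frequencies over fixed classes", {
  g <- drosophilid_groups()
  ten <- rep(list(fig_tree_A()), 10)
  cs <- census(ten, g)
  expect_equal(unname(cs$counts["A"]), 10L)
  expect_equal(unname(cs$frequencies[["A"]]), 1)
  expect_equal(sum(cs$counts), cs$n_total)

  mix <- c(rep(list(fig_tree_A()), 5), rep(list(fig_tree_B()), 3),
           rep(list(read_gene_trees(paste0(
             "((Eh:1,Eg:1):1,((Pv:1,Ci:1):1,(Rb:1,(Dm:1,(Dv:1,(Sl:1,",
             "(Cx:1,Ca:1):1):1):1):1):1):1);"))), 2))
  cs2 <- census(mix, g)
  expect_equal(unname(cs2$counts[c("A", "B", "C")]), c(5L, 3L, 2L))
  expect_equal(unname(cs2$frequencies[c("A", "B", "C")]), c(0.5, 0.3, 0.2))
  expect_equal(sum(cs2$frequencies), 1, tolerance = 1e-12)
  expect_error(census(list(), g), "at least one")
})

test_that("quartet census commutes with pre-pruning to the four taxa", {
  g <- drosophilid_groups()
  trees <- simulate_gene_trees(drosophilid_network(), 120, seed = 4)
  full <- census(trees, g, classifier = "quartet")
  pruned <- lapply(trees, ape::keep.tip, tip = unname(g$quartet))
  pre <- census(pruned, g, classifier = "quartet")
  expect_equal(full$counts, pre$counts)
})

test_that("high match frequency at a long internal branch", {
  g <- drosophilid_groups()
  trees <- simulate_gene_trees(quartet_network(T = 6, gamma = 0), 400,
                               seed = 8)
  cs <- census(trees, g, classifier = "quartet")
  expect_gt(cs$frequencies[["match"]], 0.99)
})

test_that("symmetry_test is the exact two-sided binomial", {
  # enumeration oracle: sum all outcome probabilities <= the observed one
  oracle <- function(a, b) {
    n <- a + b
    probs <- dbinom(0:n, n, 0.5)
    sum(probs[probs <= dbinom(a, n, 0.5) + 1e-12])
  }
  expect_equal(symmetry_test(5, 5)$p.value, 1)
  expect_equal(symmetry_test(8, 2)$p.value, 112 / 1024)
  expect_equal(symmetry_test(8, 2)$p.value, oracle(8, 2))
  expect_equal(symmetry_test(10, 0)$p.value, 2 / 1024)
  expect_equal(symmetry_test(363, 160)$p.value, oracle(363, 160))
  expect_error(symmetry_test(0, 0), "zero")
})

test_that("symmetry_test is symmetric and decreases with imbalance", {
  expect_equal(symmetry_test(7, 3)$p.value, symmetry_test(3, 7)$p.value)
  p <- vapply(0:5, function(d)
    symmetry_test(10 + d, 10 - d)$p.value, numeric(1))
  expect_true(all(diff(p) < 1e-12))
})

test_that("stratify_by_muller builds the table and homogeneity test", {
  mk_labels <- function(counts_by_el) {
    lab <- character(0); gene <- character(0); el <- character(0)
    i <- 0
    for (e in names(counts_by_el)) {
      ct <- counts_by_el[[e]]
      for (j in seq_along(ct)) {
        cl <- c("match", "mismatch_PD", "mismatch_RD")[j]
        if (ct[j] > 0) {
          ids <- sprintf("g%04d", i + seq_len(ct[j])); i <- i + ct[j]
          lab <- c(lab, rep(cl, ct[j])); gene <- c(gene, ids)
          el <- c(el, rep(e, ct[j]))
        }
      }
    }
    list(labels = setNames(lab, gene),
         map = data.frame(gene_id = gene, element = el))
  }
  # identical proportions across elements -> statistic 0, p = 1
  same <- mk_labels(list(A = c(30, 10, 10), B = c(30, 10, 10)))
  r1 <- stratify_by_muller(same$labels, same$map)
  expect_false(r1$monte_carlo)
  expect_equal(unname(r1$test$statistic), 0)
  expect_equal(r1$test$p.value, 1)

  # hand-computed statistic: expected (20,20,10) per row, chi-square 20
  asym <- mk_labels(list(A = c(30, 10, 10), B = c(10, 30, 10)))
  r2 <- stratify_by_muller(asym$labels, asym$map)
  expect_equal(unname(r2$test$statistic), 20, tolerance = 1e-12)
  expect_equal(unname(r2$test$parameter), 2)

  # unmapped genes are excluded and counted
  lab3 <- same$labels
  map3 <- same$map[1:60, ]
  r3 <- stratify_by_muller(lab3, map3)
  expect_equal(r3$n_unmapped, 40L)

  expect_error(stratify_by_muller(lab3, data.frame(gene_id = "zzz",
                                                   element = "A")),
               "unmapped")
  one_el <- mk_labels(list(A = c(30, 10, 10)))
  expect_error(stratify_by_muller(one_el$labels, one_el$map),
               "fewer than 2")
})

test_that("sparse tables switch to a seeded Monte Carlo p-value", {
  lab <- setNames(c(rep("match", 6), rep("mismatch_PD", 3),
                    rep("mismatch_RD", 3)), sprintf("g%02d", 1:12))
  map <- data.frame(gene_id = sprintf("g%02d", 1:12),
                    element = rep(c("A", "B"), 6))
  r <- stratify_by_muller(lab, map)
  expect_true(r$monte_carlo)
  r2 <- stratify_by_muller(lab, map)
  expect_equal(r$test$p.value, r2$test$p.value)  # fixed seed
})

test_that("all_rooted_topologies enumerates distinct rooted shapes", {
  expect_length(all_rooted_topologies(c("A", "B")), 1L)
  expect_length(all_rooted_topologies(c("A", "B", "C")), 3L)
  t4 <- all_rooted_topologies(c("A", "B", "C", "D"))
  expect_length(t4, 15L)
  keys <- vapply(t4, coalcensus:::.canonical_newick, character(1))
  expect_equal(anyDuplicated(keys), 0L)
})
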