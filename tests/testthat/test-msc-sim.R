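test_that("expected quartet frequencies follow the MSC closed form", {
  expect_equal(unname(expected_quartet_frequencies(0)),
               rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(unname(expected_quartet_frequencies(100)), c(1, 0, 0),
               tolerance = 1e-12)
  f <- expected_quartet_frequencies(0.734)
  expect_equal(unname(f), c(1 - 2 * exp(-0.734) / 3, exp(-0.734) / 3,
                            exp(-0.734) / 3))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_error(expected_quartet_frequencies(-0.1), "non-negative")
})

test_that("network frequencies reduce to pure ILS and mirror at gamma = 1", {
  expect_equal(unname(expected_network_frequencies(0.7, 0.9, 0))[c(1, 2)],
               unname(expected_quartet_frequencies(0.7))[c(1, 2)])
  g1 <- expected_network_frequencies(0.5, 1.2, 1)
  expect_equal(g1[["mismatch_major"]],
               expected_quartet_frequencies(1.2)[["match"]])
  f <- expected_network_frequencies(0.734, 0.734, 0.390)
  expect_equal(unname(f), c(0.4772, 0.3628, 0.1600), tolerance = 1e-4)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  expect_error(expected_network_frequencies(0.7, 0.7, 1.2), "gamma")
})

test_that("two-species coalescence is older than the divergence", {
  st <- species_tree("(A:1.5,B:1.5);")
  trees <- simulate_gene_trees(st, 50, seed = 2)
  for (tr in trees) {
    expect_setequal(tr$tip.label, c("A", "B"))
    root_age <- max(ape::node.depth.edgelength(tr))
    expect_gte(root_age, 1.5)
  }
})

test_that("gene-tree nodes never predate the species divergences", {
  model <- drosophilid_species_tree()
  sp <- model$phy
  sp_depth <- ape::node.depth.edgelength(sp)
  sp_age <- max(sp_depth) - sp_depth
  trees <- simulate_gene_trees(model, 30, seed = 6)
  for (tr in trees) {
    d <- ape::node.depth.edgelength(tr)
    age <- max(d) - d
    m <- length(tr$tip.label)
    for (v in (m + 1):(m + tr$Nnode)) {
      tips <- tr$tip.label[coalcensus:::.tips_under(
        list(m = m, kids = coalcensus:::.children(tr)), v)]
      sp_node <- if (length(tips) == length(sp$tip.label))
        length(sp$tip.label) + 1L else ape::getMRCA(sp, tips)
      expect_gte(age[v] + 1e-9, sp_age[sp_node])
    }
  }
})

test_that("star-tree limit gives uniform quartet classes within 3 sigma", {
  g <- drosophilid_groups()
  cs <- census(simulate_gene_trees(quartet_network(T = 0, gamma = 0), 3000,
                                   seed = 12),
               g, classifier = "quartet")
  sigma <- sqrt((1 / 3) * (2 / 3) / 3000)
  for (cl in names(cs$frequencies))
    expect_lt(abs(cs$frequencies[[cl]] - 1 / 3), 3 * sigma)
})

test_that("seeded simulation is reproducible bit-for-bit", {
  a <- simulate_gene_trees(drosophilid_network(), 5, seed = 99)
  b <- simulate_gene_trees(drosophilid_network(), 5, seed = 99)
  expect_identical(lapply(a, ape::write.tree), lapply(b, ape::write.tree))
})

test_that("evolve_jc69 honors the root sequence and zero rate", {
  tr <- read_gene_trees("(A:0.2,(B:0.1,C:0.1):0.1);")
  root <- strrep("ACGT", 25)
  sv <- evolve_jc69(tr, 100, subst_rate = 0, root_seq = root)
  expect_equal(unname(sv), rep(root, 3))
  set.seed(31); s1 <- evolve_jc69(tr, 50, 1)
  set.seed(31); s2 <- evolve_jc69(tr, 50, 1)
  expect_identical(s1, s2)
  expect_error(evolve_jc69(tr, 0), "seq_length")
})

test_that("divergence across one branch matches the JC closed form", {
  set.seed(17)
  tr <- read_gene_trees("(A:0,B:0.1073);")
  sv <- evolve_jc69(tr, 10000, subst_rate = 1)
  p <- mean(strsplit(sv[["A"]], "")[[1]] != strsplit(sv[["B"]], "")[[1]])
  p_exp <- 0.75 * (1 - exp(-4 * 0.1073 / 3))   # ~0.10
  expect_lt(abs(p - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
})

test_that("infer_nj_tree applies the JC correction and recovers topology", {
  # p = 0.1 -> d = -(3/4) log(1 - 4*0.1/3) ~ 0.1073
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 10), strrep("A", 90))
  svec <- c(t1 = a, t2 = b, t3 = a)
  tr <- infer_nj_tree(svec)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["t1", "t2"], -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(d["t1", "t3"], 0, tolerance = 1e-12)

  expect_error(infer_nj_tree(c(x = "AAA", y = "AAAA", z = "AAA")),
               "equal lengths")

  # round trip at generous branch lengths
  set.seed(23)
  gen <- read_gene_trees("(((A:0.3,B:0.3):0.3,C:0.6):0.3,D:0.9);")
  sv <- evolve_jc69(gen, 3000, 0.5)
  nj <- infer_nj_tree(sv)
  expect_equal(ape::dist.topo(ape::unroot(gen), nj), 0,
               ignore_attr = TRUE)
})

test_that("saturated pairs are capped, identical sequences give zero tree", {
  svec <- c(a = strrep("A", 40), b = strrep("C", 40), c = strrep("A", 40))
  tr <- infer_nj_tree(svec, cap = 5)
  d <- ape::cophenetic.phylo(tr)
  expect_equal(d["a", "b"], 5, tolerance = 1e-9)
  same <- c(a = strrep("ACG", 20), b = strrep("ACG", 20),
            c = strrep("ACG", 20))
  expect_equal(sum(infer_nj_tree(same)$edge.length), 0, tolerance = 1e-12)
})

test_that("inject_artifacts corrupts at the requested rates with a ledger", {
  set.seed(41)
  seqs <- lapply(setNames(nm = sprintf("g%03d", 1:100)), function(g)
    setNames(vapply(1:10, function(i) random_coding_sequence(50),
                    character(1)), paste0("t", 1:10)))
  none <- inject_artifacts(seqs, 0, 0)
  expect_identical(none$sequences, seqs)
  expect_equal(nrow(none$ledger), 0L)

  set.seed(41); a <- inject_artifacts(seqs, 0.1, 0.05)
  set.seed(41); b <- inject_artifacts(seqs, 0.1, 0.05)
  expect_identical(a$sequences, b$sequences)

  n_fs <- sum(a$ledger$type == "frame_shift")
  expect_lt(abs(n_fs - 100), 3 * sqrt(1000 * 0.1 * 0.9))
  # frame-shifted cells gained exactly the prepended prefix
  row1 <- a$ledger[a$ledger$type == "frame_shift", ][1, ]
  orig <- seqs[[row1$gene_id]][[row1$taxon]]
  corr <- a$sequences[[row1$gene_id]][[row1$taxon]]
  expect_equal(substring(corr, row1$offset + 1), orig)
})
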