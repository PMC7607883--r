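# --- multispecies-coalescent simulation kernel ----------------------------
#
# One haploid lineage is sampled per species. Within a population (a
# species-tree branch), while j >= 2 lineages remain the next coalescence
# is Exponential(rate j(j-1)/2) back in time, truncated at the branch top;
# survivors pass to the parent branch; the root population runs until a
# single lineage remains. On a network, each lineage present on the
# recipient edge at the reticulation age independently moves to the donor
# population with probability gamma.

# coalesce `pop` (vector of gene-node ids) from time t0 to t1;
# `st` is the mutable simulation state environment
.coalesce <- function(st, pop, t0, t1) {
  k <- length(pop)
  while (k >= 2L) {
    t0 <- t0 + rexp(1L, k * (k - 1L) / 2)
    if (t0 > t1) break
    ij <- sample.int(k, 2L)
    st$nnode <- st$nnode + 1L
    id <- st$nnode
    st$kid1[id] <- pop[ij[1L]]
    st$kid2[id] <- pop[ij[2L]]
    st$age[id] <- t0
    pop <- c(pop[-ij], id)
    k <- k - 1L
  }
  pop
}

.sim_msc_once <- function(model) {
  m <- model$m
  nmax <- 2L * m - 1L
  st <- new.env(parent = emptyenv())
  st$kid1 <- integer(nmax)
  st$kid2 <- integer(nmax)
  st$age <- numeric(nmax)
  st$age[1:m] <- model$age[1:m]
  st$nnode <- m
  npop <- length(model$age)
  pops <- vector("list", npop)
  cur <- numeric(npop)
  for (i in 1:m) { pops[[i]] <- i; cur[i] <- model$age[i] }
  hybrid <- inherits(model, "species_network")
  hybrid_done <- !hybrid
  for (v in model$merge_order) {
    a <- model$age[v]
    if (!hybrid_done && model$t_hybrid <= a) {
      # reticulation fires before any later (or simultaneous) merge
      rc <- model$recipient; dc <- model$donor
      pops[[rc]] <- .coalesce(st, pops[[rc]], cur[rc], model$t_hybrid)
      cur[rc] <- model$t_hybrid
      pops[[dc]] <- .coalesce(st, pops[[dc]], cur[dc], model$t_hybrid)
      cur[dc] <- model$t_hybrid
      k <- length(pops[[rc]])
      if (k) {
        go <- runif(k) < model$gamma
        pops[[dc]] <- c(pops[[dc]], pops[[rc]][go])
        pops[[rc]] <- pops[[rc]][!go]
      }
      hybrid_done <- TRUE
    }
    acc <- integer(0)
    for (child in model$kids[[v]])
      acc <- c(acc, .coalesce(st, pops[[child]], cur[child], a))
    pops[[v]] <- acc
    cur[v] <- a
  }
  # root population: coalesce everything
  pop <- .coalesce(st, pops[[model$root]], cur[model$root], Inf)
  stopifnot(length(pop) == 1L)
  st
}

# convert a simulation state to a `phylo` (ape numbering: tips 1..m,
# internals m+1..2m-1 with root = m+1; edges emitted in preorder)
.state_to_phylo <- function(st, tips) {
  m <- length(tips)
  nmax <- 2L * m - 1L
  new_id <- integer(nmax)
  new_id[1:m] <- 1:m
  # internal nodes were created in increasing age order; the root is the
  # last one -> reverse the order so the root maps to m+1
  new_id[(m + 1L):nmax] <- (3L * m) - ((m + 1L):nmax)
  edge <- matrix(0L, nmax - 1L, 2L)
  elen <- numeric(nmax - 1L)
  r <- 0L
  stack <- nmax  # old id of the root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (child in c(st$kid1[v], st$kid2[v])) {
      r <- r + 1L
      edge[r, 1L] <- new_id[v]
      edge[r, 2L] <- new_id[child]
      elen[r] <- st$age[v] - st$age[child]
      if (child > m) stack <- c(stack, child)
    }
  }
  structure(list(edge = edge, edge.length = elen, tip.label = tips,
                 Nnode = m - 1L), class = "phylo", order = "cladewise")
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' @param model a [species_tree()] or [species_network()].
#' @return a rooted binary `phylo` with branch lengths in coalescent
#'   units. Coalescence times never precede the corresponding species
#'   divergence times.
#' @seealso [simulate_gene_trees()] for many genes,
#'   [expected_quartet_frequencies()] for the closed-form check.
#' @export
simulate_gene_tree <- function(model) {
  stopifnot(inherits(model, "species_tree"))
  .state_to_phylo(.sim_msc_once(model), model$tips)
}

#' Simulate many independent gene trees
#'
#' @param model a [species_tree()] or [species_network()].
#' @param n number of gene trees.
#' @param seed optional integer seed (uses the global RNG stream when
#'   `NULL`); identical seeds reproduce runs bit-for-bit.
#' @return a named list of `phylo` objects (`g00001`, ...).
#' @export
simulate_gene_trees <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "species_tree"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- .state_to_phylo(.sim_msc_once(model),
                                                    model$tips)
  names(out) <- sprintf("g%05d", seq_len(n))
  out
}

#' Closed-form rooted quartet topology frequencies under pure ILS
#'
#' For an internal branch of `T` coalescent units the matching topology
#' has probability `1 - (2/3) exp(-T)` and each mismatch topology
#' `(1/3) exp(-T)`.
#'
#' @param T internal branch length in coalescent units (>= 0).
#' @return named numeric vector `(match, mismatch_1, mismatch_2)` summing
#'   to 1.
#' @export
expected_quartet_frequencies <- function(T) {
  stopifnot(is.numeric(T), length(T) == 1L)
  if (is.na(T) || T < 0) stop("T must be non-negative")
  e <- exp(-T)
  c(match = 1 - 2 * e / 3, mismatch_1 = e / 3, mismatch_2 = e / 3)
}

#' Expected quartet frequencies under a one-reticulation mixture
#'
#' Two-component multispecies-coalescent mixture: with probability
#' `1 - gamma` the gene follows the major species tree (internal branch
#' `T`); with probability `gamma` it follows the minor parental tree
#' (internal branch `T_prime`), whose matching topology is the major
#' tree's `mismatch_major` class.
#'
#' @param T,T_prime internal branch lengths (coalescent units) of the
#'   major and minor parental trees.
#' @param gamma inheritance probability in `[0, 1]`.
#' @return named numeric vector `(match, mismatch_major, mismatch_minor)`
#'   summing to 1.
#' @export
expected_network_frequencies <- function(T, T_prime, gamma) {
  stopifnot(is.numeric(T), is.numeric(T_prime), is.numeric(gamma))
  if (T < 0 || T_prime < 0) stop("branch lengths must be non-negative")
  if (gamma < 0 || gamma > 1) stop("gamma must be in [0, 1]")
  e <- exp(-T); ep <- exp(-T_prime)
  c(match          = (1 - gamma) * (1 - 2 * e / 3) + gamma * ep / 3,
    mismatch_major = (1 - gamma) * e / 3 + gamma * (1 - 2 * ep / 3),
    mismatch_minor = (1 - gamma) * e / 3 + gamma * ep / 3)
}
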