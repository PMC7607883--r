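# --- moment inversion of quartet topology frequencies ---------------------

#' Internal branch length implied by the matching-topology frequency
#'
#' Inverts the pure-ILS closed form `f_match = 1 - (2/3) exp(-T)`:
#' `T = -log((3/2) (1 - f_match))`.
#'
#' @param f_match matching-topology frequency, in `[1/3, 1]`.
#' @return the branch length in coalescent units; `Inf` (with a warning)
#'   when `f_match = 1`.
#' @export
estimate_ils_branch <- function(f_match) {
  stopifnot(is.numeric(f_match), length(f_match) == 1L)
  if (is.na(f_match) || f_match < 1 / 3)
    stop("anomalous frequency: f_match below 1/3 is inconsistent with ",
         "the coalescent on a tree")
  if (f_match >= 1) {
    if (f_match > 1) stop("f_match cannot exceed 1")
    warning("f_match = 1 implies an infinite internal branch")
    return(Inf)
  }
  -log(1.5 * (1 - f_match))
}

#' Moment estimate of the inheritance probability from quartet frequencies
#'
#' Inverts the one-reticulation mixture of
#' [expected_network_frequencies()] under the identifying restriction
#' `T_prime = T`: `exp(-T) = 3 f_minor` and
#' `gamma = (f_major - f_minor) / (1 - exp(-T))`. Equal mismatch
#' frequencies return the pure-ILS model with `gamma = 0`.
#'
#' @param f_match,f_mis_major,f_mis_minor the three quartet topology
#'   frequencies (must sum to 1 within 1e-9;
#'   `f_mis_major >= f_mis_minor` by labeling convention).
#' @return a list with `T_hat`, `gamma_hat` and `model` (`"pure_ils"` or
#'   `"one_reticulation"`).
#' @seealso [fit_quartet_mix()] for the full fitted-model interface.
#' @export
estimate_gamma <- function(f_match, f_mis_major, f_mis_minor) {
  f <- c(f_match, f_mis_major, f_mis_minor)
  stopifnot(is.numeric(f), length(f) == 3L, all(!is.na(f)))
  if (any(f < 0)) stop("frequencies must be non-negative")
  if (abs(sum(f) - 1) > 1e-9) stop("frequencies must sum to 1")
  if (f_mis_major < f_mis_minor)
    stop("labeling convention requires f_mis_major >= f_mis_minor")
  if (f_mis_minor > 1 / 3)
    stop("anomalous frequency: minor mismatch above 1/3 is inconsistent ",
         "with the mixture model")
  if (f_mis_minor <= 0)
    stop("minor mismatch frequency must be strictly positive")
  e <- 3 * f_mis_minor
  T_hat <- -log(e)
  if (f_mis_major == f_mis_minor)
    return(list(T_hat = T_hat, gamma_hat = 0, model = "pure_ils"))
  if (1 - e <= 0)
    stop("inconsistent with model: T = 0 cannot produce unequal ",
         "mismatch frequencies")
  list(T_hat = T_hat, gamma_hat = (f_mis_major - f_mis_minor) / (1 - e),
       model = "one_reticulation")
}

#' Plurality species-tree estimate from a quartet census
#'
#' Returns the plurality topology class as the species-tree estimate for
#' the four-taxon problem, with a Wald interval on its frequency and the
#' exact binomial [symmetry_test()] on the two non-plurality classes.
#'
#' @param x a `topology_census` from the quartet classifier, or a named
#'   count vector over `match`, `mismatch_PD`, `mismatch_RD`.
#' @param conf confidence level for the Wald interval; default 0.95.
#' @return a list with `class` (plurality class, or `NA` on a tie),
#'   `tie`, `frequency`, `wald_ci`, `symmetry_p`.
#' @export
plurality_species_tree <- function(x, conf = 0.95) {
  counts <- if (inherits(x, "topology_census")) x$counts else x
  stopifnot(length(counts) == 3L, !is.null(names(counts)))
  n <- sum(counts)
  if (n < 1) stop("empty census")
  top <- which(counts == max(counts))
  tie <- length(top) > 1L
  others <- sort(counts[-top[1]], decreasing = TRUE)
  p_sym <- symmetry_test(others[1], others[2])$p.value
  f <- counts[top[1]] / n
  z <- qnorm(1 - (1 - conf) / 2)
  half <- z * sqrt(f * (1 - f) / n)
  list(class = if (tie) NA_character_ else names(counts)[top[1]],
       tie = tie, frequency = unname(f),
       wald_ci = c(lower = max(0, f - half), upper = min(1, f + half)),
       symmetry_p = p_sym)
}

#' Fit the one-reticulation quartet mixture to topology counts
#'
#' The central fitting function of the package. Given counts of the three
#' rooted quartet topology classes, it identifies the major mismatch class
#' from the data, inverts the mixture model by the method of moments
#' ([estimate_gamma()], restriction `T_prime = T`), attaches nonparametric
#' bootstrap standard errors (multinomial resampling of the gene-level
#' class labels) and the exact mismatch [symmetry_test()].
#'
#' @param counts named non-negative counts over `match`, `mismatch_PD`,
#'   `mismatch_RD` (a quartet-classifier `topology_census` is accepted).
#' @param nboot bootstrap replicates for standard errors; 0 skips the
#'   bootstrap. Default 200.
#' @param conf confidence level for bootstrap percentile intervals.
#' @param boot_seed optional seed for the bootstrap resampling.
#' @return an object of class `quartet_mix` with components `counts`,
#'   `n`, `frequencies`, `major_class`, `minor_class`, `T_hat`,
#'   `gamma_hat`, `model`, `symmetry`, `boot` (replicate matrix), `se`,
#'   `ci`. Methods: [print()], [summary()], [coef()], [predict()],
#'   [simulate()], [plot()], [confint()].
#' @examples
#' fit <- fit_quartet_mix(c(match = 490, mismatch_PD = 360,
#'                          mismatch_RD = 150), nboot = 50, boot_seed = 1)
#' coef(fit)
#' predict(fit)
#' @export
fit_quartet_mix <- function(counts, nboot = 200, conf = 0.95,
                            boot_seed = NULL) {
  if (inherits(counts, "topology_census")) {
    if (counts$classifier != "quartet")
      stop("need a quartet-classifier census")
    counts <- counts$counts
  }
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  counts <- counts[.quartet_classes]
  if (anyNA(counts)) stop("counts must be named match, mismatch_PD, ",
                          "mismatch_RD")
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n < 1) stop("no gene trees counted")
  freqs <- counts / n
  mism <- counts[c("mismatch_PD", "mismatch_RD")]
  major <- names(mism)[which.max(mism)]
  minor <- setdiff(names(mism), major)
  est <- estimate_gamma(freqs[["match"]], freqs[[major]], freqs[[minor]])
  sym <- symmetry_test(counts[[major]], counts[[minor]])
  boot <- NULL; se <- c(T_hat = NA_real_, gamma_hat = NA_real_); ci <- NULL
  if (nboot > 0) {
    if (!is.null(boot_seed)) set.seed(boot_seed)
    draws <- rmultinom(nboot, n, freqs)
    rownames(draws) <- names(freqs)
    reps <- apply(draws, 2L, function(ct) {
      f <- ct / n
      hi <- max(f[[major]], f[[minor]]); lo <- min(f[[major]], f[[minor]])
      out <- try(estimate_gamma(f[["match"]], hi, lo), silent = TRUE)
      if (inherits(out, "try-error")) c(NA_real_, NA_real_)
      else c(out$T_hat, out$gamma_hat)
    })
    boot <- t(reps)
    colnames(boot) <- c("T_hat", "gamma_hat")
    se <- apply(boot, 2L, sd, na.rm = TRUE)
    a <- (1 - conf) / 2
    ci <- apply(boot, 2L, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  }
  structure(list(counts = counts, n = n, frequencies = freqs,
                 major_class = major, minor_class = minor,
                 T_hat = est$T_hat, gamma_hat = est$gamma_hat,
                 model = est$model, symmetry = sym,
                 boot = boot, se = se, ci = ci, conf = conf,
                 call = match.call()),
            class = "quartet_mix")
}

#' @export
print.quartet_mix <- function(x, digits = 4, ...) {
  cat("Quartet MSC mixture (moment fit, T' = T)\n")
  cat(sprintf("  n = %d gene trees: match %.1f%%, %s %.1f%% (major), %s %.1f%% (minor)\n",
              x$n, 100 * x$frequencies[["match"]],
              x$major_class, 100 * x$frequencies[[x$major_class]],
              x$minor_class, 100 * x$frequencies[[x$minor_class]]))
  cat(sprintf("  T (coalescent units) = %.*g   gamma = %.*g   [%s]\n",
              digits, x$T_hat, digits, x$gamma_hat, x$model))
  invisible(x)
}

#' @export
coef.quartet_mix <- function(object, ...) {
  c(T_hat = object$T_hat, gamma_hat = object$gamma_hat)
}

#' @export
confint.quartet_mix <- function(object, parm = c("T_hat", "gamma_hat"),
                                level = NULL, ...) {
  if (is.null(object$ci))
    stop("no bootstrap was run; refit with nboot > 0")
  if (!is.null(level) && level != object$conf)
    stop("intervals were computed at level ", object$conf,
         "; refit with conf = ", level)
  t(object$ci[, parm, drop = FALSE])
}

#' Expected class frequencies (or counts) under the fitted mixture
#'
#' @param object a `quartet_mix` fit.
#' @param type `"frequencies"` (default) or `"counts"` (scaled by the
#'   fitted sample size).
#' @param ... unused.
#' @return named vector over `match`, `mismatch_PD`, `mismatch_RD`. By
#'   moment construction these reproduce the observed frequencies when the
#'   fit succeeded.
#' @export
predict.quartet_mix <- function(object, type = c("frequencies", "counts"),
                                ...) {
  type <- match.arg(type)
  ef <- expected_network_frequencies(object$T_hat, object$T_hat,
                                     object$gamma_hat)
  out <- c(ef[["match"]],
           setNames(ef[["mismatch_major"]], object$major_class),
           setNames(ef[["mismatch_minor"]], object$minor_class))
  names(out)[1] <- "match"
  out <- out[.quartet_classes]
  if (type == "counts") out <- out * object$n
  out
}

#' Simulate topology counts from the fitted mixture
#'
#' Draws gene trees from the fitted one-reticulation network with the
#' multispecies-coalescent simulator (not from the closed form) and
#' censuses them, so simulation exercises the full generative route.
#'
#' @param object a `quartet_mix` fit.
#' @param nsim number of replicate censuses.
#' @param seed optional seed.
#' @param n gene trees per replicate; defaults to the fitted sample size.
#' @param ... unused.
#' @return a data frame with columns `match`, `mismatch_PD`,
#'   `mismatch_RD`, one row per replicate.
#' @export
simulate.quartet_mix <- function(object, nsim = 1, seed = NULL,
                                 n = object$n, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(object$T_hat))
    stop("cannot simulate from an infinite-T fit")
  groups <- drosophilid_groups()
  model <- quartet_network(T = object$T_hat, gamma = object$gamma_hat)
  # the fitted major class may be mismatch_RD; swap representatives so the
  # simulated major mismatch maps onto it
  if (object$major_class == "mismatch_RD")
    model <- quartet_network(T = object$T_hat, gamma = object$gamma_hat,
                             taxa = c(pair = "Rb", other = "Pv",
                                      dros = "Dm", out = "Eh"))
  out <- matrix(0L, nsim, 3L,
                dimnames = list(NULL, .quartet_classes))
  for (i in seq_len(nsim)) {
    trees <- simulate_gene_trees(model, n)
    cs <- census(trees, groups, classifier = "quartet")
    out[i, ] <- cs$counts[.quartet_classes]
  }
  as.data.frame(out)
}

#' @export
summary.quartet_mix <- function(object, ...) {
  structure(list(fit = object), class = "summary.quartet_mix")
}

#' @export
print.summary.quartet_mix <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  est <- coef(f)
  tab <- data.frame(estimate = est, boot_se = f$se[names(est)])
  if (!is.null(f$ci)) {
    tab$ci_lower <- f$ci[1, names(est)]
    tab$ci_upper <- f$ci[2, names(est)]
  }
  print(signif(tab, digits))
  cat(sprintf("Mismatch symmetry (exact binomial, H0 p = 1/2): p = %.3g\n",
              f$symmetry$p.value))
  if (f$symmetry$p.value < 0.05)
    cat("  mismatch classes are asymmetric: ILS alone is an unlikely",
        "explanation\n")
  invisible(x)
}

#' Barplot of observed versus fitted quartet class frequencies
#'
#' @param x a `quartet_mix` fit.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.quartet_mix <- function(x, ...) {
  obs <- x$frequencies[.quartet_classes]
  fit <- predict(x)
  graphics::barplot(rbind(observed = obs, fitted = fit), beside = TRUE,
                    legend.text = TRUE, ylab = "frequency",
                    main = "Quartet topology classes", ...)
  invisible(x)
}
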