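# --- pipeline orchestration ----------------------------------------------

.cfg_get <- function(config, field, default = NULL, required = FALSE) {
  if (!is.null(config[[field]])) return(config[[field]])
  if (required) stop("invalid config: missing field '", field, "'")
  default
}

.cfg_groups <- function(config) {
  g <- .cfg_get(config, "groups", required = TRUE)
  if (identical(g, "drosophilid")) return(drosophilid_groups())
  taxon_groups(steganinae = unlist(g$steganinae),
               drosophilinae = unlist(g$drosophilinae),
               outgroup = unlist(g$outgroup),
               steg_pair = unlist(.cfg_get(g, "steg_pair",
                                           unlist(g$steganinae)[1:2])),
               quartet = unlist(g$quartet))
}

.cfg_model <- function(config) {
  kind <- .cfg_get(config, "model", "species_tree")
  if (identical(kind, "drosophilid_network"))
    return(drosophilid_network(gamma = .cfg_get(config, "gamma", 0.390)))
  if (identical(kind, "drosophilid_species_tree"))
    return(drosophilid_species_tree())
  if (identical(kind, "quartet_network"))
    return(quartet_network(T = .cfg_get(config, "T", 0.734),
                           T_prime = .cfg_get(config, "T_prime",
                                              .cfg_get(config, "T", 0.734)),
                           gamma = .cfg_get(config, "gamma", 0.390)))
  nwk <- .cfg_get(config, "species_newick", required = TRUE)
  st <- species_tree(nwk)
  ret <- config$reticulation
  if (is.null(ret)) return(st)
  species_network(st, recipient = unlist(ret$recipient),
                  donor = unlist(ret$donor),
                  gamma = .cfg_get(ret, "gamma", required = TRUE),
                  t_hybrid = .cfg_get(ret, "t_hybrid", required = TRUE))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[order(names(config))]), collapse = ""),
             tmp)
  unname(tools::md5sum(tmp))
}

#' Run a pipeline stage
#'
#' Orchestrates the package's stages as subcommands with a YAML (or list)
#' config, deterministic seeding and a JSON run manifest. All tabular
#' artifacts are TSV with a header row. Rerunning with the same config
#' and seed reproduces the artifacts byte-identically.
#'
#' Subcommands and their main config fields:
#' \describe{
#'   \item{simulate}{`model` (`"drosophilid_network"`,
#'     `"drosophilid_species_tree"`, `"quartet_network"` or a
#'     `species_newick` string plus optional `reticulation`), `n_genes`,
#'     optional `seq_length`, `subst_rate` -> `gene_trees.nwk`,
#'     `seqs/<gene>.fasta`.}
#'   \item{inject}{`seq_dir`, `frame_shift_fraction`, `paralog_fraction`
#'     -> `corrupted/<gene>.fasta`, `artifact_ledger.tsv`.}
#'   \item{clean}{`busco_tables` and `fasta` (named maps taxon -> path),
#'     `cv_threshold` -> `genes/<gene>.fasta`, `ortholog_qc.tsv`.}
#'   \item{qc}{`trees`, `outgroup`, `quantile`, `long_branch_factor` ->
#'     `tree_qc.tsv`, `filtered_trees.nwk`.}
#'   \item{census / quartet}{`trees`, `groups` (`"drosophilid"` or an
#'     explicit mapping) -> `census.tsv`, `gene_classes.tsv`.}
#'   \item{muller}{`gene_classes`, `muller_map` (TSV paths) ->
#'     `muller_contingency.tsv`, `muller_test.txt`.}
#'   \item{estimate}{`counts` (named list) or `census` (TSV path) ->
#'     `estimate.tsv`, `estimate_report.txt`.}
#' }
#'
#' @param subcommand one of `"clean"`, `"qc"`, `"census"`, `"quartet"`,
#'   `"muller"`, `"estimate"`, `"simulate"`, `"inject"`.
#' @param config path to a YAML file or a named list.
#' @param out_dir output directory (created if needed); overrides
#'   `config$out_dir`.
#' @param seed integer seed for stochastic stages; overrides
#'   `config$seed`.
#' @return invisibly, the list of artifact paths written (including the
#'   manifest).
#' @export
run_pipeline <- function(subcommand, config, out_dir = NULL, seed = NULL) {
  subcommand <- match.arg(subcommand,
                          c("clean", "qc", "census", "quartet", "muller",
                            "estimate", "simulate", "inject"))
  if (is.character(config)) {
    if (!file.exists(config)) stop("invalid config: file not found: ",
                                   config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("invalid config: expected a list or YAML path")
  if (is.null(out_dir)) out_dir <- .cfg_get(config, "out_dir",
                                            required = TRUE)
  if (is.null(seed)) seed <- .cfg_get(config, "seed", NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  outputs <- character(0)
  emit <- function(path) { outputs <<- c(outputs, path); path }
  run <- function() {
    switch(subcommand,
      simulate = {
        model <- .cfg_model(config)
        n <- .cfg_get(config, "n_genes", required = TRUE)
        trees <- simulate_gene_trees(model, n)
        emit(write_gene_trees(trees, file.path(out_dir, "gene_trees.nwk")))
        sl <- .cfg_get(config, "seq_length")
        if (!is.null(sl)) {
          rate <- .cfg_get(config, "subst_rate", 1)
          dir.create(file.path(out_dir, "seqs"), showWarnings = FALSE)
          for (g in names(trees)) {
            sv <- evolve_jc69(trees[[g]], sl, rate)
            emit(write_fasta(
              data.frame(gene_id = g, taxon = names(sv), sequence = sv),
              file.path(out_dir, "seqs", paste0(g, ".fasta"))))
          }
        }
      },
      inject = {
        dir <- .cfg_get(config, "seq_dir", required = TRUE)
        files <- sort(list.files(dir, pattern = "\\.fasta$",
                                 full.names = TRUE))
        if (!length(files)) stop("invalid config: seq_dir has no .fasta")
        seqs <- lapply(files, function(f) {
          df <- read_fasta(f)
          setNames(df$sequence, df$taxon)
        })
        names(seqs) <- sub("\\.fasta$", "", basename(files))
        res <- inject_artifacts(
          seqs,
          .cfg_get(config, "frame_shift_fraction", required = TRUE),
          .cfg_get(config, "paralog_fraction", required = TRUE))
        dir.create(file.path(out_dir, "corrupted"), showWarnings = FALSE)
        for (g in names(res$sequences))
          emit(write_fasta(
            data.frame(gene_id = g, taxon = names(res$sequences[[g]]),
                       sequence = res$sequences[[g]]),
            file.path(out_dir, "corrupted", paste0(g, ".fasta"))))
        emit(.write_tsv(res$ledger,
                        file.path(out_dir, "artifact_ledger.tsv")))
      },
      clean = {
        bt_paths <- .cfg_get(config, "busco_tables", required = TRUE)
        fa_paths <- .cfg_get(config, "fasta", required = TRUE)
        tables <- lapply(names(bt_paths), function(tx)
          read_busco_table(bt_paths[[tx]], tx))
        names(tables) <- names(bt_paths)
        fastas <- lapply(fa_paths, read_fasta)
        tab <- collect_complete_orthologs(tables, fastas)
        tab <- fix_table_frames(tab)
        tab <- cv_filter(tab,
                         cv_threshold = .cfg_get(config, "cv_threshold",
                                                 0.10))
        dir.create(file.path(out_dir, "genes"), showWarnings = FALSE)
        for (g in tab$genes)
          emit(write_fasta(
            data.frame(gene_id = g, taxon = names(tab$seq[[g]]),
                       sequence = tab$seq[[g]]),
            file.path(out_dir, "genes", paste0(g, ".fasta"))))
        emit(write_ortholog_qc(tab,
                               file.path(out_dir, "ortholog_qc.tsv")))
      },
      qc = {
        trees <- read_gene_trees(.cfg_get(config, "trees",
                                          required = TRUE))
        if (inherits(trees, "phylo")) trees <- list(trees)
        rec <- qc_gene_trees(
          trees, outgroup = unlist(.cfg_get(config, "outgroup",
                                            required = TRUE)),
          long_branch_factor = .cfg_get(config, "long_branch_factor", 10))
        rec <- filter_outliers(rec,
                               quantile = .cfg_get(config, "quantile",
                                                   0.95))
        emit(.write_tsv(rec, file.path(out_dir, "tree_qc.tsv")))
        emit(write_gene_trees(trees[!rec$removed],
                              file.path(out_dir, "filtered_trees.nwk")))
      },
      census = ,
      quartet = {
        groups <- .cfg_groups(config)
        trees <- read_gene_trees(.cfg_get(config, "trees",
                                          required = TRUE))
        if (inherits(trees, "phylo")) trees <- list(trees)
        cs <- census(trees, groups,
                     classifier = if (subcommand == "quartet") "quartet"
                                  else "full")
        emit(.write_tsv(
          data.frame(class = names(cs$counts), count = cs$counts,
                     frequency = round(cs$frequencies, 4)),
          file.path(out_dir, "census.tsv")))
        emit(.write_tsv(cs$genes,
                        file.path(out_dir, "gene_classes.tsv")))
      },
      muller = {
        classes <- read.delim(.cfg_get(config, "gene_classes",
                                       required = TRUE),
                              stringsAsFactors = FALSE)
        mmap <- read.delim(.cfg_get(config, "muller_map",
                                    required = TRUE),
                           stringsAsFactors = FALSE)
        res <- stratify_by_muller(classes, mmap)
        tab <- as.data.frame.matrix(res$table)
        tab <- cbind(topology = rownames(tab), tab)
        emit(.write_tsv(tab,
                        file.path(out_dir, "muller_contingency.tsv")))
        rep_path <- file.path(out_dir, "muller_test.txt")
        writeLines(c(
          sprintf("chi-square homogeneity: statistic = %.4f",
                  unname(res$test$statistic)),
          sprintf("p-value = %.6g%s", res$test$p.value,
                  if (res$monte_carlo) " (Monte Carlo)" else ""),
          sprintf("genes without a Muller mapping: %d", res$n_unmapped)),
          rep_path)
        emit(rep_path)
      },
      estimate = {
        counts <- .cfg_get(config, "counts")
        if (is.null(counts)) {
          cens <- read.delim(.cfg_get(config, "census", required = TRUE),
                             stringsAsFactors = FALSE)
          counts <- setNames(cens$count, cens$class)
        }
        fit <- fit_quartet_mix(unlist(counts),
                               nboot = .cfg_get(config, "nboot", 200),
                               boot_seed = seed)
        emit(.write_tsv(
          data.frame(parameter = c("T_hat", "gamma_hat"),
                     estimate = unname(coef(fit)),
                     boot_se = unname(fit$se),
                     ci_lower = if (is.null(fit$ci)) NA else fit$ci[1, ],
                     ci_upper = if (is.null(fit$ci)) NA else fit$ci[2, ]),
          file.path(out_dir, "estimate.tsv")))
        rep_path <- file.path(out_dir, "estimate_report.txt")
        con <- textConnection("rep_lines", "w", local = TRUE)
        sink(con); print(summary(fit)); sink()
        close(con)
        writeLines(rep_lines, rep_path)
        emit(rep_path)
      })
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs))
  run()
  manifest <- list(subcommand = subcommand,
                   config_hash = .config_hash(config),
                   seed = if (is.null(seed)) NA else seed,
                   package_version =
                     as.character(packageVersion("coalcensus")),
                   outputs = sort(basename(outputs)))
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  outputs <- c(outputs, mpath)
  ok <- TRUE
  invisible(outputs)
}
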