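## Synthetic-world generation and end-to-end orchestration: configuration,
## stage running, covariate merging and the reproducibility manifest.

#' Simulation / pipeline configuration
#'
#' Bundles every tunable of the synthetic world and the analysis stages.
#' Defaults emulate the study design the package targets: two rodent-like
#' clades of 15 taxa, ten tissues, a control category plus immune categories
#' with genuine category effects on the rate of positive selection partly
#' mediated by selective constraint (pN/pS).
#'
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @param n_taxa_per_clade Taxa per clade for simulated gene trees.
#' @param tree_depth Root-to-tip expected substitutions per codon.
#' @param n_genes_per_category Named integer vector: genes per category.
#' @param fraction_positive Named vector: marginal probability that a gene
#'   of the category carries a positive-selection class.
#' @param pnps_targets Named vector: category geometric-mean pN/pS.
#' @param tau_targets Named vector: category mean tissue-specificity tau.
#' @param pnps_log_sd Gene-level SD of log pN/pS within category.
#' @param constraint_slope Logit-scale slope linking a gene's log pN/pS to
#'   its probability of positive selection (the "indirect" path).
#' @param n_tissues Number of tissues in the expression data.
#' @param n_diploid_samples Diploid samples per species (two species).
#' @param n_codons Codons per simulated gene (CDS length / 3).
#' @param theta Expected synonymous SNPs per synonymous site.
#' @param dispersion Negative-binomial dispersion of expression counts.
#' @param selection_mode `"truth"` (fast: the generator's true
#'   positive-selection status is used as the per-gene flag) or
#'   `"codon_fit"` (full: alignments are simulated and the gene-wide
#'   likelihood-ratio tests are run; only sensible for small worlds).
#' @param fdr_q FDR threshold for positive flags in `codon_fit` mode.
#' @param omega_positive dN/dS of the positive-selection class in simulated
#'   alignments.
#' @param weight_positive Mixture weight of the positive-selection class.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(
    seed = 1,
    n_taxa_per_clade = 15,
    tree_depth = 0.5,
    n_genes_per_category = c(control = 150, cytokines = 150,
                             cell_surface = 150, signaling = 150),
    fraction_positive = c(control = 0.05, cytokines = 0.30,
                          cell_surface = 0.20, signaling = 0.05),
    pnps_targets = c(control = 0.15, cytokines = 0.30,
                     cell_surface = 0.25, signaling = 0.10),
    tau_targets = c(control = 0.40, cytokines = 0.70,
                    cell_surface = 0.60, signaling = 0.35),
    pnps_log_sd = 0.4,
    constraint_slope = 1.2,
    n_tissues = 10,
    n_diploid_samples = c(8, 31),
    n_codons = 500,
    theta = 0.04,
    dispersion = 0.1,
    selection_mode = c("truth", "codon_fit"),
    fdr_q = 0.2,
    omega_positive = 5,
    weight_positive = 0.1) {
  selection_mode <- match.arg(selection_mode)
  cats <- names(n_genes_per_category)
  stopifnot(!is.null(cats),
            setequal(cats, names(fraction_positive)),
            setequal(cats, names(pnps_targets)),
            setequal(cats, names(tau_targets)),
            all(n_genes_per_category >= 1),
            all(fraction_positive >= 0 & fraction_positive <= 1),
            all(tau_targets >= 0 & tau_targets <= 1),
            n_tissues >= 2, tree_depth > 0, theta > 0)
  rm(cats)
  structure(as.list(environment()), class = "simulation_config")
}

## deterministic per-stage seed derivation (kept below 2^31)
derive_seed <- function(seed, stage) {
  (seed * 7919 + sum(utf8ToInt(stage)) * 131) %% 2147483629 + 1
}

## random CDS without stop codons
random_cds <- function(n_codons, seed) {
  withr::with_seed(seed, paste(
    sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = ""))
}

#' Simulate a synthetic study ("world")
#'
#' Generates the full gene-level truth and the observable data the pipeline
#' consumes: per-gene category, true pN/pS (log-normal around the category
#' target), true positive-selection status (logistic in log pN/pS plus a
#' direct category effect), per-species variant tables on simulated CDSs,
#' an expression count matrix with category tau targets, and auxiliary
#' covariates (PPI counts, sequence lengths).
#'
#' The marginal positive fraction of a category equals
#' `fraction_positive[cat]` up to Jensen error; its decomposition into a
#' direct category effect and a constraint-mediated part is controlled by
#' `constraint_slope`.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_world` list: `genes` (truth table), `variants`
#'   (per-species list of per-gene variant tables), `cds` (per-gene CDS),
#'   `expression` (see [simulate_expression()]), `config`.
#' @export
simulate_world <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cats <- names(config$n_genes_per_category)
  n <- sum(config$n_genes_per_category)
  category <- rep(cats, config$n_genes_per_category)
  gene_id <- sprintf("gene_%05d", seq_len(n))

  world_seed <- derive_seed(config$seed, "world")
  genes <- withr::with_seed(world_seed, {
    log_target <- log(config$pnps_targets[category])
    true_log_pnps <- stats::rnorm(n, log_target, config$pnps_log_sd)
    ## alpha chosen so the marginal positive fraction matches the category
    ## target while the constraint-mediated path runs through log pN/pS
    ctrl <- cats[1]
    alpha <- stats::qlogis(config$fraction_positive[category]) -
      config$constraint_slope * (log_target - log(config$pnps_targets[[ctrl]]))
    lp <- alpha + config$constraint_slope *
      (true_log_pnps - log(config$pnps_targets[[ctrl]]))
    true_positive <- stats::runif(n) < stats::plogis(lp)
    ## generator-level dN/dS: constrained genes evolve slower; positive
    ## selection adds a bump
    dnds_true <- exp(stats::rnorm(n, log(0.15) +
                                    0.8 * (true_log_pnps - mean(true_log_pnps)),
                                  0.3)) + ifelse(true_positive, 0.15, 0)
    tau_t <- pmin(1, pmax(0, stats::rnorm(n, config$tau_targets[category], 0.12)))
    data.frame(gene_id = gene_id, category = category,
               true_pnps = exp(true_log_pnps), true_positive = true_positive,
               true_tau = tau_t, dnds = dnds_true,
               ppi_count = stats::rpois(n, 25) + 1,
               stringsAsFactors = FALSE)
  })

  cds <- lapply(seq_len(n), function(i)
    random_cds(config$n_codons, derive_seed(world_seed + i, "cds")))
  names(cds) <- gene_id

  variants <- lapply(seq_along(config$n_diploid_samples), function(sp) {
    vs <- lapply(seq_len(n), function(i) {
      simulate_variants(cds[[i]], target_pnps = genes$true_pnps[i],
                        n_diploids = config$n_diploid_samples[sp],
                        theta = config$theta,
                        seed = derive_seed(world_seed + i, paste0("var", sp)))
    })
    names(vs) <- gene_id
    vs
  })
  names(variants) <- paste0("species", seq_along(config$n_diploid_samples))

  expr <- simulate_expression(
    n_genes = n, n_tissues = config$n_tissues, tau_target = genes$true_tau,
    library_sizes = rep(2e6, 2 * config$n_tissues),
    seed = derive_seed(world_seed, "expr"), dispersion = config$dispersion)
  rownames(expr$counts) <- gene_id
  names(expr$true_tau) <- gene_id
  expr$effective_length <- stats::setNames(
    rep(3 * config$n_codons, n), gene_id)

  structure(list(genes = genes, cds = cds, variants = variants,
                 expression = expr, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic world:", nrow(x$genes), "genes,",
      length(unique(x$genes$category)), "categories\n")
  invisible(x)
}

#' Merge per-gene results into the covariate table
#'
#' Joins selection-test results, pN/pS, expression covariates, PPI counts,
#' sequence lengths and category labels on `gene_id`; logs attrition counts
#' per input.
#'
#' @param test_results `data.frame` with `gene_id`, `positive` (0/1) and
#'   optionally `dnds`.
#' @param pnps Named numeric vector (gene -> mean pN/pS) or `data.frame`
#'   with `gene_id`, `pnps`.
#' @param expression `data.frame` with `gene_id`, `mean_expression`, `tau`.
#' @param categories `data.frame` with `gene_id`, `category`.
#' @param ppi_table Optional `data.frame` with `gene_id`, `ppi_count`.
#' @param lengths Optional named vector or `data.frame` (`gene_id`,
#'   `seq_length`).
#' @return `data.frame` keyed by `gene_id` with attribute `attrition`.
#' @export
merge_covariates <- function(test_results, pnps, expression, categories,
                             ppi_table = NULL, lengths = NULL) {
  as_df <- function(x, value_name) {
    if (is.data.frame(x)) return(x)
    data.frame(gene_id = names(x), v = as.numeric(x),
               stringsAsFactors = FALSE) |>
      stats::setNames(c("gene_id", value_name))
  }
  pnps <- as_df(pnps, "pnps")
  if (!is.null(lengths)) lengths <- as_df(lengths, "seq_length")
  inputs <- list(tests = test_results, pnps = pnps, expression = expression,
                 categories = categories)
  if (!is.null(ppi_table)) inputs$ppi <- ppi_table
  if (!is.null(lengths)) inputs$lengths <- lengths
  for (nm in names(inputs)) {
    if (anyDuplicated(inputs[[nm]]$gene_id))
      stop("duplicate gene ids in ", nm)
  }
  out <- inputs[[1]]
  for (nm in names(inputs)[-1]) out <- merge(out, inputs[[nm]], by = "gene_id")
  if (nrow(out) == 0) warning("no shared gene ids across inputs")
  attr(out, "attrition") <- vapply(inputs, nrow, numeric(1)) - nrow(out)
  out
}

#' Run the pipeline end to end on a synthetic world
#'
#' Stages, in dependency order: world synthesis, selection testing (true
#' flags or full codon-model fits), per-species pN/pS through the filter
#' cascade, expression summarization, covariate merging and the category
#' statistics (binomial GLM with and without the pN/pS covariate, Dunnett
#' contrasts vs control, linear model for dN/dS, Kruskal-Wallis/Dunn on
#' pN/pS).
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV and a JSON manifest with checksums is produced.
#' @param stages Character vector of stages to run (dependencies of omitted
#'   stages are skipped with a warning downstream).
#' @return List: `covariates` (merged gene table), `stats` (model results),
#'   `world`, `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL,
                         stages = c("simulate", "selection", "pnps",
                                    "expression", "merge", "stats")) {
  world <- simulate_world(config)
  genes <- world$genes
  n <- nrow(genes)

  ## --- selection stage ---------------------------------------------------
  if ("selection" %in% stages) {
    if (config$selection_mode == "codon_fit") {
      tree <- simulate_tree(config$n_taxa_per_clade, config$tree_depth,
                            seed = derive_seed(config$seed, "tree"))
      rows <- lapply(seq_len(n), function(i) {
        mdl <- if (genes$true_positive[i])
          mixture_codon_model(omega = c(0.1, 0.8, config$omega_positive),
                              p_omega = c(0.65, 0.35 - config$weight_positive,
                                          config$weight_positive))
        else mixture_codon_model(omega = c(0.1, 0.8, 1.0),
                                 p_omega = c(0.65, 0.25, 0.10))
        sim <- simulate_codon_alignment(tree, mdl, config$n_codons,
                                        seed = derive_seed(config$seed + i, "aln"))
        gene_selection_tests(sim$alignment, tree, gene_id = genes$gene_id[i],
                             include_paml = FALSE,
                             seed = derive_seed(config$seed + i, "fit"))
      })
      sel <- do.call(rbind, rows)
      fdr <- bh_fdr(sel$model_averaged_p, config$fdr_q)
      tests <- data.frame(gene_id = sel$gene_id, positive = as.integer(fdr$flag),
                          dnds = sel$global_omega, q_value = fdr$q,
                          stringsAsFactors = FALSE)
    } else {
      tests <- data.frame(gene_id = genes$gene_id,
                          positive = as.integer(genes$true_positive),
                          dnds = genes$dnds, stringsAsFactors = FALSE)
    }
  } else {
    tests <- data.frame(gene_id = genes$gene_id,
                        positive = as.integer(genes$true_positive),
                        dnds = genes$dnds, stringsAsFactors = FALSE)
  }

  ## --- pN/pS stage -------------------------------------------------------
  pnps_by_species <- lapply(world$variants, function(vs) {
    vals <- vapply(names(vs), function(g) {
      gene_pnps(world$cds[[g]], vs[[g]], gene_id = g,
                maf_threshold = 0)$pnps
    }, numeric(1))
    vals
  })
  pnps_mean <- mean_ortholog_pnps(pnps_by_species[[1]], pnps_by_species[[2]])

  ## --- expression stage --------------------------------------------------
  if ("expression" %in% stages) {
    expr_summary <- expression_summary(world$expression$counts,
                                       world$expression$effective_length,
                                       world$expression$sample_tissue)
    expr_cov <- expr_summary[, c("gene_id", "mean_expression", "tau")]
  } else {
    warning("expression stage disabled: tau and mean expression dropped")
    expr_cov <- data.frame(gene_id = genes$gene_id,
                           mean_expression = NA_real_, tau = NA_real_,
                           stringsAsFactors = FALSE)
  }

  ## --- merge -------------------------------------------------------------
  covariates <- merge_covariates(
    tests, pnps_mean, expr_cov,
    categories = genes[, c("gene_id", "category")],
    ppi_table = genes[, c("gene_id", "ppi_count")],
    lengths = stats::setNames(nchar(unlist(world$cds)), genes$gene_id))
  covariates <- transform_covariates(covariates)
  ctrl <- names(config$n_genes_per_category)[1]
  covariates$category <- stats::relevel(factor(covariates$category), ref = ctrl)

  ## --- stats -------------------------------------------------------------
  stats_out <- NULL
  if ("stats" %in% stages) {
    m0 <- fit_binomial_glm(covariates, positive ~ category)
    m1 <- fit_binomial_glm(covariates, positive ~ category + pnps_z)
    stats_out <- list(
      glm_category = m0,
      glm_category_pnps = m1,
      dunnett_category = dunnett_vs_control(m0, ctrl,
                                            seed = derive_seed(config$seed, "dun0")),
      dunnett_category_pnps = dunnett_vs_control(m1, ctrl,
                                                 seed = derive_seed(config$seed, "dun1")),
      lm_dnds = fit_linear_model(covariates, sqrt_dnds ~ category),
      kruskal_pnps = kruskal_dunn(covariates$pnps, covariates$category, ctrl)
    )
  }

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "results"), recursive = TRUE,
               showWarnings = FALSE)
    paths <- c(
      covariates = file.path(out_dir, "results", "covariates.tsv"),
      selection = file.path(out_dir, "results", "selection.tsv"),
      config = file.path(out_dir, "config.yaml"))
    utils::write.table(covariates, paths[["covariates"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(tests, paths[["selection"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_config(config, paths[["config"]])
    manifest <- list(
      config_hash = unname(tools::md5sum(paths[["config"]])),
      seed = config$seed,
      checksums = as.list(tools::md5sum(unname(paths))),
      attrition = as.list(attr(covariates, "attrition")),
      n_genes = list(world = n, analyzed = nrow(covariates)))
    jsonlite::write_json(manifest,
                         file.path(out_dir, "results", "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }

  list(covariates = covariates, stats = stats_out, tests = tests,
       world = world, manifest = manifest)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return `path` / the restored `simulation_config`.
#' @export
write_config <- function(config, path) {
  x <- lapply(unclass(config), function(v) {
    if (!is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  listify <- function(v) if (is.list(v)) unlist(v) else v
  do.call(simulation_config, lapply(x, listify))
}
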