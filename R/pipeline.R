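#' Validate a pipeline configuration
#'
#' A configuration is a named list (usually read from a YAML file with
#' [read_pipeline_config()]) holding either an `inputs` block of file
#' paths (`expression`, `labels`, `strata`, `cc_genes` (a GMT with one
#' set), optionally `edges`, `cluster` (GMT), `ontology`, `annotations`,
#' `gene_sets`) or a `simulate` block of [simulation_config()] arguments
#' -- exactly one of the two -- plus analysis options.
#'
#' @param config Named list.
#' @return The validated config with defaults filled in.
#' @export
pipeline_config <- function(config) {
  has_inputs <- !is.null(config$inputs)
  has_sim <- !is.null(config$simulate)
  if (has_inputs == has_sim)
    stop("config must have exactly one of `inputs` and `simulate`")
  if (has_inputs) {
    for (field in c("expression", "labels", "strata")) {
      path <- config$inputs[[field]]
      if (is.null(path)) stop("inputs$", field, " is required")
      if (!file.exists(path))
        stop("inputs$", field, ": no such file: ", path)
    }
    for (field in c("cc_genes", "edges", "cluster", "ontology",
                    "annotations", "gene_sets")) {
      path <- config$inputs[[field]]
      if (!is.null(path) && !file.exists(path))
        stop("inputs$", field, ": no such file: ", path)
    }
  }
  defaults <- list(contrast = "contrast", reference = "reference",
                   uc_max = 2L, log_offset = 1,
                   confidence_threshold = 0.5, min_neighbors = 3L,
                   alpha = 0.05, seed = 1L, outdir = "cellrecap_out")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  pipeline_config(yaml::read_yaml(path))
}

# materialize the analysis inputs: either read from disk or simulate
load_pipeline_inputs <- function(config, with_network = FALSE) {
  if (!is.null(config$simulate)) {
    args <- config$simulate
    args$seed <- args$seed %||% config$seed
    sc <- do.call(simulation_config, args)
    if (with_network) {
      strata <- stratum_gene_table(sc)
      net <- simulate_network(sc, strata)
      shifts <- NULL
      if (!is.null(sc$neighborhood_coupling)) {
        shifts <- stats::setNames(net$truth$blended_shift,
                                  net$truth$node)
        shifts <- shifts[!is.na(shifts)]
      }
      sim <- simulate_expression(sc, gene_shifts = shifts)
      sim$edges <- net$edges
      sim$network_truth <- net$truth
    } else {
      sim <- simulate_expression(sc)
    }
    sim$config <- sc
    return(sim)
  }
  inp <- config$inputs
  out <- list(
    matrix = read_expression(inp$expression,
                             layout = inp$layout %||% "dense",
                             labels_path = inp$labels),
    strata = read_phylostrata(inp$strata))
  out$cc_genes <- if (!is.null(inp$cc_genes)) read_gmt(inp$cc_genes)[[1]]
  if (with_network) {
    if (is.null(inp$edges)) stop("inputs$edges is required here")
    out$edges <- read_network_edges(inp$edges)
  }
  if (!is.null(inp$cluster)) out$cluster <- read_gmt(inp$cluster)[[1]]
  out
}

write_manifest <- function(config, outdir, files) {
  manifest <- list(
    package = "cellrecap",
    version = as.character(utils::packageVersion("cellrecap")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$simulate$seed %||% config$seed,
    config_hash = digest_config(config),
    outputs = files)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# small deterministic hash (FNV-1a over the deparsed config) -- enough to
# tie outputs to the configuration that produced them
digest_config <- function(config) {
  config$outdir <- NULL    # results do not depend on where they land
  s <- paste(deparse(config[sort(names(config))]), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the evolutionary + slope profile workflow
#'
#' Normalizes, computes the per-stratum intercept contrasts between the
#' configured populations and the per-stratum slope profile of the
#' reference population, and writes `evolutionary_profile.tsv`,
#' `slope_profile.tsv` and a run manifest under `config$outdir`.
#'
#' @param config A [pipeline_config()] (or plain list passed through it).
#' @return Invisibly, a list with the two profile data frames.
#' @export
run_profile <- function(config) {
  config <- pipeline_config(config)
  dat <- load_pipeline_inputs(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  message("profile: ", nrow(dat$matrix$values), " genes x ",
          ncol(dat$matrix$values), " cells")
  evo <- evolutionary_profile(dat$matrix, dat$strata, dat$cc_genes,
                              config$contrast, config$reference,
                              log_offset = config$log_offset,
                              alpha = config$alpha)
  slp <- slope_profile(dat$matrix, dat$strata, dat$cc_genes,
                       population = config$reference,
                       log_offset = config$log_offset,
                       alpha = config$alpha)
  files <- c("evolutionary_profile.tsv", "slope_profile.tsv")
  write_profile(evo, file.path(config$outdir, files[1]))
  write_profile(slp, file.path(config$outdir, files[2]))
  write_manifest(config, config$outdir, files)
  invisible(list(evolutionary = evo, slopes = slp))
}

#' Run the interactome-neighborhood contrast workflow
#'
#' Builds the confidence-filtered network, computes per-node
#' neighborhood MC/UC fractions, bins UC genes by MC fraction (and MC
#' genes by UC fraction), contrasts each bin between the configured
#' populations, and writes `neighborhood_profile.tsv`,
#' `composition_bins.gmt`, `bin_contrasts.tsv` (plus
#' `cluster_contrasts.tsv` when a cluster-membership set is given).
#'
#' @inheritParams run_profile
#' @return Invisibly, a list with the neighborhood profile, bins and
#'   contrast tables.
#' @export
run_network_contrast <- function(config) {
  config <- pipeline_config(config)
  dat <- load_pipeline_inputs(config, with_network = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  net <- build_network(dat$edges, dat$strata,
                       config$confidence_threshold, config$uc_max)
  message("network: ", igraph::vcount(net), " nodes, ",
          igraph::ecount(net), " edges after confidence filter")
  nb <- neighborhood_fractions(net, config$min_neighbors)
  bins <- bin_by_composition(nb)
  message("bins: ", paste(sprintf("%s=%d", names(bins), lengths(bins)),
                          collapse = ", "))
  contrasts <- contrast_gene_sets(dat$matrix, bins, dat$cc_genes,
                                  config$contrast, config$reference,
                                  log_offset = config$log_offset,
                                  alpha = config$alpha)
  files <- c("neighborhood_profile.tsv", "composition_bins.gmt",
             "bin_contrasts.tsv")
  write_neighborhood_profile(nb, file.path(config$outdir, files[1]))
  write_gmt(bins[lengths(bins) > 0], file.path(config$outdir, files[2]))
  write_profile(contrasts, file.path(config$outdir, files[3]))
  cluster_tab <- NULL
  if (!is.null(dat$cluster)) {
    groups <- cluster_contrast_groups(dat$strata, dat$cluster,
                                      config$uc_max)
    cluster_tab <- contrast_gene_sets(dat$matrix, groups, dat$cc_genes,
                                      config$contrast, config$reference,
                                      log_offset = config$log_offset,
                                      alpha = config$alpha)
    files <- c(files, "cluster_contrasts.tsv")
    write_profile(cluster_tab, file.path(config$outdir,
                                         "cluster_contrasts.tsv"))
  }
  write_manifest(config, config$outdir, files)
  invisible(list(neighborhood = nb, bins = bins,
                 bin_contrasts = contrasts,
                 cluster_contrasts = cluster_tab))
}

#' Run the functional-enrichment workflow
#'
#' Propagates ontology annotations up the DAG, merges in any extra gene
#' sets (after identical-membership deduplication), tests the configured
#' sample (default: the UC genes present in the matrix) against the
#' universe of dated matrix genes, and writes `enrichment.tsv`.
#'
#' @inheritParams run_profile
#' @return Invisibly, the `enrichment_result`.
#' @export
run_enrichment <- function(config) {
  config <- pipeline_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    dat <- load_pipeline_inputs(config)
    universe <- intersect(names(dat$strata), rownames(dat$matrix$values))
    sample_genes <- intersect(uc_genes(dat$strata, config$uc_max),
                              universe)
    dag <- simulate_ontology(
      n_terms = 30, depth = 3, genes = universe,
      annotations_per_gene = 2, seed = config$seed,
      planted = list(term_name = "planted UC-biased process",
                     genes = sample_genes))
    categories <- propagate_annotations(dag)
  } else {
    dat <- load_pipeline_inputs(config)
    inp <- config$inputs
    if (is.null(inp$ontology) || is.null(inp$annotations))
      stop("inputs$ontology and inputs$annotations are required")
    dag <- read_ontology(inp$ontology, inp$annotations)
    categories <- propagate_annotations(dag)
    if (!is.null(inp$gene_sets))
      categories <- c(categories,
                      deduplicate_pathways(read_gmt(inp$gene_sets)))
    universe <- intersect(
      intersect(names(dat$strata), rownames(dat$matrix$values)),
      unique(dag$annotations$gene))
    sample_genes <- intersect(uc_genes(dat$strata, config$uc_max),
                              universe)
  }
  message("enrichment: sample ", length(sample_genes), " of ",
          length(universe), " universe genes, ",
          length(categories), " categories")
  res <- enrich_gene_sample(sample_genes, universe, categories)
  write_enrichment(res, file.path(config$outdir, "enrichment.tsv"))
  write_manifest(config, config$outdir, "enrichment.tsv")
  invisible(res)
}

#' Run the synthetic recovery benchmark
#'
#' Simulates expression (and, when neighborhood coupling is configured,
#' the interactome), runs the full analysis, and reports how well the
#' programmed quantities are recovered: per-stratum shift calls against
#' the programmed signs, per-stratum slope signs, and monotonicity of
#' the per-bin contrasts.  Writes `benchmark_report.tsv` plus the
#' underlying profile tables.
#'
#' @inheritParams run_profile
#' @return Invisibly, a list with the report and the profiles.
#' @export
run_benchmark <- function(config) {
  if (is.null(config$simulate) && is.null(config$inputs))
    config$simulate <- list()
  config <- pipeline_config(config)
  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% config$seed
  sc <- do.call(simulation_config, sim_args)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  with_net <- !is.null(sc$neighborhood_coupling)
  cfg2 <- config
  cfg2$simulate <- sim_args
  dat <- load_pipeline_inputs(cfg2, with_network = with_net)
  contrast <- sc$populations[2]; reference <- sc$populations[1]

  evo <- evolutionary_profile(dat$matrix, dat$strata, dat$cc_genes,
                              contrast, reference,
                              log_offset = config$log_offset,
                              alpha = config$alpha)
  # expected calls from the realized per-gene programmed shifts (equal
  # to the configured profile unless neighborhood coupling re-blended
  # them); |mean| <= 0.02 log2 units is treated as no programmed signal
  realized <- dat$truth$gene_shift[names(dat$strata),
                                   sc$populations[2]]
  mean_shift <- tapply(realized, dat$strata, mean)[as.character(1:17)]
  expected_call <- ifelse(mean_shift > 0.02, "up",
                          ifelse(mean_shift < -0.02, "down", "null"))
  miscalls <- sum(evo$call != expected_call)

  slp <- slope_profile(dat$matrix, dat$strata, dat$cc_genes,
                       population = reference, scale = "log2",
                       log_offset = config$log_offset)
  nonzero <- sc$slope_profile != 0
  sign_ok <- sum(sign(slp$slope[nonzero]) ==
                   sign(sc$slope_profile[nonzero]))

  report <- data.frame(
    metric = c("shift_miscalls", "shift_strata",
               "slope_sign_correct", "slope_strata_nonzero"),
    value = c(miscalls, 17L, sign_ok, sum(nonzero)),
    stringsAsFactors = FALSE)

  bin_tab <- NULL
  if (with_net) {
    net <- build_network(dat$edges, dat$strata,
                         config$confidence_threshold, config$uc_max)
    nb <- neighborhood_fractions(net, config$min_neighbors)
    bins <- bin_by_composition(nb)
    bin_tab <- contrast_gene_sets(dat$matrix, bins, dat$cc_genes,
                                  contrast, reference,
                                  log_offset = config$log_offset)
    uc_bins <- bin_tab[grepl("^UC_", bin_tab$group), ]
    monotone <- as.integer(!is.unsorted(uc_bins$delta))
    report <- rbind(report, data.frame(
      metric = c("uc_bins_monotone", "uc_top_bin_delta"),
      value = c(monotone, uc_bins$delta[nrow(uc_bins)]),
      stringsAsFactors = FALSE))
  }
  n_signal <- sum(!evo$call %in% c("null", "empty"))
  if (n_signal <= 2)   # within the expected false-call rate at 95% CIs
    message("benchmark: no signal recovered (", n_signal,
            " of 17 strata non-null)")
  files <- c("benchmark_report.tsv", "evolutionary_profile.tsv",
             "slope_profile.tsv")
  rep_out <- report
  rep_out$value <- format_num(rep_out$value)
  utils::write.table(rep_out, file.path(config$outdir, files[1]),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_profile(evo, file.path(config$outdir, files[2]))
  write_profile(slp, file.path(config$outdir, files[3]))
  if (!is.null(bin_tab)) {
    files <- c(files, "bin_contrasts.tsv")
    write_profile(bin_tab, file.path(config$outdir, "bin_contrasts.tsv"))
  }
  write_manifest(config, config$outdir, files)
  invisible(list(report = report, evolutionary = evo, slopes = slp,
                 bin_contrasts = bin_tab))
}

#' Write every synthetic input of a simulation to disk
#'
#' Materializes one simulated study (expression matrix, labels, strata,
#' cell-cycle signature GMT, edge list) as the plain-text files the
#' reading side of the pipeline consumes -- the round-trip entry point
#' for file-based runs.
#'
#' @inheritParams run_profile
#' @return Invisibly, the vector of written file paths.
#' @export
run_simulate <- function(config) {
  config <- pipeline_config(config)
  dat <- load_pipeline_inputs(config, with_network = TRUE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$outdir,
                     c("expression.tsv", "cell_labels.tsv",
                       "phylostrata.tsv", "cc_signature.gmt",
                       "edges.tsv"))
  write_expression(dat$matrix, paths[1], "dense", labels_path = paths[2])
  write_phylostrata(dat$strata, paths[3])
  write_gmt(list(cell_cycle = dat$cc_genes), paths[4])
  write_network_edges(dat$edges, paths[5])
  write_manifest(config, config$outdir, basename(paths))
  invisible(paths)
}
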