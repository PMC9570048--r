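#' Propagate direct annotations up an ontology DAG
#'
#' A gene belongs to a category if it is directly annotated to it or to
#' any of its descendants.  This matters because specific processes carry
#' almost all direct annotations while their umbrella terms carry almost
#' none; counting without propagation would make broad categories look
#' empty.  Computed for every term by a leaves-first sweep (each term's
#' gene set is its direct genes united with its children's propagated
#' sets).
#'
#' @param dag An [ontology()].
#' @return Named list: term id -> character vector of annotated genes
#'   (after propagation).
#' @export
propagate_annotations <- function(dag) {
  stopifnot(inherits(dag, "ontology"))
  direct <- split(dag$annotations$gene, dag$annotations$term)
  genes <- stats::setNames(rep(list(character(0)), nrow(dag$terms)),
                           dag$terms$id)
  for (id in names(direct)) genes[[id]] <- unique(direct[[id]])
  # push each term's accumulated set into its parents, in leaves-first
  # order so grandchildren are already folded in
  for (id in dag$topo_order)
    for (p in dag$parents[[id]])
      genes[[p]] <- unique(c(genes[[p]], genes[[id]]))
  lapply(genes, sort)
}

#' Exact hypergeometric over/under-representation test
#'
#' Tests whether a category's count in a gene sample departs from the
#' expectation `n_sample * K / N` under random sampling from the
#' universe.  The tail is chosen by the observed/expected ratio: upper
#' tail `P(X >= k)` when O/E > 1 (enrichment), lower tail `P(X <= k)`
#' when O/E < 1 (underrepresentation).  At O/E exactly 1 the smaller tail
#' is doubled and capped at 1 (two-sided fallback).
#'
#' @param k Observed category genes in the sample.
#' @param K Category genes in the universe.
#' @param n_sample Sample size.
#' @param N Universe size.
#' @return List: `p_value`, `oe_ratio`, `expected`, `direction`
#'   ("enriched", "underrepresented" or "none").
#' @export
hypergeometric_test <- function(k, K, n_sample, N) {
  if (N < 1 || K < 0 || K > N || n_sample < 0 || n_sample > N ||
      k < 0 || k > min(K, n_sample) || k < max(0, n_sample + K - N))
    stop("inconsistent hypergeometric counts")
  expected <- n_sample * K / N
  oe <- if (expected > 0) k / expected else NA_real_
  if (is.na(oe) || oe == 1) {
    upper <- stats::phyper(k - 1, K, N - K, n_sample, lower.tail = FALSE)
    lower <- stats::phyper(k, K, N - K, n_sample)
    p <- min(1, 2 * min(upper, lower))
    dir <- "none"
  } else if (oe > 1) {
    p <- stats::phyper(k - 1, K, N - K, n_sample, lower.tail = FALSE)
    dir <- "enriched"
  } else {
    p <- stats::phyper(k, K, N - K, n_sample)
    dir <- "underrepresented"
  }
  list(p_value = p, oe_ratio = oe, expected = expected, direction = dir)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values mapped back to input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of FDR-adjusted values.
#' @export
correct_fdr <- function(p_values) {
  if (any(is.na(p_values) | p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Merge gene sets with identical membership
#'
#' Pathway compendia aggregated from several databases repeat the same
#' gene set under different names; entries with set-equal membership are
#' united into one, with the names concatenated.  Proper subsets are not
#' merged.
#'
#' @param collection Named list of character vectors.
#' @param sep Separator for the merged names.
#' @return Deduplicated named list.
#' @export
deduplicate_pathways <- function(collection, sep = "|") {
  if (length(collection) == 0) return(collection)
  keys <- vapply(collection, function(g)
    paste(sort(unique(g)), collapse = "\r"), character(1))
  split_idx <- split(seq_along(collection), keys)
  # preserve first-appearance order
  split_idx <- split_idx[order(vapply(split_idx, min, integer(1)))]
  out <- lapply(split_idx, function(i) sort(unique(collection[[i[1]]])))
  names(out) <- vapply(split_idx, function(i)
    paste(names(collection)[i], collapse = sep), character(1))
  out
}

#' Hypergeometric enrichment of a gene sample over categories
#'
#' Runs the exact test for every category (ontology terms after
#' propagation, plus any extra gene sets), restricted to the analysis
#' universe, corrects across all tested categories with
#' Benjamini-Hochberg, and ranks by FDR.  The universe should be the
#' genes that could have entered the sample (dated, annotated, present in
#' the analyzed matrix), not the whole genome.  Categories with fewer
#' than `min_category` universe genes are skipped as untestable.
#'
#' @param sample Character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe Character vector of gene ids.
#' @param categories Named list of gene-id vectors (e.g. the output of
#'   [propagate_annotations()], possibly concatenated with gene sets).
#' @param min_category Minimum universe genes per tested category.
#' @return `enrichment_result` data frame sorted by FDR: `category`,
#'   `k`, `K`, `expected`, `oe_ratio`, `direction`, `p_value`, `fdr`.
#' @export
enrich_gene_sample <- function(sample, universe, categories,
                               min_category = 3L) {
  extra <- setdiff(sample, universe)
  if (length(extra))
    stop("sample gene(s) outside the universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  universe <- unique(universe)
  sample <- unique(sample)
  N <- length(universe)
  n <- length(sample)
  rows <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], universe)
    K <- length(cat_genes)
    if (K < min_category) return(NULL)
    k <- length(intersect(cat_genes, sample))
    ht <- hypergeometric_test(k, K, n, N)
    data.frame(category = nm, k = k, K = K, expected = ht$expected,
               oe_ratio = ht$oe_ratio, direction = ht$direction,
               p_value = ht$p_value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(structure(data.frame(category = character(0), k = integer(0),
                                K = integer(0), expected = numeric(0),
                                oe_ratio = numeric(0),
                                direction = character(0),
                                p_value = numeric(0), fdr = numeric(0)),
                     class = c("enrichment_result", "data.frame")))
  res <- do.call(rbind, rows)
  res$fdr <- correct_fdr(res$p_value)
  res <- res[order(res$fdr, res$p_value, res$category), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"))
}

#' Write enrichment results as TSV
#'
#' @param res An `enrichment_result`.
#' @param path Output path.
#' @export
write_enrichment <- function(res, path) {
  out <- as.data.frame(res)
  for (col in c("expected", "oe_ratio", "p_value", "fdr"))
    out[[col]] <- format_num(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
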