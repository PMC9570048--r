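#' Build the confidence-filtered protein-interaction network
#'
#' Keeps edges with confidence strictly above the threshold (the default
#' 0.5 keeps the top-half-confidence interactions), collapses duplicate
#' undirected pairs to the maximum confidence, drops self-loops, and
#' labels every node UC, MC or unknown from the phylostratum map.
#'
#' @param edges Edge data frame from [read_network_edges()] (columns
#'   `protein_a`, `protein_b`, `confidence`).
#' @param strata Named integer vector from [read_phylostrata()].
#' @param confidence_threshold Strict lower bound on retained confidence.
#' @param uc_max UC/MC boundary stratum (see [uc_genes()]).
#' @return An `igraph` undirected simple graph with vertex attribute
#'   `origin` ("UC", "MC" or "unknown") and edge attribute `confidence`.
#' @export
build_network <- function(edges, strata, confidence_threshold = 0.5,
                          uc_max = 2L) {
  if (any(edges$confidence <= 0 | edges$confidence > 1))
    stop("edge confidence outside (0, 1]")
  keep <- edges$confidence > confidence_threshold &
    edges$protein_a != edges$protein_b
  edges <- edges[keep, , drop = FALSE]
  # canonical undirected key, keep max confidence among duplicates
  key <- ifelse(edges$protein_a < edges$protein_b,
                paste(edges$protein_a, edges$protein_b, sep = "\r"),
                paste(edges$protein_b, edges$protein_a, sep = "\r"))
  ord <- order(key, -edges$confidence)
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  g <- igraph::graph_from_data_frame(
    edges[, c("protein_a", "protein_b", "confidence")],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  origin <- rep("unknown", length(nodes))
  dated <- nodes %in% names(strata)
  origin[dated] <- ifelse(strata[nodes[dated]] <= uc_max, "UC", "MC")
  igraph::V(g)$origin <- origin
  g
}

#' One-step-neighborhood UC/MC composition per node
#'
#' For every node: the fraction of MC-origin proteins among its dated
#' (UC or MC) direct interaction partners.  Undated neighbors are
#' excluded from the denominator; nodes with fewer than `min_neighbors`
#' dated neighbors get `mc_fraction = NA` (undefined, not an error).
#'
#' @param net Graph from [build_network()].
#' @param min_neighbors Minimum dated neighbors for a defined fraction.
#' @return Data frame: `node`, `origin`, `n_neighbors`, `n_dated`,
#'   `mc_fraction`, `uc_fraction`.
#' @export
neighborhood_fractions <- function(net, min_neighbors = 3L) {
  nodes <- igraph::V(net)$name
  origin <- igraph::V(net)$origin
  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  rows <- lapply(seq_along(nodes), function(i) {
    nb_origin <- origin[as.integer(adj[[i]])]
    n_dated <- sum(nb_origin != "unknown")
    f <- if (n_dated >= min_neighbors)
      sum(nb_origin == "MC") / n_dated else NA_real_
    data.frame(node = nodes[i], origin = origin[i],
               n_neighbors = length(nb_origin), n_dated = n_dated,
               mc_fraction = f, uc_fraction = 1 - f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Bin genes by the opposite-origin fraction in their neighborhood
#'
#' UC genes are partitioned by the MC fraction of their neighborhood into
#' `[0, 0.25]`, `(0.25, 0.5]`, `(0.5, 0.75]`, `(0.75, 1]` (the lowest bin
#' means "0.25 or a lesser fraction"); MC genes are binned symmetrically
#' by the UC fraction.  The bins come back as a gene-set collection ready
#' for per-bin intercept contrasts.
#'
#' @param profile Output of [neighborhood_fractions()].
#' @return Named list of gene-id vectors with names like `UC_mc_0.25` ..
#'   `UC_mc_1` and `MC_uc_0.25` .. `MC_uc_1`; empty bins trigger a
#'   warning and are kept (empty) in the collection.
#' @export
bin_by_composition <- function(profile) {
  breaks <- c(0, 0.25, 0.5, 0.75, 1)
  bin_of <- function(f) as.integer(cut(f, breaks, include.lowest = TRUE))
  out <- list()
  for (side in c("UC", "MC")) {
    frac <- if (side == "UC") profile$mc_fraction else profile$uc_fraction
    sel <- profile$origin == side & !is.na(frac)
    bins <- bin_of(frac[sel])
    lab <- paste0(side, "_", if (side == "UC") "mc" else "uc", "_",
                  c("0.25", "0.5", "0.75", "1"))
    for (b in 1:4)
      out[[lab[b]]] <- profile$node[sel][bins == b]
  }
  empty <- names(out)[lengths(out) == 0]
  if (length(empty))
    warning("empty composition bin(s): ", paste(empty, collapse = ", "))
  out
}

#' Gene groups defined by giant-cluster membership
#'
#' Intersects UC/MC origin with membership in the UC giant interactome
#' cluster (supplied as an input gene set; cluster detection itself is
#' upstream knowledge, not computed here) into the six standard groups:
#' all UC, all MC, UC inside/outside the cluster, MC inside/outside.
#'
#' @param strata Named integer vector from [read_phylostrata()].
#' @param cluster Character vector of cluster-member gene ids.
#' @param uc_max UC/MC boundary stratum.
#' @return Named list of gene-id vectors; empty groups trigger a warning.
#' @export
cluster_contrast_groups <- function(strata, cluster, uc_max = 2L) {
  uc <- uc_genes(strata, uc_max)
  mc <- mc_genes(strata, uc_max)
  out <- list(
    UC_all = uc,
    MC_all = mc,
    UC_in_cluster = intersect(uc, cluster),
    UC_outside_cluster = setdiff(uc, cluster),
    MC_in_cluster = intersect(mc, cluster),
    MC_outside_cluster = setdiff(mc, cluster))
  empty <- names(out)[lengths(out) == 0]
  if (length(empty))
    warning("empty cluster group(s): ", paste(empty, collapse = ", "))
  out
}

#' Write a neighborhood profile as TSV
#'
#' @param profile Output of [neighborhood_fractions()].
#' @param path Output path.
#' @export
write_neighborhood_profile <- function(profile, path) {
  out <- profile
  out$mc_fraction <- format_num(out$mc_fraction)
  out$uc_fraction <- format_num(out$uc_fraction)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
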