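#' Quantile-normalize an expression matrix
#'
#' Forces every cell's value distribution onto the across-cell mean of the
#' sorted value vectors while preserving within-cell rank order.  Tied
#' values receive the mean of the reference quantiles their rank range
#' spans, which keeps the result deterministic and permutation-invariant.
#' Normalization is always computed on the full matrix, never per
#' population: both populations of a later contrast must share one scale
#' for their intercepts to be comparable.
#'
#' @param em An [expression_matrix()].
#' @return A quantile-normalized [expression_matrix()].
#' @export
quantile_normalize <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  if (ncol(em$values) < 2)
    stop("quantile normalization needs >= 2 cells")
  norm <- limma::normalizeQuantiles(em$values, ties = TRUE)
  dimnames(norm) <- dimnames(em$values)
  expression_matrix(norm, em$cell_labels)
}

#' Per-cell back-transformed mean of a gene group
#'
#' For every cell, the group's values are log2-transformed (with a
#' pseudo-count `log_offset`), averaged, and the average back-transformed
#' as `2^mean - log_offset` (floored at zero).  With `log_offset = 0` this
#' is the geometric mean.  Set `back_transform = FALSE` to keep the signal
#' on the log2 scale, e.g. for slope recovery in log2 units.
#'
#' @param em An [expression_matrix()].
#' @param genes Character vector of gene ids (intersected with matrix
#'   rows; empty intersection is an error).
#' @param log_offset Pseudo-count added before log2 (default 1; use 0 only
#'   when all group values are strictly positive).
#' @param group_name Label carried in the result.
#' @param back_transform Back-transform the mean to the linear scale?
#' @return A `cell_signal` data frame: `cell_id`, `label`, `signal`; the
#'   group name, number of genes used and scale are carried as attributes.
#' @export
group_mean_per_cell <- function(em, genes, log_offset = 1,
                                group_name = "group",
                                back_transform = TRUE) {
  stopifnot(inherits(em, "expr_matrix"))
  genes <- intersect(genes, rownames(em$values))
  if (length(genes) == 0)
    stop("gene group '", group_name,
         "' has no genes in common with the matrix")
  sub <- em$values[genes, , drop = FALSE]
  if (log_offset == 0 && any(sub == 0))
    stop("zero values in group '", group_name,
         "' with log_offset = 0 would give -Inf; use a positive offset")
  m <- colMeans(log2(sub + log_offset))
  signal <- if (back_transform) pmax(2^m - log_offset, 0) else m
  structure(
    data.frame(cell_id = colnames(em$values),
               label = unname(em$cell_labels),
               signal = unname(signal),
               stringsAsFactors = FALSE),
    group = group_name,
    n_genes_used = length(genes),
    scale = if (back_transform) "linear" else "log2",
    log_offset = log_offset,
    class = c("cell_signal", "data.frame"))
}

#' Assemble a cell signal from raw vectors
#'
#' Light constructor for a per-cell signal that did not come from
#' [group_mean_per_cell()] (e.g. an externally computed covariate).
#'
#' @param cell_id Character vector of cell ids.
#' @param label Population/stage label per cell.
#' @param signal Numeric signal per cell.
#' @param group_name Group label carried as an attribute.
#' @return A `cell_signal` data frame.
#' @export
cell_signal <- function(cell_id, label, signal, group_name = "group") {
  stopifnot(length(cell_id) == length(label),
            length(cell_id) == length(signal))
  structure(
    data.frame(cell_id = as.character(cell_id),
               label = as.character(label),
               signal = as.numeric(signal), stringsAsFactors = FALSE),
    group = group_name, n_genes_used = NA_integer_, scale = "linear",
    log_offset = NA_real_,
    class = c("cell_signal", "data.frame"))
}

#' Cell-cycle signature signal with optional overlap removal
#'
#' Computes the per-cell mean of a cell-cycle signature gene set (the
#' regression covariate controlling for proliferative activity) and, when
#' `remove_overlap` is set, strips the signature genes from the tested
#' group.  Overlap removal prevents the circularity of regressing a group
#' on a covariate it partly contains: cell-cycle expression correlates
#' with unicellular-origin gene expression even after the shared genes are
#' removed, so the shared genes themselves must not drive the result.
#'
#' @param em An [expression_matrix()].
#' @param cc_genes Cell-cycle signature gene ids (e.g. the mitotic cell
#'   cycle GO category, GO:0000278).
#' @param tested_group Gene ids of the group under study.
#' @param remove_overlap Remove `cc_genes` from `tested_group`?
#' @param log_offset Passed to [group_mean_per_cell()].
#' @param back_transform Passed to [group_mean_per_cell()].
#' @return List with `cc_signal` (a `cell_signal`) and `tested_group`
#'   (possibly reduced gene set).
#' @export
cell_cycle_signal <- function(em, cc_genes, tested_group,
                              remove_overlap = TRUE, log_offset = 1,
                              back_transform = TRUE) {
  cc_signal <- group_mean_per_cell(em, cc_genes, log_offset,
                                   group_name = "cell_cycle",
                                   back_transform = back_transform)
  group <- tested_group
  if (remove_overlap) {
    group <- setdiff(tested_group, cc_genes)
    if (length(intersect(group, rownames(em$values))) == 0)
      stop("removing the cell-cycle overlap empties the tested group")
  }
  list(cc_signal = cc_signal, tested_group = group)
}

#' Write a cell signal table for inspection
#'
#' @param signal A `cell_signal`.
#' @param path Output TSV path.
#' @export
write_cell_signal <- function(signal, path) {
  out <- data.frame(cell_id = signal$cell_id, label = signal$label,
                    group = attr(signal, "group"),
                    signal = format_num(signal$signal))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# fixed-width numeric formatting used by all TSV writers, so repeated runs
# are byte-identical
format_num <- function(x) formatC(x, digits = 12, format = "g")
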