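#' Construct an expression matrix with cell population labels
#'
#' The central container of the package: a genes x cells matrix of
#' non-negative transcript levels on the linear scale, plus one population
#' (or developmental stage) label per cell.  Values are stored linear and
#' log-transformed only inside the per-cell averaging step, so that input
#' files stay in their natural units.
#'
#' @param values Numeric genes x cells matrix with unique rownames (gene
#'   ids) and colnames (cell ids); all values must be >= 0.
#' @param cell_labels Named character vector mapping every cell id to its
#'   population/stage label.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, cell_labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene ids as rownames and cell ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene id(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicated cell id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stop("expression values must be non-negative and non-missing")
  missing_lab <- setdiff(colnames(values), names(cell_labels))
  if (length(missing_lab))
    stop("cell(s) without a population label: ",
         paste(missing_lab, collapse = ", "))
  structure(
    list(values = values,
         cell_labels = cell_labels[colnames(values)]),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values), "cells\n")
  cat("populations:",
      paste(sprintf("%s (%d)", names(table(x$cell_labels)),
                    table(x$cell_labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Two layouts are supported: `dense` (TSV, genes in rows, first column
#' gene id, header = cell ids) and `triplet` (MatrixMarket coordinate file
#' plus sibling `<path>.rownames` / `<path>.colnames` files, one id per
#' line).  Cell labels come from a separate two-column TSV
#' (`cell_id<TAB>label`, with header).
#'
#' @param path Path to the matrix file.
#' @param layout `"dense"` or `"triplet"`.
#' @param labels_path Path to the cell-label TSV.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, layout = c("dense", "triplet"),
                            labels_path) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("no such file: ", path)
  if (layout == "dense") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    if (anyDuplicated(genes))
      stop("duplicated gene row(s) in ", path, ": ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "))
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- genes
  } else {
    mm <- as.matrix(Matrix::readMM(path))
    rn <- readLines(paste0(path, ".rownames"))
    cn <- readLines(paste0(path, ".colnames"))
    if (nrow(mm) != length(rn) || ncol(mm) != length(cn))
      stop("triplet dimensions do not match rowname/colname files")
    dimnames(mm) <- list(rn, cn)
    vals <- mm
  }
  labels <- read_cell_labels(labels_path)
  expression_matrix(vals, labels)
}

#' Write an expression matrix
#'
#' @inheritParams read_expression
#' @param em An [expression_matrix()].
#' @export
write_expression <- function(em, path, layout = c("dense", "triplet"),
                             labels_path = NULL) {
  layout <- match.arg(layout)
  if (layout == "dense") {
    tab <- data.frame(gene_id = rownames(em$values), em$values,
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(em$values, sparse = TRUE), path)
    writeLines(rownames(em$values), paste0(path, ".rownames"))
    writeLines(colnames(em$values), paste0(path, ".colnames"))
  }
  if (!is.null(labels_path)) write_cell_labels(em$cell_labels, labels_path)
  invisible(path)
}

#' Read / write cell population labels
#'
#' @param path Two-column TSV (`cell_id`, `label`) with header.
#' @return Named character vector.
#' @export
read_cell_labels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' @rdname read_cell_labels
#' @param labels Named character vector (names = cell ids).
#' @export
write_cell_labels <- function(labels, path) {
  utils::write.table(
    data.frame(cell_id = names(labels), label = unname(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene -> phylostratum table
#'
#' Two-column TSV (`gene_id`, `stratum`) with header; strata are integers
#' in 1..17, stratum 1 being cellular organisms and 17 Hominidae.
#'
#' @param path Path to the TSV.
#' @return Named integer vector (names = gene ids).
#' @export
read_phylostrata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  strata <- as.integer(tab[[2]])
  names(strata) <- as.character(tab[[1]])
  validate_phylostrata(strata)
}

validate_phylostrata <- function(strata) {
  if (anyDuplicated(names(strata)))
    stop("duplicated gene id(s) in phylostratum map")
  bad <- is.na(strata) | strata < 1L | strata > 17L
  if (any(bad))
    stop("stratum outside 1..17 for gene(s): ",
         paste(names(strata)[bad], collapse = ", "))
  strata
}

#' @rdname read_phylostrata
#' @param strata Named integer vector.
#' @export
write_phylostrata <- function(strata, path) {
  utils::write.table(
    data.frame(gene_id = names(strata), stratum = unname(strata)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The 17 phylostratum labels
#'
#' Ordered clade names used for human gene dating, from cellular organisms
#' to Hominidae.
#' @export
phylostratum_names <- function() {
  c("cellular organisms", "Eukaryota", "Opisthokonta", "Metazoa",
    "Eumetazoa", "Bilateria", "Chordata", "Vertebrata", "Euteleostomi",
    "Tetrapoda", "Amniota", "Mammalia", "Theria", "Eutheria",
    "Boreoeutheria", "Primates", "Hominidae")
}

#' Unicellular- and multicellular-origin gene sets
#'
#' Genes with stratum `<= uc_max` are of unicellular (UC) origin, the rest
#' of multicellular (MC) origin.  The default boundary places Opisthokonta
#' (stratum 3) on the MC side; it is configurable because Opisthokonta can
#' be viewed as either the last unicellular or the first multicellular
#' stage.
#'
#' @param strata Named integer vector from [read_phylostrata()].
#' @param uc_max Last stratum counted as unicellular (default 2).
#' @return Character vector of gene ids.
#' @export
uc_genes <- function(strata, uc_max = 2L) names(strata)[strata <= uc_max]

#' @rdname uc_genes
#' @export
mc_genes <- function(strata, uc_max = 2L) names(strata)[strata > uc_max]

#' Read / write GMT gene-set files
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' Lines with fewer than three fields are rejected.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    fields <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line (< 3 fields): ", substr(l, 1, 60))
    unique(fields[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) stop("duplicated gene-set name(s) in GMT")
  if (any(lengths(sets) == 0)) stop("empty gene set(s) in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a confidence-scored edge list
#'
#' Three-column TSV (`protein_a`, `protein_b`, `confidence`) with header;
#' confidences must lie in (0, 1].
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `protein_a`, `protein_b`,
#'   `confidence`.
#' @export
read_network_edges <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  edges <- data.frame(protein_a = as.character(tab[[1]]),
                      protein_b = as.character(tab[[2]]),
                      confidence = as.numeric(tab[[3]]),
                      stringsAsFactors = FALSE)
  if (any(is.na(edges$confidence) | edges$confidence <= 0 |
            edges$confidence > 1))
    stop("edge confidence outside (0, 1]")
  edges
}

#' @rdname read_network_edges
#' @param edges Edge data frame.
#' @export
write_network_edges <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Construct an ontology DAG with gene annotations
#'
#' @param terms `data.frame` with columns `id`, `name`.
#' @param parents Named list: term id -> character vector of parent term
#'   ids (`is_a` edges, child to parent).  Must be acyclic.
#' @param annotations `data.frame` with columns `gene`, `term` (direct
#'   annotations only).
#' @return An object of class `ontology`.
#' @export
ontology <- function(terms, parents, annotations) {
  stopifnot(is.data.frame(terms), all(c("id", "name") %in% names(terms)))
  if (anyDuplicated(terms$id)) stop("duplicated term id(s)")
  unknown_parent <- setdiff(unlist(parents), terms$id)
  if (length(unknown_parent))
    stop("is_a edge to unknown term(s): ",
         paste(unknown_parent, collapse = ", "))
  unknown_child <- setdiff(names(parents), terms$id)
  if (length(unknown_child))
    stop("is_a edge from unknown term(s): ",
         paste(unknown_child, collapse = ", "))
  ord <- topological_order(terms$id, parents)  # errors on cycles
  unknown_term <- setdiff(annotations$term, terms$id)
  if (length(unknown_term))
    stop("annotation to unknown term(s): ",
         paste(unique(unknown_term), collapse = ", "))
  structure(list(terms = terms, parents = parents,
                 annotations = annotations, topo_order = ord),
            class = "ontology")
}

# Kahn topological order over child->parent edges; roots (no parents)
# come last.  Errors on a cycle.
topological_order <- function(ids, parents) {
  nparents <- vapply(ids, function(id) {
    p <- parents[[id]]
    if (is.null(p)) 0L else length(p)
  }, integer(1))
  children <- list()
  for (child in names(parents))
    for (p in parents[[child]])
      children[[p]] <- c(children[[p]], child)
  # process leaves-first: count unprocessed children per term
  nchildren <- vapply(ids, function(id) {
    ch <- children[[id]]
    if (is.null(ch)) 0L else length(ch)
  }, integer(1))
  names(nchildren) <- ids
  queue <- ids[nchildren == 0L]
  order <- character(0)
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    order <- c(order, id)
    for (p in parents[[id]]) {
      nchildren[p] <- nchildren[p] - 1L
      if (nchildren[p] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) != length(ids))
    stop("ontology is_a graph contains a cycle")
  order
}

#' @export
print.ontology <- function(x, ...) {
  cat("ontology:", nrow(x$terms), "terms,",
      nrow(x$annotations), "direct annotations\n")
  invisible(x)
}

#' Read an ontology from an OBO-subset file plus an annotation TSV
#'
#' The OBO subset understands `[Term]` stanzas with `id:`, `name:` and
#' `is_a:` lines only.  Annotations are a two-column TSV (`gene`, `term`)
#' with header.
#'
#' @param path OBO-subset file.
#' @param annotations_path Annotation TSV.
#' @return An [ontology()].
#' @export
read_ontology <- function(path, annotations_path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  ids <- character(0); nms <- character(0); parents <- list()
  cur <- NULL
  for (line in lines) {
    line <- sub("\\s+$", "", line)
    if (line == "[Term]") { cur <- NULL; next }
    if (startsWith(line, "id: ")) {
      cur <- sub("^id: ", "", line)
      ids <- c(ids, cur); nms <- c(nms, NA_character_)
    } else if (startsWith(line, "name: ") && !is.null(cur)) {
      nms[length(nms)] <- sub("^name: ", "", line)
    } else if (startsWith(line, "is_a: ") && !is.null(cur)) {
      parent <- sub(" !.*$", "", sub("^is_a: ", "", line))
      parents[[cur]] <- c(parents[[cur]], parent)
    }
  }
  ann <- utils::read.delim(annotations_path, stringsAsFactors = FALSE)
  annotations <- data.frame(gene = as.character(ann[[1]]),
                            term = as.character(ann[[2]]),
                            stringsAsFactors = FALSE)
  ontology(data.frame(id = ids, name = nms, stringsAsFactors = FALSE),
           parents, annotations)
}

#' @rdname read_ontology
#' @param dag An [ontology()].
#' @export
write_ontology <- function(dag, path, annotations_path) {
  stanzas <- vapply(seq_len(nrow(dag$terms)), function(i) {
    id <- dag$terms$id[i]
    is_a <- dag$parents[[id]]
    paste(c("[Term]",
            paste0("id: ", id),
            paste0("name: ", dag$terms$name[i]),
            if (length(is_a)) paste0("is_a: ", is_a)),
          collapse = "\n")
  }, character(1))
  writeLines(paste(stanzas, collapse = "\n\n"), path)
  utils::write.table(dag$annotations, annotations_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
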