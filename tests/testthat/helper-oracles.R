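# Independent oracles used across tests.  These deliberately avoid the
# package's own code paths: the ANCOVA oracle solves the normal equations
# of the full design matrix, the hypergeometric oracle enumerates
# outcomes with binomial coefficients, and the propagation oracle takes
# a brute-force transitive closure of the is_a relation.

# 3-parameter equal-slope ANCOVA via explicit normal equations; returns
# the group-indicator coefficient, its SE and two-sided t p-value
ancova_oracle <- function(x_ref, y_ref, x_con, y_con) {
  y <- c(y_ref, y_con)
  g <- c(rep(0, length(y_ref)), rep(1, length(y_con)))
  x <- c(x_ref, x_con)
  X <- cbind(1, g, x)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  resid <- y - X %*% beta
  df <- length(y) - 3
  sigma2 <- sum(resid^2) / df
  cov <- sigma2 * solve(XtX)
  se <- sqrt(cov[2, 2])
  tstat <- beta[2] / se
  list(delta = beta[2], se = se, slope = beta[3],
       p = 2 * stats::pt(-abs(tstat), df))
}

# exact hypergeometric point mass via binomial coefficients
hyper_point_oracle <- function(i, K, n, N) {
  choose(K, i) * choose(N - K, n - i) / choose(N, n)
}

hyper_upper_oracle <- function(k, K, n, N) {
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  sum(vapply(k:hi, hyper_point_oracle, numeric(1), K = K, n = n, N = N))
}

hyper_lower_oracle <- function(k, K, n, N) {
  lo <- max(0, n + K - N)
  sum(vapply(lo:k, hyper_point_oracle, numeric(1), K = K, n = n, N = N))
}

# brute-force transitive closure: term -> all genes annotated to it or
# to any term from which it is reachable via child->parent edges
propagation_oracle <- function(dag) {
  ids <- dag$terms$id
  n <- length(ids)
  reach <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(reach) <- TRUE
  for (child in names(dag$parents))
    for (p in dag$parents[[child]]) reach[child, p] <- TRUE
  repeat {
    # boolean matrix "multiplication" one step at a time
    new <- (reach %*% reach) > 0
    if (identical(new, reach)) break
    reach <- new
  }
  out <- lapply(ids, function(term) {
    below <- ids[reach[, term]]   # terms that reach `term` (descendants)
    sort(unique(dag$annotations$gene[dag$annotations$term %in% below]))
  })
  names(out) <- ids
  out
}

# random small ontology for propagation tests
random_dag <- function(n_terms, seed) {
  set.seed(seed)
  ids <- sprintf("R%02d", seq_len(n_terms))
  parents <- list()
  for (i in seq(2, n_terms)) {
    k <- sample(1:min(2, i - 1), 1)
    parents[[ids[i]]] <- sample(ids[seq_len(i - 1)], k)
  }
  genes <- sprintf("g%02d", 1:20)
  ann <- data.frame(
    gene = sample(genes, 30, replace = TRUE),
    term = sample(ids, 30, replace = TRUE),
    stringsAsFactors = FALSE)
  ontology(data.frame(id = ids, name = ids, stringsAsFactors = FALSE),
           parents, unique(ann))
}

# small hand-sized expression matrix
tiny_matrix <- function(values, labels) {
  expression_matrix(values, labels)
}

# fast simulation config for structural tests
small_sim_config <- function(...) {
  args <- list(n_genes_per_stratum = 5L, n_cells_per_population = 30L,
               n_cc_genes = 10L, n_background_genes = 200L, seed = 42L)
  override <- list(...)
  args[names(override)] <- override
  do.call(simulation_config, args)
}
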