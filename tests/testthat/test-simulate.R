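test_that("config validation enforces the generator invariants", {
  expect_error(simulation_config(n_genes_per_stratum = 0), ">= 1")
  expect_error(simulation_config(noise_sd = -1), "noise_sd")
  expect_error(simulation_config(slope_profile = rep(0, 16)), "17")
  expect_error(simulation_config(shift_profile = rep(0, 5)), "17")
  expect_error(
    simulation_config(network_params = list(
      n_mc_blocks = 2, p_within_uc = 1.5, p_within_mc = 0.1,
      p_between_mc = 0.1, p_uc_mc = 0.1)),
    "probabilities")
})

test_that("no-signal configuration yields constant stratum genes", {
  sc <- small_sim_config(noise_sd = 0, slope_profile = rep(0, 17),
                         shift_profile = rep(0, 17))
  sim <- simulate_expression(sc)
  stratum_rows <- sim$matrix$values[names(sim$strata), ]
  expect_equal(max(apply(stratum_rows, 1, function(r) diff(range(r)))),
               0)
})

test_that("a single programmed shift doubles exactly that stratum", {
  shift <- rep(0, 17); shift[5] <- 1
  sc <- small_sim_config(noise_sd = 0, slope_profile = rep(0, 17),
                         shift_profile = shift)
  sim <- simulate_expression(sc)
  ref_cells <- names(sim$matrix$cell_labels)[
    sim$matrix$cell_labels == "reference"]
  con_cells <- names(sim$matrix$cell_labels)[
    sim$matrix$cell_labels == "contrast"]
  for (s in c(4, 5, 6)) {
    genes <- names(sim$strata)[sim$strata == s]
    ratio <- sim$matrix$values[genes, con_cells[1]] /
      sim$matrix$values[genes, ref_cells[1]]
    expect_equal(unname(ratio), rep(if (s == 5) 2 else 1,
                                    length(genes)))
  }
})

test_that("matrix is strictly positive and log2 recovers the model", {
  sc <- small_sim_config(noise_sd = 0.3)
  sim <- simulate_expression(sc)
  expect_gt(min(sim$matrix$values), 0)
  # reconstruct each gene's expected log2 value and compare residuals
  act <- sim$truth$cell_activity[colnames(sim$matrix$values)]
  pop <- sim$matrix$cell_labels
  genes <- names(sim$strata)
  slopes <- sc$slope_profile[sim$strata]
  resid <- log2(sim$matrix$values[genes, ]) -
    (sc$alpha_base + sim$truth$gene_shift[genes, pop] +
       outer(slopes, act))
  expect_lt(abs(mean(resid)), 0.05)
  expect_lt(abs(stats::sd(resid) - 0.3), 0.05)
})

test_that("programmed slope signs appear in the group correlations", {
  sc <- simulation_config(
    n_genes_per_stratum = 20L, n_cells_per_population = 100L,
    n_cc_genes = 20L, n_background_genes = 500L,
    slope_profile = c(0.4, 0.4, 0.2, 0.1, 0, rep(-0.2, 12)),
    seed = 9L)
  sim <- simulate_expression(sc)
  cc_sig <- group_mean_per_cell(sim$matrix, sim$cc_genes)
  s1 <- group_mean_per_cell(sim$matrix,
                            names(sim$strata)[sim$strata == 1])
  s6 <- group_mean_per_cell(sim$matrix,
                            names(sim$strata)[sim$strata == 6])
  expect_gt(stats::cor(s1$signal, cc_sig$signal), 0)
  expect_lt(stats::cor(s6$signal, cc_sig$signal), 0)
})

test_that("expression generation is byte-reproducible under one seed", {
  sc <- small_sim_config()
  a <- simulate_expression(sc)
  b <- simulate_expression(sc)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("network blend arithmetic and determinism hold", {
  # blended shift at f = 0.75 with bases (-0.1, +0.1):
  # -0.1 * 0.25 + 0.1 * 0.75 = +0.05 (sign reversal)
  sc <- small_sim_config(neighborhood_coupling = c(-0.1, 0.1))
  strata <- c(stats::setNames(rep(1L, 30), paste0("u", 1:30)),
              stats::setNames(rep(5L, 60), paste0("m", 1:60)))
  net <- simulate_network(sc, strata)
  defined <- !is.na(net$truth$true_mc_fraction)
  expect_equal(net$truth$blended_shift[defined],
               -0.1 * (1 - net$truth$true_mc_fraction[defined]) +
                 0.1 * net$truth$true_mc_fraction[defined])
  at75 <- which(abs(net$truth$true_mc_fraction - 0.75) < 1e-12)
  if (length(at75))
    expect_equal(net$truth$blended_shift[at75[1]], 0.05)
  net2 <- simulate_network(sc, strata)
  expect_identical(serialize(net, NULL), serialize(net2, NULL))
  expect_true(all(net$edges$confidence > 0.4 &
                    net$edges$confidence <= 1))
})

test_that("disconnected blocks give pure own-block neighborhoods", {
  sc <- small_sim_config(network_params = list(
    n_mc_blocks = 1L, p_within_uc = 0.5, p_within_mc = 0.5,
    p_between_mc = 0, p_uc_mc = 0))
  strata <- c(stats::setNames(rep(1L, 20), paste0("u", 1:20)),
              stats::setNames(rep(5L, 20), paste0("m", 1:20)))
  net <- simulate_network(sc, strata)
  uc_rows <- net$truth$node %in% paste0("u", 1:20) &
    !is.na(net$truth$true_mc_fraction)
  expect_true(all(net$truth$true_mc_fraction[uc_rows] == 0))
})

test_that("simulated ontology is a valid single-rooted DAG", {
  genes <- paste0("g", 1:15)
  dag <- simulate_ontology(12, 3, genes, seed = 4)
  # validity was checked by the constructor; root has no parents
  roots <- setdiff(dag$terms$id,
                   names(dag$parents)[lengths(dag$parents) > 0])
  expect_length(roots, 1)
  # star: propagation adds only the root
  star <- simulate_ontology(6, 1, genes, annotations_per_gene = 1,
                            seed = 4)
  prop <- propagate_annotations(star)
  root <- setdiff(star$terms$id, names(star$parents))
  expect_setequal(prop[[root]], unique(star$annotations$gene))
  dag2 <- simulate_ontology(12, 3, genes, seed = 4)
  expect_identical(serialize(dag, NULL), serialize(dag2, NULL))
  expect_error(simulate_ontology(2, 3, genes), "depth")
})

test_that("a planted term is enriched for the planted sample", {
  genes <- paste0("g", 1:60)
  planted_genes <- paste0("g", 1:12)
  dag <- simulate_ontology(15, 2, genes, seed = 8,
                           planted = list(term_name = "planted",
                                          genes = planted_genes))
  categories <- propagate_annotations(dag)
  res <- enrich_gene_sample(planted_genes, genes, categories)
  planted_id <- dag$terms$id[dag$terms$name == "planted"]
  expect_gt(res$oe_ratio[res$category == planted_id], 1)
  expect_identical(res$category[1], planted_id)
})
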