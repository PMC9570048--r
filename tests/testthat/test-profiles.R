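test_that("noiseless log2 slope profile recovers the programmed slopes", {
  beta <- c(0.4, 0.4, 0.25, 0.1, -0.05, rep(-0.2, 12))
  sc <- small_sim_config(noise_sd = 0, slope_profile = beta,
                         shift_profile = rep(0, 17),
                         n_background_genes = 0L)
  sim <- simulate_expression(sc)
  slp <- slope_profile(sim$matrix, sim$strata, sim$cc_genes,
                       population = "reference", normalize = FALSE,
                       log_offset = 0, scale = "log2")
  expect_equal(slp$slope, beta, tolerance = 1e-9)
})

test_that("noisy slope profile recovers the sign pattern", {
  sc <- simulation_config(n_genes_per_stratum = 30L,
                          n_cells_per_population = 150L,
                          n_background_genes = 1000L, seed = 12L)
  sim <- simulate_expression(sc)
  slp <- slope_profile(sim$matrix, sim$strata, sim$cc_genes,
                       population = "reference")
  expect_true(all(slp$slope[1:2] > 0))        # UC strata track the cycle
  expect_true(all(slp$slope[6:17] < 0))       # post-Bilateria negative
})

test_that("constant covariate propagates as an error", {
  sc <- small_sim_config(
    noise_sd = 0, slope_profile = rep(0, 17),
    shift_profile = rep(0, 17),
    cc_activity_params = list(reference = c(location = 1, scale = 0),
                              contrast = c(location = 1, scale = 0)))
  sim <- simulate_expression(sc)
  expect_error(
    slope_profile(sim$matrix, sim$strata, sim$cc_genes,
                  population = "reference", normalize = FALSE),
    "constant")
})

test_that("evolutionary profile calls match the confidence intervals", {
  sc <- small_sim_config(n_cells_per_population = 60L)
  sim <- simulate_expression(sc)
  evo <- evolutionary_profile(sim$matrix, sim$strata, sim$cc_genes,
                              "contrast", "reference")
  expect_equal(nrow(evo), 17)
  expect_identical(evo$call[evo$ci_high < 0],
                   rep("down", sum(evo$ci_high < 0)))
  expect_identical(evo$call[evo$ci_low > 0],
                   rep("up", sum(evo$ci_low > 0)))
  expect_identical(evo$call[evo$ci_low <= 0 & evo$ci_high >= 0],
                   rep("null", sum(evo$ci_low <= 0 & evo$ci_high >= 0)))
  expect_true(all(evo$n_genes == 5))
  expect_true(all(evo$low_power == FALSE))
})

test_that("contrasting a population against itself is exactly null", {
  sc <- small_sim_config()
  sim <- simulate_expression(sc)
  evo <- evolutionary_profile(sim$matrix, sim$strata, sim$cc_genes,
                              "reference", "reference")
  expect_equal(evo$delta, rep(0, 17))
})

test_that("profile is invariant to gene and cell order", {
  sc <- small_sim_config(n_cells_per_population = 40L)
  sim <- simulate_expression(sc)
  evo <- evolutionary_profile(sim$matrix, sim$strata, sim$cc_genes,
                              "contrast", "reference")
  set.seed(1)
  gperm <- sample(nrow(sim$matrix$values))
  cperm <- sample(ncol(sim$matrix$values))
  em2 <- expression_matrix(sim$matrix$values[gperm, cperm],
                           sim$matrix$cell_labels[cperm])
  evo2 <- evolutionary_profile(em2, sim$strata, sim$cc_genes,
                               "contrast", "reference")
  expect_equal(evo2$delta, evo$delta)
  expect_equal(evo2$se, evo$se)
})

test_that("empty and tiny strata are flagged, not dropped", {
  sc <- small_sim_config(n_cells_per_population = 40L)
  sim <- simulate_expression(sc)
  strata <- sim$strata[sim$strata != 4]          # stratum 4 missing
  strata <- strata[!(names(strata) %in%
                       names(sim$strata)[sim$strata == 7][1:3])]
  evo <- evolutionary_profile(sim$matrix, strata, sim$cc_genes,
                              "contrast", "reference")
  expect_identical(evo$call[4], "empty")
  expect_true(evo$low_power[4])
  expect_true(evo$low_power[7])                  # 2 genes left
  expect_false(is.na(evo$delta[7]))
})

test_that("ontogenetic profile peaks at the programmed stage", {
  stages <- c("zygote", "cleavage", "blastocyst", "late")
  shift <- cbind(cleavage = c(0.1, 0.1, rep(0, 15)),
                 blastocyst = c(0.6, 0.6, rep(0, 15)),
                 late = c(-0.3, -0.3, rep(0, 15)))
  sc <- simulation_config(n_genes_per_stratum = 10L,
                          n_cells_per_population = 60L,
                          populations = stages,
                          shift_profile = shift,
                          n_background_genes = 500L,
                          n_cc_genes = 20L, seed = 3L)
  sim <- simulate_expression(sc)
  prof <- ontogenetic_profile(sim$matrix, sim$strata, sim$cc_genes,
                              stage_order = stages,
                              reference_stage = "zygote")
  expect_equal(prof$delta[prof$stage == "zygote"], 0)
  expect_identical(prof$stage[which.max(prof$delta)], "blastocyst")
  expect_lt(prof$delta[prof$stage == "late"], 0)
  expect_error(
    ontogenetic_profile(sim$matrix, sim$strata, sim$cc_genes,
                        c(stages, "nope"), "zygote"),
    "nope")
})

test_that("identical stages contrast to zero", {
  sc <- small_sim_config(n_cells_per_population = 30L)
  sim <- simulate_expression(sc)
  # relabel half of the reference cells as a twin stage: same
  # distribution, contrast should be null
  labels <- sim$matrix$cell_labels
  ref_cells <- names(labels)[labels == "reference"]
  labels[ref_cells[seq(1, length(ref_cells), 2)]] <- "twin"
  em <- expression_matrix(sim$matrix$values, labels)
  prof <- ontogenetic_profile(em, sim$strata, sim$cc_genes,
                              c("reference", "twin"), "reference")
  expect_identical(prof$call[prof$stage == "twin"], "null")
})

test_that("gene-set collection contrasts run per group", {
  sc <- small_sim_config(n_cells_per_population = 50L)
  sim <- simulate_expression(sc)
  groups <- list(uc = uc_genes(sim$strata),
                 mid = names(sim$strata)[sim$strata %in% 3:9],
                 empty_one = "not_a_gene")
  tab <- contrast_gene_sets(sim$matrix, groups, sim$cc_genes,
                            "contrast", "reference")
  expect_equal(nrow(tab), 3)
  expect_identical(tab$call[tab$group == "empty_one"], "empty")
  expect_lt(tab$delta[tab$group == "uc"], 0)
  expect_gt(tab$delta[tab$group == "mid"], 0)
})
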