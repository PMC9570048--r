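#' Evolutionary profile: per-stratum intercept contrasts between two
#' populations
#'
#' For each of the 17 phylostrata: take the stratum's genes (minus the
#' cell-cycle signature when `remove_overlap` is set), average them per
#' cell, and contrast the two populations by the intercept difference at a
#' common slope, with the cell-cycle signature mean as covariate.
#' The qualitative call per stratum is made from the confidence interval:
#' `down` when the CI lies entirely below 0, `up` when entirely above,
#' otherwise `null`.  Strata with fewer than 5 dated genes are flagged
#' low-power rather than dropped.
#'
#' @param em An [expression_matrix()] (linear scale).
#' @param strata Named integer vector from [read_phylostrata()].
#' @param cc_genes Cell-cycle signature gene ids.
#' @param contrast_pop,reference_pop Population labels (delta = contrast
#'   minus reference).
#' @param normalize Quantile-normalize the matrix first (default TRUE).
#' @param remove_overlap Strip `cc_genes` from each stratum group.
#' @param log_offset Pseudo-count for the log2 transform.
#' @param alpha CI level is `1 - alpha`.
#' @return `evo_profile` data frame, one row per stratum: `stratum`,
#'   `stratum_name`, `n_genes`, `delta`, `se`, `ci_low`, `ci_high`, `p`,
#'   `slope`, `call`, `low_power`.
#' @export
evolutionary_profile <- function(em, strata, cc_genes, contrast_pop,
                                 reference_pop, normalize = TRUE,
                                 remove_overlap = TRUE, log_offset = 1,
                                 alpha = 0.05) {
  if (normalize) em <- quantile_normalize(em)
  cc_signal <- group_mean_per_cell(em, cc_genes, log_offset, "cell_cycle")
  rows <- lapply(1:17, function(s) {
    genes <- names(strata)[strata == s]
    if (remove_overlap) genes <- setdiff(genes, cc_genes)
    genes <- intersect(genes, rownames(em$values))
    if (length(genes) == 0)
      return(data.frame(stratum = s,
                        stratum_name = phylostratum_names()[s],
                        n_genes = 0L, delta = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p = NA_real_, slope = NA_real_, call = "empty",
                        low_power = TRUE, stringsAsFactors = FALSE))
    sig <- group_mean_per_cell(em, genes, log_offset,
                               group_name = paste0("stratum_", s))
    ct <- intercept_contrast(sig, cc_signal, contrast_pop, reference_pop,
                             alpha)
    data.frame(stratum = s, stratum_name = phylostratum_names()[s],
               n_genes = length(genes), delta = ct$delta, se = ct$se,
               ci_low = ct$ci[1], ci_high = ct$ci[2], p = ct$p_value,
               slope = ct$slope, call = ci_call(ct$ci),
               low_power = length(genes) < 5L, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            contrast = contrast_pop, reference = reference_pop,
            class = c("evo_profile", "data.frame"))
}

ci_call <- function(ci) {
  if (anyNA(ci)) "null"
  else if (ci[2] < 0) "down"
  else if (ci[1] > 0) "up"
  else "null"
}

#' Slope profile: per-stratum regression slopes within one population
#'
#' The slope of each stratum's group signal on the cell-cycle signature
#' signal, with confidence intervals.  Positive slopes indicate coupling
#' to proliferation (typical of unicellular-origin strata); the coupling
#' declines across multicellular strata and turns negative after
#' Bilateria, where genes serve differentiation and tissue-specific
#' functions.  `scale = "log2"` regresses log2 group means on log2
#' signature means, which recovers a generative log2-linear coupling in
#' its own units.
#'
#' @inheritParams evolutionary_profile
#' @param population Population label (`NULL` = all cells).
#' @param scale `"linear"` (back-transformed, as in the population
#'   contrasts) or `"log2"`.
#' @return `slope_profile` data frame: `stratum`, `stratum_name`,
#'   `n_genes`, `slope`, `se`, `ci_low`, `ci_high`, `r_squared`,
#'   `low_power`.
#' @export
slope_profile <- function(em, strata, cc_genes, population = NULL,
                          normalize = TRUE, remove_overlap = TRUE,
                          log_offset = 1, alpha = 0.05,
                          scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  bt <- scale == "linear"
  if (normalize) em <- quantile_normalize(em)
  cc_signal <- group_mean_per_cell(em, cc_genes, log_offset, "cell_cycle",
                                   back_transform = bt)
  rows <- lapply(1:17, function(s) {
    genes <- names(strata)[strata == s]
    if (remove_overlap) genes <- setdiff(genes, cc_genes)
    genes <- intersect(genes, rownames(em$values))
    if (length(genes) == 0)
      return(data.frame(stratum = s,
                        stratum_name = phylostratum_names()[s],
                        n_genes = 0L, slope = NA_real_, se = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        r_squared = NA_real_, low_power = TRUE,
                        stringsAsFactors = FALSE))
    sig <- group_mean_per_cell(em, genes, log_offset,
                               group_name = paste0("stratum_", s),
                               back_transform = bt)
    fit <- fit_group_regression(sig, cc_signal, population, alpha)
    data.frame(stratum = s, stratum_name = phylostratum_names()[s],
               n_genes = length(genes), slope = fit$slope,
               se = fit$slope_se, ci_low = fit$slope_ci[1],
               ci_high = fit$slope_ci[2], r_squared = fit$r_squared,
               low_power = length(genes) < 5L, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            population = if (is.null(population)) "all" else population,
            scale = scale,
            class = c("slope_profile", "data.frame"))
}

#' Ontogenetic profile: one gene group contrasted across developmental
#' stages
#'
#' Contrasts a single gene group (default: unicellular-origin genes,
#' strata 1-2) between every developmental stage and a fixed reference
#' stage, yielding the trajectory of the group's cell-cycle-controlled
#' expression across ontogenesis.  The reference stage's own contrast is
#' identically zero.
#'
#' @inheritParams evolutionary_profile
#' @param stage_order Character vector of stage labels in ontogenetic
#'   order; every stage must be present in the matrix labels.
#' @param reference_stage Stage all others are contrasted against.
#' @param group Gene ids of the tested group; `NULL` uses UC genes
#'   (strata `<= uc_max`).
#' @param uc_max UC/MC boundary stratum used when `group` is `NULL`.
#' @return `onto_profile` data frame, one row per stage in `stage_order`.
#' @export
ontogenetic_profile <- function(em, strata, cc_genes, stage_order,
                                reference_stage, group = NULL,
                                uc_max = 2L, normalize = TRUE,
                                remove_overlap = TRUE, log_offset = 1,
                                alpha = 0.05) {
  unknown <- setdiff(stage_order, unique(em$cell_labels))
  if (length(unknown))
    stop("unknown stage label(s): ", paste(unknown, collapse = ", "))
  if (!reference_stage %in% stage_order)
    stop("reference stage '", reference_stage, "' not in stage_order")
  if (normalize) em <- quantile_normalize(em)
  if (is.null(group)) group <- uc_genes(strata, uc_max)
  if (remove_overlap) group <- setdiff(group, cc_genes)
  cc_signal <- group_mean_per_cell(em, cc_genes, log_offset, "cell_cycle")
  sig <- group_mean_per_cell(em, group, log_offset, group_name = "tested")
  rows <- lapply(stage_order, function(stage) {
    if (stage == reference_stage)
      return(data.frame(stage = stage, delta = 0, se = 0, ci_low = 0,
                        ci_high = 0, p = 1, slope = NA_real_,
                        call = "null", stringsAsFactors = FALSE))
    ct <- intercept_contrast(sig, cc_signal, stage, reference_stage,
                             alpha)
    data.frame(stage = stage, delta = ct$delta, se = ct$se,
               ci_low = ct$ci[1], ci_high = ct$ci[2], p = ct$p_value,
               slope = ct$slope, call = ci_call(ct$ci),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            reference = reference_stage,
            class = c("onto_profile", "data.frame"))
}

#' Intercept contrasts for an arbitrary gene-set collection
#'
#' Runs the cell-cycle-controlled intercept contrast for each gene set in
#' a collection (regulatory groups, cluster-membership groups,
#' neighborhood-composition bins, ...), sharing one normalization and one
#' covariate across all sets.
#'
#' @inheritParams evolutionary_profile
#' @param groups Named list of gene-id vectors.
#' @return `group_contrasts` data frame, one row per non-empty group:
#'   `group`, `n_genes`, `delta`, `se`, `ci_low`, `ci_high`, `p`,
#'   `slope`, `call`.
#' @export
contrast_gene_sets <- function(em, groups, cc_genes, contrast_pop,
                               reference_pop, normalize = TRUE,
                               remove_overlap = TRUE, log_offset = 1,
                               alpha = 0.05) {
  if (normalize) em <- quantile_normalize(em)
  cc_signal <- group_mean_per_cell(em, cc_genes, log_offset, "cell_cycle")
  rows <- lapply(names(groups), function(nm) {
    genes <- groups[[nm]]
    if (remove_overlap) genes <- setdiff(genes, cc_genes)
    genes <- intersect(genes, rownames(em$values))
    if (length(genes) == 0)
      return(data.frame(group = nm, n_genes = 0L, delta = NA_real_,
                        se = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p = NA_real_,
                        slope = NA_real_, call = "empty",
                        stringsAsFactors = FALSE))
    sig <- group_mean_per_cell(em, genes, log_offset, group_name = nm)
    ct <- intercept_contrast(sig, cc_signal, contrast_pop, reference_pop,
                             alpha)
    data.frame(group = nm, n_genes = length(genes), delta = ct$delta,
               se = ct$se, ci_low = ct$ci[1], ci_high = ct$ci[2],
               p = ct$p_value, slope = ct$slope, call = ci_call(ct$ci),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            contrast = contrast_pop, reference = reference_pop,
            class = c("group_contrasts", "data.frame"))
}

#' Write a profile table as TSV
#'
#' @param profile A profile data frame from [evolutionary_profile()],
#'   [slope_profile()] or [ontogenetic_profile()].
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  out <- as.data.frame(profile)
  num <- vapply(out, is.numeric, logical(1)) &
    !vapply(out, is.integer, logical(1))
  out[num] <- lapply(out[num], format_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
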