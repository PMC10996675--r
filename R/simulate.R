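#' Configuration for the synthetic cross-ome panel
#'
#' Defaults emulate a genotype screen profiled in quadruplicate on matched
#' protein and lipid layers: a control plus `n_genotypes` mutants, planted
#' co-perturbed protein/lipid modules whose members shift together by
#' `effect_size` log2 units in a module-specific subset of mutants, Gaussian
#' replicate noise, and random plus intensity-dependent (MNAR) dropout.
#'
#' @param n_genotypes Number of mutant genotypes (control added on top).
#' @param n_replicates Replicates per genotype.
#' @param n_proteins,n_lipids Features per layer.
#' @param n_modules Planted cross-ome modules.
#' @param module_proteins,module_lipids Members per module and layer.
#' @param effect_size Log2 shift applied to module members in affected
#'   genotypes.
#' @param affected_genotypes Mutants affected per module (drawn without
#'   replacement; the drawn subsets are distinct across modules so modules
#'   stay identifiable).
#' @param noise_sd Replicate-level Gaussian noise SD (log2 units).
#' @param baseline_mean,baseline_sd Per-feature baseline abundance
#'   distribution (log2 scale).
#' @param missing_random Probability of random dropout per cell.
#' @param mnar_slope Slope of the logistic intensity-dependent dropout
#'   applied to cells below the 10th abundance percentile.
#' @param seed Integer seed; the whole panel is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genotypes = 12, n_replicates = 4, n_proteins = 600,
                       n_lipids = 300, n_modules = 5, module_proteins = 30,
                       module_lipids = 15, effect_size = 1.5,
                       affected_genotypes = 3, noise_sd = 0.4,
                       baseline_mean = 20, baseline_sd = 3,
                       missing_random = 0.05, mnar_slope = 1.0, seed = 1) {
  cfg <- list(n_genotypes = n_genotypes, n_replicates = n_replicates,
              n_proteins = n_proteins, n_lipids = n_lipids,
              n_modules = n_modules, module_proteins = module_proteins,
              module_lipids = module_lipids, effect_size = effect_size,
              affected_genotypes = affected_genotypes, noise_sd = noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              missing_random = missing_random, mnar_slope = mnar_slope,
              seed = seed)
  if (cfg$n_modules * cfg$module_proteins > cfg$n_proteins ||
      cfg$n_modules * cfg$module_lipids > cfg$n_lipids) {
    abort("module members exceed the layer size")
  }
  if (cfg$affected_genotypes > cfg$n_genotypes) {
    abort("affected_genotypes exceeds the number of mutants")
  }
  if (cfg$missing_random < 0 || cfg$missing_random > 1) {
    abort("missing_random must be in [0, 1]")
  }
  if (choose(cfg$n_genotypes, cfg$affected_genotypes) < cfg$n_modules) {
    abort("not enough distinct affected-genotype subsets for the modules")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a matched protein/lipid genotype panel
#'
#' Cell values follow
#' `baseline(feature) + effect_size * [member & affected] + N(0, noise_sd^2)`;
#' cross-ome correlation between a module's proteins and lipids then arises
#' from their shared affected-genotype pattern, which is how the analysis
#' expects real co-perturbation to surface. Dropout combines a uniform
#' random component with a logistic missing-not-at-random component acting
#' on the lowest decile of abundance. One annotation term per planted module
#' is emitted per layer, plus size-matched decoy terms over unplanted
#' features.
#'
#' @param cfg A [sim_config()].
#' @return A list: `protein`, `lipid` (omics tibbles), `meta` (metadata
#'   tibble, control genotype `"control"`), `annotations` (list of `protein`
#'   and `lipid` long annotation tibbles), `truth` (list with `modules`
#'   tibble, `affected` tibble, `effect_size`, dropout masks).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, simulate_panel_impl(cfg))
}

simulate_panel_impl <- function(cfg) {
  genotypes <- c("control", sprintf("KO%02d", seq_len(cfg$n_genotypes)))
  meta <- tidyr::expand_grid(genotype = genotypes,
                             replicate = seq_len(cfg$n_replicates)) |>
    dplyr::mutate(sample_id = sprintf("%s_r%d", .data$genotype,
                                      .data$replicate),
                  .before = "genotype")
  meta <- validate_metadata(meta, control = "control")

  protein_ids <- sprintf("P%04d", seq_len(cfg$n_proteins))
  lipid_ids <- sprintf("L%04d", seq_len(cfg$n_lipids))

  # distinct affected-genotype subsets keep modules identifiable
  mutants <- setdiff(genotypes, "control")
  affected <- list()
  while (length(affected) < cfg$n_modules) {
    draw <- sort(sample(mutants, cfg$affected_genotypes))
    key <- paste(draw, collapse = "|")
    if (!key %in% names(affected)) affected[[key]] <- draw
  }
  affected <- unname(affected)

  mod_prot <- split(sample(protein_ids, cfg$n_modules * cfg$module_proteins),
                    rep(seq_len(cfg$n_modules), each = cfg$module_proteins))
  mod_lip <- split(sample(lipid_ids, cfg$n_modules * cfg$module_lipids),
                   rep(seq_len(cfg$n_modules), each = cfg$module_lipids))

  sim_layer <- function(ids, members) {
    n_feat <- length(ids)
    n_samp <- nrow(meta)
    baseline <- rnorm(n_feat, cfg$baseline_mean, cfg$baseline_sd)
    vals <- matrix(baseline, n_feat, n_samp) +
      matrix(rnorm(n_feat * n_samp, 0, cfg$noise_sd), n_feat, n_samp)
    dimnames(vals) <- list(ids, meta$sample_id)
    for (m in seq_len(cfg$n_modules)) {
      rows <- match(members[[m]], ids)
      cols <- which(meta$genotype %in% affected[[m]])
      vals[rows, cols] <- vals[rows, cols] + cfg$effect_size
    }
    # dropout: uniform random, plus logistic MNAR below the 10th percentile
    p_drop <- matrix(cfg$missing_random, n_feat, n_samp)
    if (cfg$mnar_slope > 0) {
      q10 <- quantile(vals, 0.1)
      low <- vals < q10
      p_mnar <- plogis(cfg$mnar_slope * (q10 - vals))
      p_drop[low] <- 1 - (1 - p_drop[low]) * (1 - p_mnar[low])
    }
    mask <- matrix(runif(n_feat * n_samp) < p_drop, n_feat, n_samp,
                   dimnames = dimnames(vals))
    vals[mask] <- NA_real_
    list(values = vals, mask = mask)
  }

  prot <- sim_layer(protein_ids, mod_prot)
  lip <- sim_layer(lipid_ids, mod_lip)

  make_sets <- function(ids, members, layer) {
    planted <- purrr::imap(members, function(feats, m) {
      tibble::tibble(term_id = sprintf("module%s_%s", m, layer),
                     description = sprintf("planted module %s (%s)", m, layer),
                     feature_id = feats)
    })
    unplanted <- setdiff(ids, unlist(members))
    size <- length(members[[1]])
    n_decoys <- min(length(members), floor(length(unplanted) / size))
    decoys <- purrr::map(seq_len(n_decoys), function(d) {
      tibble::tibble(term_id = sprintf("decoy%d_%s", d, layer),
                     description = sprintf("size-matched decoy %d (%s)", d, layer),
                     feature_id = sample(unplanted, size))
    })
    out <- dplyr::bind_rows(c(planted, decoys))
    attr(out, "layer") <- layer
    out
  }
  ann_prot <- make_sets(protein_ids, mod_prot, "protein")
  ann_lip <- make_sets(lipid_ids, mod_lip, "lipid")

  truth <- list(
    modules = dplyr::bind_rows(c(
      unname(purrr::imap(mod_prot, ~ tibble::tibble(module = as.integer(.y),
                                                    layer = "protein",
                                                    feature_id = .x))),
      unname(purrr::imap(mod_lip, ~ tibble::tibble(module = as.integer(.y),
                                                   layer = "lipid",
                                                   feature_id = .x))))),
    affected = dplyr::bind_rows(
      unname(purrr::imap(affected,
                         ~ tibble::tibble(module = as.integer(.y),
                                          genotype = .x)))),
    effect_size = cfg$effect_size,
    dropout = list(protein = prot$mask, lipid = lip$mask)
  )

  list(protein = omics_from_values(prot$values, layer = "protein"),
       lipid = omics_from_values(lip$values, layer = "lipid"),
       meta = meta,
       annotations = list(protein = ann_prot, lipid = ann_lip),
       truth = truth)
}

#' Adjusted Rand index between cluster assignments and planted modules
#'
#' @param assignments Tibble with `feature_id`, `cluster`.
#' @param truth_modules Tibble with `feature_id`, `module` for one layer.
#' @return ARI over the shared features, or `NA` when none are shared.
#' @export
planted_ari <- function(assignments, truth_modules) {
  shared <- dplyr::inner_join(assignments, truth_modules, by = "feature_id")
  if (nrow(shared) == 0) return(NA_real_)
  mclust::adjustedRandIndex(shared$cluster, shared$module)
}

#' Evaluate pipeline recovery of planted structure
#'
#' Summarises how well a pipeline run recovered the generator's ground
#' truth: the adjusted Rand index per axis (clusters versus planted modules,
#' restricted to planted features that survived filtering), the fraction of
#' within-module lipid-protein pairs with positive tau, and the fraction of
#' planted annotation terms reaching BH `q < 0.05` in their best-matching
#' cluster (the cluster with the largest member overlap).
#'
#' @param truth Ground-truth list from [simulate_panel()].
#' @param protein_clusters,lipid_clusters `crossome_clusters` models.
#' @param enrich_protein,enrich_lipid Enrichment tibbles from
#'   [fisher_enrich()]; may be `NULL` to skip that metric.
#' @param cm Long cross-correlation tibble (pre- or post-filter).
#' @param q_cutoff BH q-value below which a planted term counts as recovered.
#' @return One-row tibble: `ari_protein`, `ari_lipid`,
#'   `tau_sign_accuracy`, `recovered_terms_protein`, `recovered_terms_lipid`.
#' @export
evaluate_recovery <- function(truth, protein_clusters, lipid_clusters,
                              enrich_protein = NULL, enrich_lipid = NULL,
                              cm = NULL, q_cutoff = 0.05) {
  mod_p <- dplyr::filter(truth$modules, .data$layer == "protein")
  mod_l <- dplyr::filter(truth$modules, .data$layer == "lipid")
  ari_p <- planted_ari(protein_clusters$assignments, mod_p)
  ari_l <- planted_ari(lipid_clusters$assignments, mod_l)

  tau_sign <- NA_real_
  if (!is.null(cm)) {
    pairs <- dplyr::inner_join(
      dplyr::rename(mod_l, lipid_id = "feature_id"),
      dplyr::rename(mod_p, protein_id = "feature_id"),
      by = "module", relationship = "many-to-many") |>
      dplyr::inner_join(cm, by = c("lipid_id", "protein_id")) |>
      dplyr::filter(!is.na(.data$tau))
    tau_sign <- if (nrow(pairs) > 0) mean(pairs$tau > 0) else NA_real_
  }

  frac_recovered <- function(enrich) {
    if (is.null(enrich) || nrow(enrich) == 0) return(NA_real_)
    planted_terms <- unique(grep("^module", enrich$term_id, value = TRUE))
    if (length(planted_terms) == 0) return(NA_real_)
    hits <- vapply(planted_terms, function(tm) {
      rows <- enrich[enrich$term_id == tm, , drop = FALSE]
      best <- rows[which.max(rows$a), , drop = FALSE]
      nrow(best) > 0 && best$q_value < q_cutoff
    }, logical(1))
    mean(hits)
  }

  tibble::tibble(
    ari_protein = ari_p,
    ari_lipid = ari_l,
    tau_sign_accuracy = tau_sign,
    recovered_terms_protein = frac_recovered(enrich_protein),
    recovered_terms_lipid = frac_recovered(enrich_lipid)
  )
}
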