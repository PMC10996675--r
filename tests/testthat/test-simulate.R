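small_cfg <- function(...) {
  sim_config(n_genotypes = 6, n_replicates = 3, n_proteins = 60,
             n_lipids = 30, n_modules = 3, module_proteins = 6,
             module_lipids = 3, ...)
}

test_that("the same seed reproduces the panel bit-exactly", {
  p1 <- simulate_panel(small_cfg(seed = 9))
  p2 <- simulate_panel(small_cfg(seed = 9))
  expect_identical(p1$protein, p2$protein)
  expect_identical(p1$lipid, p2$lipid)
  expect_identical(p1$truth$modules, p2$truth$modules)
  p3 <- simulate_panel(small_cfg(seed = 10))
  expect_false(identical(p1$protein, p3$protein))
})

test_that("zero noise and zero dropout plant the effect exactly", {
  cfg <- small_cfg(noise_sd = 0, missing_random = 0, mnar_slope = 0, seed = 4)
  panel <- simulate_panel(cfg)
  expect_equal(sum(is.na(crossome:::omics_values(panel$protein))), 0L)
  expect_equal(sum(is.na(crossome:::omics_values(panel$lipid))), 0L)

  diff <- log2fc_vs_control(panel$protein, panel$meta)
  truth <- panel$truth
  joined <- dplyr::inner_join(
    diff, dplyr::filter(truth$modules, layer == "protein"),
    by = "feature_id") |>
    dplyr::left_join(dplyr::mutate(truth$affected, hit = TRUE),
                     by = c("module", "genotype")) |>
    dplyr::mutate(hit = !is.na(hit))
  expect_equal(joined$log2fc[joined$hit],
               rep(cfg$effect_size, sum(joined$hit)))
  expect_equal(joined$log2fc[!joined$hit], rep(0, sum(!joined$hit)))
})

test_that("control-vs-control fold changes carry no spurious effect", {
  cfg <- small_cfg(noise_sd = 0.4, missing_random = 0, mnar_slope = 0,
                   seed = 13)
  panel <- simulate_panel(cfg)
  meta2 <- panel$meta
  # relabel half the control replicates as a pseudo-mutant
  ctrl <- which(meta2$genotype == "control")
  # with 3 control replicates, compare replicate 1 vs 2-3 across many features
  meta2$genotype[ctrl[1]] <- "pseudo"
  attr(meta2, "control") <- "control"
  diff <- log2fc_vs_control(panel$protein, meta2, min_reps = 1)
  fc <- diff$log2fc[diff$genotype == "pseudo"]
  se <- cfg$noise_sd * sqrt(1 + 1 / 2) / sqrt(length(fc))
  expect_lt(abs(mean(fc, na.rm = TRUE)), 3 * se)
})

test_that("MNAR dropout rate is non-increasing in abundance", {
  cfg <- sim_config(n_genotypes = 8, n_replicates = 4, n_proteins = 400,
                    n_lipids = 100, missing_random = 0, mnar_slope = 1,
                    seed = 17)
  panel <- simulate_panel(cfg)
  vals_obs <- crossome:::omics_values(panel$protein)
  mask <- panel$truth$dropout$protein
  # reconstruct pre-dropout values for binning: observed where kept
  expect_true(all(is.na(vals_obs[mask])))
  kept <- !is.na(vals_obs)
  bins <- cut(vals_obs[kept], quantile(vals_obs[kept], seq(0, 1, 0.2)),
              include.lowest = TRUE)
  # dropout happened below the 10th percentile only: rates by observed bin
  # cannot be checked directly post hoc, so check the generative rule:
  # every masked cell must lie in the low-abundance regime or be random,
  # and with missing_random = 0 all dropout is MNAR
  expect_gt(sum(mask), 0)
  # rate per abundance bin computed on the truth: all masked cells were low
  # (their observed value is gone), so verify via a fresh no-dropout twin
  cfg0 <- sim_config(n_genotypes = 8, n_replicates = 4, n_proteins = 400,
                     n_lipids = 100, missing_random = 0, mnar_slope = 0,
                     seed = 17)
  twin <- simulate_panel(cfg0)
  full <- crossome:::omics_values(twin$protein)
  expect_equal(dim(full), dim(mask))
  q <- quantile(full, seq(0, 1, 0.1))
  bin <- cut(as.vector(full), q, include.lowest = TRUE)
  rate <- tapply(as.vector(mask), bin, mean)
  expect_true(all(diff(rate) <= 1e-9))
  expect_equal(unname(rate[length(rate)]), 0)
})

test_that("planted ARI rewards relabelings and punishes shuffles", {
  truth <- tibble::tibble(feature_id = sprintf("F%02d", 1:30),
                          module = rep(1:3, each = 10))
  asg <- tibble::tibble(feature_id = truth$feature_id,
                        cluster = c(3L, 1L, 2L)[truth$module])
  expect_equal(planted_ari(asg, truth), 1)

  set.seed(19)
  aris <- replicate(100, {
    shuf <- dplyr::mutate(asg, cluster = sample(cluster))
    planted_ari(shuf, truth)
  })
  expect_lt(max(abs(aris)), 0.35)
  expect_lt(abs(mean(aris)), 0.05)

  none <- tibble::tibble(feature_id = "other", module = 1L)
  expect_true(is.na(planted_ari(asg, none)))
})

test_that("invalid generator configurations are rejected", {
  expect_error(sim_config(n_proteins = 10, n_modules = 5,
                          module_proteins = 30), "exceed")
  expect_error(sim_config(affected_genotypes = 20), "exceeds")
  expect_error(sim_config(missing_random = 1.2), "missing_random")
  expect_error(sim_config(n_genotypes = 3, n_modules = 5,
                          affected_genotypes = 3), "distinct")
})

test_that("module feature sets are disjoint and affected sets distinct", {
  panel <- simulate_panel(small_cfg(seed = 23))
  mods <- panel$truth$modules
  for (ly in c("protein", "lipid")) {
    ids <- mods$feature_id[mods$layer == ly]
    expect_equal(anyDuplicated(ids), 0L)
  }
  keys <- panel$truth$affected |>
    dplyr::group_by(module) |>
    dplyr::summarise(key = paste(sort(genotype), collapse = "|"))
  expect_equal(anyDuplicated(keys$key), 0L)
})
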