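diff_fixture <- function() {
  tidyr::expand_grid(feature_id = c("F1", "F2", "F3", "F4"),
                     genotype = c("KO1", "KO2")) |>
    dplyr::mutate(log2fc = c(1.0, 0.5,   # F1 in KO1, KO2
                             0.5, NA,    # F2
                             -0.25, 2,   # F3
                             0, 1)[seq_len(8)],
                  n_case = 4L, n_control = 4L)
}

test_that("set signatures aggregate member fold changes per genotype", {
  diff <- diff_fixture()
  s <- set_signature(diff, c("F1", "F2"), mode = "sum", set_id = "S")
  expect_equal(s$value[s$genotype == "KO1"], 1.5)
  expect_equal(s$n_members_used[s$genotype == "KO1"], 2L)
  # F2 missing in KO2: only F1 contributes
  expect_equal(s$value[s$genotype == "KO2"], 0.5)
  expect_equal(s$n_members_used[s$genotype == "KO2"], 1L)

  m <- set_signature(diff, c("F1", "F2"), mode = "mean")
  expect_equal(m$value[m$genotype == "KO1"], 0.75)

  # all members missing in a genotype -> missing value, n_used 0
  diff_na <- dplyr::mutate(diff,
                           log2fc = ifelse(genotype == "KO2", NA, log2fc))
  sna <- set_signature(diff_na, c("F1", "F2"))
  expect_true(is.na(sna$value[sna$genotype == "KO2"]))
  expect_equal(sna$n_members_used[sna$genotype == "KO2"], 0L)

  expect_error(set_signature(diff, character()), "non-empty")
})

test_that("sum signatures are additive over disjoint member sets", {
  diff <- diff_fixture()
  s12 <- set_signature(diff, c("F1", "F2"), mode = "sum")
  s34 <- set_signature(diff, c("F3", "F4"), mode = "sum")
  sall <- set_signature(diff, c("F1", "F2", "F3", "F4"), mode = "sum")
  merged <- dplyr::full_join(s12, s34, by = "genotype")
  expect_equal(sall$value,
               dplyr::coalesce(merged$value.x, 0) +
                 dplyr::coalesce(merged$value.y, 0))
})

test_that("module signatures treat curated sets independently", {
  diff <- diff_fixture()
  curated <- tibble::tibble(term_id = c("A", "A", "B", "B"),
                            feature_id = c("F1", "F2", "F3", "F4"))
  sigs <- module_signatures(diff, curated, mode = "mean")
  solo_a <- set_signature(diff, c("F1", "F2"), mode = "mean", set_id = "A")
  expect_equal(sigs[sigs$set_id == "A", ], solo_a)

  # set = all features, mean -> per-genotype grand mean
  allset <- tibble::tibble(term_id = "all",
                           feature_id = unique(diff$feature_id))
  grand <- module_signatures(diff, allset, mode = "mean")
  by_hand <- diff |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(v = mean(log2fc, na.rm = TRUE))
  expect_equal(grand$value, by_hand$v)
})

test_that("a planted zero-noise effect is recovered exactly by mean signatures", {
  cfg <- sim_config(n_genotypes = 4, n_proteins = 40, n_lipids = 20,
                    n_modules = 2, module_proteins = 5, module_lipids = 3,
                    noise_sd = 0, missing_random = 0, mnar_slope = 0,
                    effect_size = 1.5, seed = 3)
  panel <- simulate_panel(cfg)
  diff <- log2fc_vs_control(panel$protein, panel$meta)
  truth <- panel$truth
  members <- truth$modules$feature_id[truth$modules$module == 1 &
                                        truth$modules$layer == "protein"]
  affected <- truth$affected$genotype[truth$affected$module == 1]
  sig <- set_signature(diff, members, mode = "mean")
  expect_equal(sig$value[sig$genotype %in% affected],
               rep(1.5, length(affected)))
  expect_equal(sig$value[!sig$genotype %in% affected],
               rep(0, sum(!sig$genotype %in% affected)))
})

test_that("network extraction selects seed-touching edges above threshold", {
  cm <- tibble::tibble(
    lipid_id = c("L1", "L1", "L1", "L2", "L2", "L3"),
    protein_id = c("Pa", "Pb", "Pc", "Pa", "Pd", "Pd"),
    tau = c(0.9, 0.7, 0.5, 0.6, -0.8, 0.3),
    n_pairs = 20L)
  net <- extract_network(cm, "L1", tau_threshold = 0.4)
  expect_equal(nrow(net$edges), 3L)
  expect_setequal(net$nodes$feature_id[net$nodes$layer == "protein"],
                  c("Pa", "Pb", "Pc"))

  # threshold 1 -> empty network is valid
  empty <- extract_network(cm, "L1", tau_threshold = 1)
  expect_equal(nrow(empty$edges), 0L)

  # seeds on both layers union without duplicate edges
  both <- extract_network(cm, c("L1", "Pa"), tau_threshold = 0.4)
  expect_equal(nrow(both$edges), 4L)
  expect_equal(anyDuplicated(both$edges[, c("lipid_id", "protein_id")]), 0L)

  # monotone in the threshold: higher threshold yields a subgraph
  lo <- extract_network(cm, c("L1", "L2"), tau_threshold = 0.4)
  hi <- extract_network(cm, c("L1", "L2"), tau_threshold = 0.65)
  expect_true(all(paste(hi$edges$lipid_id, hi$edges$protein_id) %in%
                    paste(lo$edges$lipid_id, lo$edges$protein_id)))

  expect_error(extract_network(cm, "nope"), "seed features")

  g <- as_igraph(net)
  expect_equal(igraph::gorder(g), 4L)
  expect_true(igraph::is_bipartite(g))
})

test_that("top-partner frequencies count and conserve correctly", {
  cm <- tidyr::expand_grid(lipid_id = c("L1", "L2"),
                           protein_id = sprintf("P%d", 1:5)) |>
    dplyr::mutate(tau = c(0.9, 0.8, 0.7, 0.2, 0.1,
                          0.85, 0.75, 0.65, 0.3, 0.05),
                  n_pairs = 20L)
  freq <- top_partner_frequency(cm, n_top = 3)
  expect_equal(freq$frequency[match(c("P1", "P2", "P3"), freq$protein_id)],
               rep(2L, 3))
  expect_equal(sum(freq$frequency), 6L)  # 2 lipids x top 3

  # saturation: more requested than available, with warning; conservation
  expect_warning(all5 <- top_partner_frequency(cm, n_top = 10), "fewer than")
  expect_equal(sum(all5$frequency), 10L)

  # category map sending everything to one label conserves the total
  cats <- stats::setNames(rep("X", 5), sprintf("P%d", 1:5))
  freqc <- top_partner_frequency(cm, n_top = 3, categories = cats)
  cc <- attr(freqc, "category_counts")
  expect_equal(cc$count[cc$category == "X"], 6L)

  # deterministic tie-break: equal taus resolved by protein id
  tie <- tibble::tibble(lipid_id = "L1", protein_id = c("Pb", "Pa", "Pc"),
                        tau = c(0.5, 0.5, 0.5), n_pairs = 20L)
  f1 <- top_partner_frequency(tie, n_top = 2)
  expect_setequal(f1$protein_id, c("Pa", "Pb"))
})

test_that("outlier analysis flags extreme genotypes with robust z", {
  genos <- sprintf("G%02d", 1:6)
  diff <- tibble::tibble(feature_id = "F1", genotype = genos,
                         log2fc = c(-0.2, -0.1, 0.0, 0.1, 0.2, 3.0))
  rep_ <- outlier_analysis(diff, z_cutoff = 2.5, min_genotypes = 6)
  flagged <- rep_$scores$genotype[rep_$scores$flagged]
  expect_equal(flagged, "G06")
  z6 <- rep_$scores$robust_z[rep_$scores$genotype == "G06"]
  expect_equal(z6, (3.0 - 0.05) / (stats::mad(diff$log2fc) + 1e-9),
               tolerance = 1e-9)
  expect_gt(z6, 13)

  # degenerate: all equal -> MAD and SD fallback are 0 -> no flags
  flat <- dplyr::mutate(diff, log2fc = 1)
  rflat <- outlier_analysis(flat, min_genotypes = 6)
  expect_false(any(rflat$scores$flagged))

  # symmetric +/- v pair: both flagged or neither
  sym <- tibble::tibble(feature_id = "F1", genotype = sprintf("G%02d", 1:8),
                        log2fc = c(-0.1, 0.1, -0.05, 0.05, 0, 0, -4, 4))
  rsym <- outlier_analysis(sym, min_genotypes = 8)
  fl <- rsym$scores$flagged[rsym$scores$genotype %in% c("G07", "G08")]
  expect_equal(fl[1], fl[2])

  # location invariance
  shift <- dplyr::mutate(diff, log2fc = log2fc + 10)
  rshift <- outlier_analysis(shift, min_genotypes = 6)
  expect_equal(rep_$scores$flagged, rshift$scores$flagged)

  # features under the genotype floor are skipped with a warning
  expect_warning(r2 <- outlier_analysis(diff, min_genotypes = 10), "skipped")
  expect_equal(nrow(r2$scores), 0L)
})

test_that("flagged genotypes get a similarity ranking over flagged features", {
  genos <- sprintf("G%02d", 1:10)
  set.seed(71)
  feats <- sprintf("F%02d", 1:6)
  diff <- tidyr::expand_grid(feature_id = feats, genotype = genos) |>
    dplyr::mutate(log2fc = rnorm(dplyr::n(), 0, 0.1))
  # G01 extreme on all features; G02 mirrors G01's pattern
  pattern <- seq(3, 5.5, length.out = 6)
  diff$log2fc[diff$genotype == "G01"] <- pattern
  diff$log2fc[diff$genotype == "G02"] <- pattern * 0.9 + 0.05
  rep_ <- outlier_analysis(diff, z_cutoff = 2.5, min_genotypes = 10)
  expect_true(all(c("G01", "G02") %in% rep_$scores$genotype[rep_$scores$flagged]))
  sim_g1 <- rep_$similar[rep_$similar$genotype == "G01", ]
  expect_false("G01" %in% sim_g1$other)
  expect_equal(sim_g1$other[1], "G02")  # most similar profile ranks first
})
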