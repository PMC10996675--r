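make_clusters <- function(assignments) {
  structure(list(axis = "protein", k = length(unique(assignments$cluster)),
                 assignments = assignments,
                 dendrogram_order = assignments$feature_id,
                 inertia = 0, seed = 1, restarts = 1),
            class = "crossome_clusters")
}

test_that("Fisher enrichment equals the hypergeometric tail oracle", {
  # N = 100, K = 20, n = 10, a = 8
  background <- sprintf("F%03d", 1:100)
  term <- background[1:20]
  cluster <- c(background[1:8], background[90:91])
  asg <- tibble::tibble(
    feature_id = background,
    cluster = ifelse(background %in% cluster, 1L, 2L))
  ann <- tibble::tibble(term_id = "T1", description = "term one",
                        feature_id = term)
  res <- fisher_enrich(make_clusters(asg), ann)
  row <- res[res$cluster == 1 & res$term_id == "T1", ]
  expect_equal(row$a, 8L)
  expect_equal(row$p_value, oracle_hyper_tail(8, 20, 100, 10),
               tolerance = 1e-14)

  # zero overlap has the full upper-tail mass
  asg0 <- tibble::tibble(feature_id = background,
                         cluster = ifelse(background %in% background[21:30],
                                          1L, 2L))
  res0 <- fisher_enrich(make_clusters(asg0), ann)
  expect_equal(res0$p_value[res0$cluster == 1], 1)

  # cluster identical to the term: single most extreme table, p = 1/C(N, n)
  termK <- background[1:10]
  asgK <- tibble::tibble(feature_id = background,
                         cluster = ifelse(background %in% termK, 1L, 2L))
  annK <- tibble::tibble(term_id = "TK", description = "k", feature_id = termK)
  resK <- fisher_enrich(make_clusters(asgK), annK)
  expect_equal(resK$p_value[resK$cluster == 1], 1 / choose(100, 10),
               tolerance = 1e-12)
})

test_that("Fisher p matches the oracle across random tables (property)", {
  set.seed(61)
  for (i in 1:50) {
    N <- sample(10:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    a <- sample(max(1, n - (N - K)):min(K, n), 1)
    background <- sprintf("F%03d", 1:N)
    term <- background[1:K]
    cluster <- c(background[seq_len(a)],
                 if (n > a) background[K + seq_len(n - a)])
    asg <- tibble::tibble(
      feature_id = background,
      cluster = ifelse(background %in% cluster, 1L, 2L))
    ann <- tibble::tibble(term_id = "T", description = "t", feature_id = term)
    res <- fisher_enrich(make_clusters(asg), ann)
    got <- res$p_value[res$cluster == 1]
    expect_equal(got, oracle_hyper_tail(a, K, N, n), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up formula and stays consistent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(62)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
})

test_that("enrichment restricts annotations to the background before testing", {
  background <- sprintf("F%02d", 1:20)
  asg <- tibble::tibble(feature_id = background,
                        cluster = rep(1:2, each = 10))
  ann <- tibble::tibble(term_id = "T", description = "t",
                        feature_id = c(background[1:5], "OUTSIDE1", "OUTSIDE2"))
  res <- fisher_enrich(make_clusters(asg), ann)
  expect_equal(res$a[res$cluster == 1] + res$c[res$cluster == 1], 5L)
  expect_equal(res$a + res$b + res$c + res$d, rep(20L, nrow(res)))
  expect_error(fisher_enrich(make_clusters(asg), ann,
                             background = background[1:5]),
               "every cluster member")
})

test_that("rank-skew test is exact for members at the top of the ranking", {
  diff <- tibble::tibble(
    feature_id = c("CE1", "CE2", "x1", "x2", "x3"),
    genotype = "KO1",
    log2fc = c(5, 4, 3, 2, 1))
  res <- class_rank_test(diff, "KO1", c("CE1", "CE2"))
  expect_equal(res$p_value, 0.1)  # 1 / C(5, 2)
  expect_equal(res$p_value, oracle_rank_skew(c(1, 2), 5))
  expect_equal(res$mean_rank, 1.5)
  expect_equal(res$method, "exact")

  # single member at rank 1 of 10 -> p = 1/10
  diff10 <- tibble::tibble(feature_id = sprintf("f%02d", 1:10),
                           genotype = "KO1", log2fc = 10:1)
  res10 <- class_rank_test(diff10, "KO1", "f01")
  expect_equal(res10$p_value, 0.1)
})

test_that("rank-skew exact p equals enumeration for arbitrary placements", {
  set.seed(63)
  for (i in 1:20) {
    N <- sample(5:12, 1)
    m <- sample(1:3, 1)
    fc <- sample(seq(-3, 3, length.out = N))  # distinct values
    ids <- sprintf("f%02d", 1:N)
    members <- sample(ids, m)
    diff <- tibble::tibble(feature_id = ids, genotype = "g", log2fc = fc)
    res <- class_rank_test(diff, "g", members)
    ranks <- rank(-fc)[ids %in% members]
    expect_equal(res$p_value, oracle_rank_skew(ranks, N), tolerance = 1e-12)
  }
})

test_that("rank-skew normal approximation tracks the reference test on ties", {
  set.seed(64)
  fc <- sample(rep(1:20, each = 3))  # heavy ties, N = 60 forces the switch
  ids <- sprintf("f%02d", seq_along(fc))
  members <- ids[1:12]
  diff <- tibble::tibble(feature_id = ids, genotype = "g", log2fc = fc)
  res <- class_rank_test(diff, "g", members)
  expect_equal(res$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(
    fc[ids %in% members], fc[!ids %in% members],
    alternative = "greater", correct = TRUE, exact = FALSE))
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-10)

  expect_error(class_rank_test(diff, "g", "absent"), "no class member")
})
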