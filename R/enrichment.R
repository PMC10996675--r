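#' Fisher's exact enrichment of clusters against annotation sets
#'
#' One-sided (upper-tail) Fisher's exact test per (cluster, term): with
#' background size `N`, term size `K`, cluster size `n` and overlap `a`, the
#' p-value is the hypergeometric tail `sum_{k >= a} C(K,k) C(N-K,n-k) / C(N,n)`.
#' Annotation sets are restricted to the background before testing, and
#' Benjamini-Hochberg q-values are computed over all tested (cluster, term)
#' pairs of the run.
#'
#' @param clusters A `crossome_clusters` object (or a tibble with
#'   `feature_id`, `cluster`).
#' @param annotations Long annotation tibble (`term_id`, `description`,
#'   `feature_id`).
#' @param background Character vector of feature ids forming the testing
#'   universe; defaults to the clustered features (everything that survived
#'   the connectivity filter on that axis). Must cover all cluster members.
#' @return Tibble with `cluster`, `term_id`, `description`, the 2x2 counts
#'   `a`, `b`, `c`, `d`, `odds_ratio`, `p_value`, `q_value`.
#' @export
fisher_enrich <- function(clusters, annotations, background = NULL) {
  assign_tbl <- if (inherits(clusters, "crossome_clusters")) {
    clusters$assignments
  } else {
    clusters
  }
  if (!all(c("feature_id", "cluster") %in% names(assign_tbl))) {
    abort("`clusters` must provide feature_id and cluster")
  }
  background <- background %||% unique(assign_tbl$feature_id)
  if (length(background) == 0) abort("empty background")
  if (!all(assign_tbl$feature_id %in% background)) {
    abort("background must contain every cluster member")
  }
  ann <- annotations |>
    dplyr::filter(.data$feature_id %in% background) |>
    dplyr::distinct(.data$term_id, .data$description, .data$feature_id)
  if (nrow(ann) == 0) {
    return(tibble::tibble(cluster = integer(), term_id = character(),
                          description = character(), a = integer(),
                          b = integer(), c = integer(), d = integer(),
                          odds_ratio = numeric(), p_value = numeric(),
                          q_value = numeric()))
  }
  N <- length(unique(background))
  terms <- split(ann$feature_id, ann$term_id)
  desc <- ann |> dplyr::distinct(.data$term_id, .data$description)
  members <- split(assign_tbl$feature_id, assign_tbl$cluster)

  grid <- tidyr::expand_grid(cluster = names(members), term_id = names(terms))
  res <- purrr::pmap(grid, function(cluster, term_id) {
    cl <- members[[cluster]]
    tm <- terms[[term_id]]
    a <- length(intersect(cl, tm))
    b <- length(cl) - a
    c_ <- length(tm) - a
    d <- N - a - b - c_
    or <- if (b == 0 || c_ == 0) Inf else (a * d) / (b * c_)
    p <- phyper(a - 1, length(tm), N - length(tm), length(cl),
                lower.tail = FALSE)
    tibble::tibble(cluster = cluster, term_id = term_id,
                   a = a, b = b, c = c_, d = d,
                   odds_ratio = or, p_value = p)
  })
  out <- dplyr::bind_rows(res) |>
    dplyr::left_join(desc, by = "term_id") |>
    dplyr::relocate("description", .after = "term_id") |>
    dplyr::mutate(cluster = utils::type.convert(.data$cluster, as.is = TRUE),
                  q_value = bh_adjust(.data$p_value)) |>
    dplyr::arrange(.data$cluster, .data$p_value)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: `q_i = min_{j >= rank(i)} m p_(j)/j`,
#' capped at 1. Thin validation wrapper over the standard BH adjustment.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Rank-skew test for a feature class
#'
#' Ranks all features of one genotype by log2 fold change (descending, so
#' rank 1 is the most increased) and asks whether a class's members sit
#' toward that upper end: a one-sided Wilcoxon rank-sum test of member ranks
#' against the rest. The exact null distribution is used when
#' `min(group sizes) <= 10`, `N <= 30` and there are no ties; otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param diff Long differential tibble from [log2fc_vs_control()].
#' @param genotype Genotype to test.
#' @param class_members Character vector of member feature ids.
#' @return One-row tibble: `n_members`, `n_other`, `mean_rank` (members' mean
#'   descending rank), `statistic` (Mann-Whitney U toward high skew),
#'   `p_value`, `method`.
#' @export
class_rank_test <- function(diff, genotype, class_members) {
  fc <- diff |>
    dplyr::filter(.data$genotype == !!genotype, !is.na(.data$log2fc))
  if (nrow(fc) == 0) abort(sprintf("no fold changes for genotype '%s'", genotype))
  is_member <- fc$feature_id %in% class_members
  m <- sum(is_member)
  n <- sum(!is_member)
  if (m == 0) abort("no class member has a non-missing fold change")
  if (n == 0) abort("no non-member has a non-missing fold change")

  r_desc <- rank(-fc$log2fc, ties.method = "average")
  N <- m + n
  # members toward the top of the descending ranking <=> large ascending ranks
  r_asc <- N + 1 - r_desc
  u <- sum(r_asc[is_member]) - m * (m + 1) / 2
  has_ties <- any(duplicated(fc$log2fc))

  if (!has_ties && min(m, n) <= 10 && N <= 30) {
    p <- pwilcox(u - 1, m, n, lower.tail = FALSE)
    method <- "exact"
  } else {
    tie_tab <- table(r_desc)
    tie_term <- sum(tie_tab^3 - tie_tab)
    mu <- m * n / 2
    sigma2 <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    p <- if (sigma2 <= 0) 1 else {
      pnorm((u - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
    }
    method <- "normal"
  }
  tibble::tibble(n_members = m, n_other = n,
                 mean_rank = mean(r_desc[is_member]),
                 statistic = u, p_value = min(p, 1), method = method)
}
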