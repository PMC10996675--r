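#' Cluster one axis of the cross-correlation matrix
#'
#' Feature vectors are rows (lipids: tau across retained proteins) or columns
#' (proteins: tau across retained lipids) of the dense tau matrix, with
#' missing tau treated as 0 (the null-association value) for distances only.
#' Hierarchical clustering (average linkage, Euclidean) supplies the heatmap
#' ordering; assignments come from k-means with k-means++ initialisation,
#' taking the best of `restarts` starts by within-cluster sum of squares.
#' Features are put in a canonical (sorted id) order before seeding, so input
#' order cannot change the result.
#'
#' @param cm Long cross-correlation tibble (normally after
#'   [filter_connected()]).
#' @param axis `"protein"` or `"lipid"`.
#' @param k Number of clusters (panel-scale defaults: 18 protein clusters;
#'   13 lipid clusters, with 14 in use for some heatmaps — both one flag away).
#' @param seed Integer seed making assignments reproducible.
#' @param restarts Number of k-means++ starts.
#' @return A `crossome_clusters` object: list with `axis`, `k`, `assignments`
#'   (tibble `feature_id`, `cluster`), `dendrogram_order`, `inertia`, `seed`,
#'   `restarts`.
#' @export
cluster_axis <- function(cm, axis = c("protein", "lipid"), k, seed = 1,
                         restarts = 50) {
  axis <- match.arg(axis)
  if (nrow(cm) == 0) abort("cannot cluster an empty cross-correlation matrix")
  m <- crossome_matrix(cm, fill = 0)
  x <- if (axis == "lipid") m else t(m)
  x <- x[order(rownames(x)), , drop = FALSE]
  fit_feature_clusters(x, axis = axis, k = k, seed = seed, restarts = restarts)
}

#' Group genotypes by signature profiles
#'
#' k-means over per-genotype profile vectors (for example mean log2 fold
#' changes per curated annotation group), the device used to place mutants
#' into genotype groups.
#'
#' @param signatures A genotype-by-variable profile: either a numeric matrix
#'   with genotype rownames or a data frame with a `genotype` column and
#'   numeric profile columns. Missing profile values are treated as 0.
#' @param k Number of genotype groups.
#' @param seed,restarts As in [cluster_axis()].
#' @return A `crossome_clusters` object with `axis = "genotype"`.
#' @export
genotype_groups <- function(signatures, k, seed = 1, restarts = 50) {
  if (is.data.frame(signatures)) {
    if (!"genotype" %in% names(signatures)) {
      abort("`signatures` data frame needs a 'genotype' column")
    }
    m <- as.matrix(signatures[, setdiff(names(signatures), "genotype"),
                              drop = FALSE])
    rownames(m) <- signatures$genotype
  } else {
    m <- as.matrix(signatures)
  }
  if (is.null(rownames(m))) abort("`signatures` must name its genotypes")
  m[is.na(m)] <- 0
  m <- m[order(rownames(m)), , drop = FALSE]
  fit_feature_clusters(m, axis = "genotype", k = k, seed = seed,
                       restarts = restarts)
}

# shared k-means++/hclust engine over a features x variables matrix
fit_feature_clusters <- function(x, axis, k, seed, restarts) {
  k <- stopifnot_scalar_int(k, "k")
  seed <- stopifnot_scalar_int(seed, "seed")
  restarts <- stopifnot_scalar_int(restarts, "restarts")
  n <- nrow(x)
  if (k > n) abort(sprintf("k = %d exceeds the %d features on this axis", k, n))
  if (k < 1) abort("`k` must be >= 1")

  d <- dist(x, method = "euclidean")
  dorder <- if (n > 1) rownames(x)[hclust(d, method = "average")$order]
            else rownames(x)

  fit <- with_local_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(x, k)
      km <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })

  structure(list(
    axis = axis,
    k = k,
    assignments = tibble::tibble(feature_id = rownames(x),
                                 cluster = as.integer(fit$cluster)),
    dendrogram_order = dorder,
    inertia = fit$tot.withinss,
    seed = seed,
    restarts = restarts
  ), class = "crossome_clusters")
}

# k-means++ seeding: first center uniform, then distance^2-weighted draws
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1L)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
    for (i in 2:k) {
      if (all(d2 <= 0)) {
        # fewer distinct points than k: fall back to unused rows
        remaining <- setdiff(seq_len(n), idx[seq_len(i - 1L)])
        idx[i] <- remaining[sample.int(length(remaining), 1L)]
      } else {
        idx[i] <- sample.int(n, 1L, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums((x - matrix(x[idx[i], ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' @export
print.crossome_clusters <- function(x, ...) {
  cat(sprintf("<crossome_clusters> axis=%s k=%d features=%d inertia=%.4g seed=%d\n",
              x$axis, x$k, nrow(x$assignments), x$inertia, x$seed))
  invisible(x)
}

#' Tidy a cluster model into its assignment table
#'
#' @param x A `crossome_clusters` object.
#' @param ... Unused.
#' @return Tibble with `feature_id`, `axis`, `cluster`.
#' @export
tidy.crossome_clusters <- function(x, ...) {
  dplyr::mutate(x$assignments, axis = x$axis, .after = "feature_id")
}

#' One-row summary of a cluster model
#'
#' @param x A `crossome_clusters` object.
#' @param ... Unused.
#' @return Tibble with `axis`, `k`, `n_features`, `inertia`, `seed`.
#' @export
glance.crossome_clusters <- function(x, ...) {
  tibble::tibble(axis = x$axis, k = x$k, n_features = nrow(x$assignments),
                 inertia = x$inertia, seed = x$seed)
}

#' Cluster members as a named list
#'
#' @param model A `crossome_clusters` object.
#' @return Named list, one character vector of feature ids per cluster.
#' @export
cluster_members <- function(model) {
  split(model$assignments$feature_id, model$assignments$cluster)
}
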