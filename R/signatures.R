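#' Per-genotype signature of a feature set
#'
#' Aggregates a member set's log2 fold changes per genotype: `sum` for
#' correlation-derived clusters (a summed cluster signature), `mean` for
#' curated sets (an average module abundance). Missing member cells are
#' excluded; a genotype's value is missing only when no member has a fold
#' change there.
#'
#' @param diff Long differential tibble from [log2fc_vs_control()].
#' @param members Non-empty character vector of member feature ids.
#' @param mode `"sum"` or `"mean"`.
#' @param set_id Label carried into the output.
#' @return Tibble with `set_id`, `genotype`, `value`, `n_members_used`,
#'   `mode`.
#' @export
set_signature <- function(diff, members, mode = c("sum", "mean"),
                          set_id = "set") {
  mode <- match.arg(mode)
  if (length(members) == 0) abort("`members` must be non-empty")
  agg <- if (mode == "sum") sum else mean
  diff |>
    dplyr::filter(.data$feature_id %in% members) |>
    dplyr::group_by(.data$genotype) |>
    dplyr::summarise(
      n_members_used = sum(!is.na(.data$log2fc)),
      value = ifelse(.data$n_members_used > 0,
                     agg(.data$log2fc[!is.na(.data$log2fc)]), NA_real_),
      .groups = "drop") |>
    dplyr::transmute(set_id = set_id, genotype = .data$genotype,
                     value = .data$value,
                     n_members_used = .data$n_members_used, mode = mode)
}

#' Signatures for every cluster of a cluster model
#'
#' @param diff Long differential tibble.
#' @param clusters A `crossome_clusters` object.
#' @param mode Aggregation mode, default `"sum"` (cluster signatures).
#' @return Tibble of [set_signature()] rows, one block per cluster, with
#'   `set_id` like `"cluster_8"`.
#' @export
cluster_signatures <- function(diff, clusters, mode = "sum") {
  members <- cluster_members(clusters)
  purrr::imap(members, function(ids, cl) {
    set_signature(diff, ids, mode = mode,
                  set_id = paste0("cluster_", cl))
  }) |>
    dplyr::bind_rows()
}

#' Signatures for curated annotation sets
#'
#' Applies [set_signature()] independently to every term of an annotation
#' collection (organelle lists, OXPHOS complex modules, and similar curated
#' gene sets).
#'
#' @param diff Long differential tibble.
#' @param curated Long annotation tibble (`term_id`, `feature_id`).
#' @param mode Aggregation mode, default `"mean"` (curated-set signatures).
#' @return Tibble of signature rows, `set_id` = term id.
#' @export
module_signatures <- function(diff, curated, mode = "mean") {
  terms <- split(curated$feature_id, curated$term_id)
  purrr::imap(terms, function(ids, term) {
    set_signature(diff, ids, mode = mode, set_id = term)
  }) |>
    dplyr::bind_rows()
}

#' Genotype-by-set signature matrix
#'
#' @param signatures Signature tibble from [cluster_signatures()] or
#'   [module_signatures()].
#' @return Tibble, one row per genotype, one column per set.
#' @export
signature_profiles <- function(signatures) {
  tidyr::pivot_wider(signatures[, c("set_id", "genotype", "value")],
                     names_from = "set_id", values_from = "value")
}

#' Extract a bipartite lipid-protein network around seed features
#'
#' Keeps every (lipid, protein) correlation touching a seed feature (on
#' either layer) with `|tau|` strictly above the threshold. Nodes appear only
#' when they carry at least one edge.
#'
#' @param cm Long cross-correlation tibble.
#' @param seed_features Character vector of lipid and/or protein ids.
#' @param tau_threshold Absolute tau an edge must strictly exceed.
#' @param clusters Optional named list of `crossome_clusters` (elements
#'   `protein`, `lipid`) used to attach cluster attributes to nodes.
#' @return A `crossome_network` list: `edges` tibble
#'   (`lipid_id`, `protein_id`, `tau`), `nodes` tibble (`feature_id`,
#'   `layer`, `cluster`, `is_seed`), `tau_threshold`.
#' @export
extract_network <- function(cm, seed_features, tau_threshold = 0.4,
                            clusters = NULL) {
  known <- union(cm$lipid_id, cm$protein_id)
  missing_seeds <- setdiff(seed_features, known)
  if (length(seed_features) > 0 && length(missing_seeds) == length(seed_features)) {
    abort("none of the seed features occur in the cross-correlation matrix")
  }
  edges <- cm |>
    dplyr::filter(!is.na(.data$tau), abs(.data$tau) > tau_threshold,
                  .data$lipid_id %in% seed_features |
                    .data$protein_id %in% seed_features) |>
    dplyr::distinct(.data$lipid_id, .data$protein_id, .keep_all = TRUE) |>
    dplyr::select("lipid_id", "protein_id", "tau")
  nodes <- dplyr::bind_rows(
    tibble::tibble(feature_id = unique(edges$lipid_id), layer = "lipid"),
    tibble::tibble(feature_id = unique(edges$protein_id), layer = "protein")
  ) |>
    dplyr::mutate(is_seed = .data$feature_id %in% seed_features,
                  cluster = NA_integer_)
  if (!is.null(clusters)) {
    for (layer in intersect(names(clusters), c("protein", "lipid"))) {
      asg <- clusters[[layer]]$assignments
      hit <- nodes$layer == layer
      nodes$cluster[hit] <-
        asg$cluster[match(nodes$feature_id[hit], asg$feature_id)]
    }
  }
  structure(list(edges = edges, nodes = nodes,
                 tau_threshold = tau_threshold),
            class = "crossome_network")
}

#' @export
print.crossome_network <- function(x, ...) {
  cat(sprintf("<crossome_network> %d edges, %d nodes, |tau| > %.3g\n",
              nrow(x$edges), nrow(x$nodes), x$tau_threshold))
  invisible(x)
}

#' Convert an extracted network to an igraph object
#'
#' @param network A `crossome_network`.
#' @return A bipartite `igraph` graph with `tau` edge weights and `layer`,
#'   `cluster`, `is_seed` vertex attributes.
#' @export
as_igraph <- function(network) {
  g <- igraph::graph_from_data_frame(
    network$edges |>
      dplyr::transmute(from = .data$lipid_id, to = .data$protein_id,
                       tau = .data$tau),
    directed = FALSE,
    vertices = network$nodes |>
      dplyr::transmute(name = .data$feature_id, layer = .data$layer,
                       cluster = .data$cluster, is_seed = .data$is_seed))
  igraph::V(g)$type <- igraph::V(g)$layer == "protein"
  g
}

#' Write a network as edge-list TSV and GraphML
#'
#' @param network A `crossome_network`.
#' @param edge_path TSV path for the edge list.
#' @param graphml_path Optional GraphML path.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(network, edge_path, graphml_path = NULL) {
  readr::write_tsv(network$edges, edge_path, progress = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(network), graphml_path, format = "graphml")
  }
  invisible(edge_path)
}

#' Frequency of top correlated partners across a lipid subset
#'
#' For each lipid, takes its `n_top` proteins with highest tau (descending
#' tau, ties broken by protein id), counts how often each protein recurs
#' across the lipids, and optionally aggregates the counts by a category
#' label (e.g. receptor families).
#'
#' @param cm Long cross-correlation tibble.
#' @param lipid_subset Lipid ids to scan; defaults to all lipids in `cm`.
#' @param n_top Partners taken per lipid (the "top 10" of the resource
#'   analysis).
#' @param categories Optional named character vector mapping protein id to a
#'   category label; unmapped proteins get `"other"`.
#' @return Tibble `protein_id`, `category`, `frequency`, sorted by
#'   frequency; a `"category_counts"` attribute holds the per-category sums.
#' @export
top_partner_frequency <- function(cm, lipid_subset = NULL, n_top = 10,
                                  categories = NULL) {
  n_top <- stopifnot_scalar_int(n_top, "n_top")
  if (n_top < 1) abort("`n_top` must be >= 1")
  lipid_subset <- lipid_subset %||% unique(cm$lipid_id)
  sub <- cm |>
    dplyr::filter(.data$lipid_id %in% lipid_subset, !is.na(.data$tau))
  short <- sub |>
    dplyr::count(.data$lipid_id) |>
    dplyr::filter(.data$n < n_top)
  if (nrow(short) > 0) {
    warn(sprintf("%d lipid(s) have fewer than %d non-missing partners; taking all available",
                 nrow(short), n_top))
  }
  top <- sub |>
    dplyr::group_by(.data$lipid_id) |>
    dplyr::arrange(dplyr::desc(.data$tau), .data$protein_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = n_top) |>
    dplyr::ungroup()
  out <- top |>
    dplyr::count(.data$protein_id, name = "frequency") |>
    dplyr::mutate(category = if (is.null(categories)) "other" else
      dplyr::coalesce(unname(categories[.data$protein_id]), "other")) |>
    dplyr::relocate("category", .after = "protein_id") |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$protein_id)
  attr(out, "category_counts") <- out |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(count = sum(.data$frequency), .groups = "drop")
  out
}

#' Genotype outlier analysis on fold-change profiles
#'
#' For each feature, computes a robust z-score per genotype,
#' `z = (log2fc - median) / (1.4826 MAD + eps)` over that feature's genotype
#' values (falling back to the sample SD when the MAD is 0), and flags
#' genotypes with `|z| >= z_cutoff`. For every genotype with at least one
#' flag, the remaining genotypes are ranked by Pearson correlation over the
#' flagged feature vector, answering "which other genotypes show a similar
#' pattern".
#'
#' @param diff Long differential tibble.
#' @param feature_ids Features to test; defaults to all features in `diff`.
#' @param z_cutoff Robust z magnitude at which a genotype is flagged.
#' @param min_genotypes Minimum non-missing genotype values per feature;
#'   features below it are skipped with a warning.
#' @return A `crossome_outliers` list: `scores` tibble (`feature_id`,
#'   `genotype`, `log2fc`, `robust_z`, `flagged`), `similar` tibble
#'   (`genotype`, `other`, `similarity`, `n_features`), and the parameters.
#' @export
outlier_analysis <- function(diff, feature_ids = NULL, z_cutoff = 2.5,
                             min_genotypes = 10) {
  feature_ids <- feature_ids %||% unique(diff$feature_id)
  min_genotypes <- stopifnot_scalar_int(min_genotypes, "min_genotypes")
  eps <- 1e-9
  sub <- diff |>
    dplyr::filter(.data$feature_id %in% feature_ids)
  counts <- sub |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(n_ok = sum(!is.na(.data$log2fc)), .groups = "drop")
  skipped <- counts$feature_id[counts$n_ok < min_genotypes]
  if (length(skipped) > 0) {
    warn(sprintf("%d feature(s) skipped: fewer than %d genotype values",
                 length(skipped), min_genotypes))
  }
  scores <- sub |>
    dplyr::filter(!.data$feature_id %in% skipped) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::mutate(robust_z = {
      v <- .data$log2fc
      med <- median(v, na.rm = TRUE)
      scale <- mad(v, na.rm = TRUE)  # already 1.4826-scaled
      if (!is.na(scale) && scale == 0) scale <- sd(v, na.rm = TRUE)
      (v - med) / (scale + eps)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(flagged = !is.na(.data$robust_z) &
                    abs(.data$robust_z) >= z_cutoff) |>
    dplyr::select("feature_id", "genotype", "log2fc", "robust_z", "flagged")

  flagged_genos <- unique(scores$genotype[scores$flagged])
  fc_wide <- tidyr::pivot_wider(scores[, c("feature_id", "genotype", "log2fc")],
                                names_from = "genotype",
                                values_from = "log2fc")
  similar <- purrr::map(flagged_genos, function(g) {
    feats <- scores$feature_id[scores$flagged & scores$genotype == g]
    block <- fc_wide[fc_wide$feature_id %in% feats, , drop = FALSE]
    others <- setdiff(names(block)[-1], g)
    sims <- vapply(others, function(o) {
      ok <- !is.na(block[[g]]) & !is.na(block[[o]])
      if (sum(ok) < 2 || sd(block[[g]][ok]) == 0 || sd(block[[o]][ok]) == 0) {
        return(NA_real_)
      }
      cor(block[[g]][ok], block[[o]][ok])
    }, numeric(1))
    tibble::tibble(genotype = g, other = others, similarity = unname(sims),
                   n_features = nrow(block)) |>
      dplyr::arrange(dplyr::desc(.data$similarity))
  }) |>
    dplyr::bind_rows()

  structure(list(scores = scores, similar = similar, z_cutoff = z_cutoff,
                 min_genotypes = min_genotypes, skipped = skipped),
            class = "crossome_outliers")
}

#' @export
print.crossome_outliers <- function(x, ...) {
  cat(sprintf("<crossome_outliers> %d score(s), %d flagged, cutoff %.3g\n",
              nrow(x$scores), sum(x$scores$flagged), x$z_cutoff))
  invisible(x)
}

#' Tidy an outlier report
#'
#' @param x A `crossome_outliers` object.
#' @param ... Unused.
#' @return The per-(feature, genotype) score tibble.
#' @export
tidy.crossome_outliers <- function(x, ...) x$scores
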