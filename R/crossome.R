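#' Kendall tau-b between two numeric vectors
#'
#' Tie-corrected rank correlation on pairwise-complete observations:
#' `tau_b = (C - D) / sqrt((n0 - n1) (n0 - n2))` with `n0 = n (n - 1) / 2`
#' and `n1`, `n2` the tie terms of `x` and `y`. Pairs where either value is
#' missing are dropped first. Returns a missing tau when fewer than two
#' complete pairs remain or either vector is constant over them.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `tau` and `n` (the number of complete pairs used).
#' @export
#' @examples
#' kendall_tau_b(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4))$tau  # 0.4
kendall_tau_b <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have the same length")
  res <- .kendall_tau_b_cpp(as.numeric(x), as.numeric(y))
  list(tau = res$tau, n = as.integer(res$n))
}

#' Lipid-by-protein Kendall cross-correlation matrix
#'
#' Computes tau-b for every (lipid, protein) pair across the panel. With
#' `mode = "replicate_level"` (default) profiles are the per-sample values;
#' with `mode = "genotype_mean"` each feature is first collapsed to its
#' per-genotype mean (control included) and tau is computed over genotypes.
#' Cells whose pairwise-complete overlap falls below `min_overlap` are
#' reported missing.
#'
#' @param protein,lipid Omics tibbles aligned on the same samples
#'   (see [align_layers()]).
#' @param meta Sample metadata; required for `mode = "genotype_mean"`.
#' @param mode Correlation axis, `"replicate_level"` or `"genotype_mean"`.
#' @param min_overlap Minimum usable pairs per tau cell.
#' @return A long tibble with columns `lipid_id`, `protein_id`, `tau`,
#'   `n_pairs`, carrying `"profile_mode"` and `"min_overlap"` attributes.
#'   `tau` is `NA` where the overlap was insufficient.
#' @export
cross_correlate <- function(protein, lipid, meta = NULL,
                            mode = c("replicate_level", "genotype_mean"),
                            min_overlap = 12) {
  mode <- match.arg(mode)
  validate_omics(protein)
  validate_omics(lipid)
  ps <- setdiff(names(protein), "feature_id")
  ls_ <- setdiff(names(lipid), "feature_id")
  if (!identical(sort(ps), sort(ls_))) {
    abort("protein and lipid layers must share the same sample set; run align_layers() first")
  }
  min_overlap <- stopifnot_scalar_int(min_overlap, "min_overlap")

  pm <- omics_values(protein)[, ps, drop = FALSE]
  lm_ <- omics_values(lipid)[, ps, drop = FALSE]
  if (mode == "genotype_mean") {
    if (is.null(meta)) abort("`meta` is required for mode = 'genotype_mean'")
    meta <- validate_metadata(meta, control = attr(meta, "control") %||% "control")
    pm <- genotype_means(pm, meta)
    lm_ <- genotype_means(lm_, meta)
  }
  n_profiles <- ncol(pm)
  if (n_profiles < min_overlap) {
    abort(sprintf("only %d shared profile(s); min_overlap is %d",
                  n_profiles, min_overlap))
  }

  res <- .cross_kendall_cpp(t(lm_), t(pm))  # lipids x proteins
  tau <- res$tau
  npairs <- res$n_pairs
  tau[npairs < min_overlap] <- NA_real_

  out <- tibble::tibble(
    lipid_id = rep(rownames(lm_), times = nrow(pm)),
    protein_id = rep(rownames(pm), each = nrow(lm_)),
    tau = as.vector(tau),
    n_pairs = as.vector(npairs)
  )
  attr(out, "profile_mode") <- mode
  attr(out, "min_overlap") <- min_overlap
  out
}

# collapse a features x samples matrix to features x genotypes means
genotype_means <- function(m, meta) {
  geno <- meta$genotype[match(colnames(m), meta$sample_id)]
  keep <- !is.na(geno)
  m <- m[, keep, drop = FALSE]
  geno <- geno[keep]
  groups <- unique(geno)
  out <- vapply(groups, function(g) {
    rowMeans(m[, geno == g, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(m)))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- groups
  rownames(out) <- rownames(m)
  out
}

#' Connectivity retention filter
#'
#' Retains a lipid (and, independently, a protein) only if it has at least
#' `min_partners` correlations with `|tau|` strictly above `tau_threshold`,
#' counted in a single pass against the full pre-filter matrix; the returned
#' matrix is the full matrix restricted to the retained rows and columns.
#' Missing tau cells never count as partners.
#'
#' @param cm Long cross-correlation tibble from [cross_correlate()].
#' @param tau_threshold Absolute tau that a partner must strictly exceed.
#' @param min_partners Minimum number of qualifying partners.
#' @return The filtered long tibble (same columns and attributes), plus
#'   `"retained_lipids"` and `"retained_proteins"` attributes.
#' @export
filter_connected <- function(cm, tau_threshold = 0.4, min_partners = 2) {
  if (!is.numeric(tau_threshold) || tau_threshold <= 0 || tau_threshold >= 1) {
    abort("`tau_threshold` must be in (0, 1)")
  }
  min_partners <- stopifnot_scalar_int(min_partners, "min_partners")
  if (min_partners < 1) abort("`min_partners` must be >= 1")

  strong <- dplyr::filter(cm, !is.na(.data$tau),
                          abs(.data$tau) > tau_threshold)
  keep_lipids <- strong |>
    dplyr::count(.data$lipid_id) |>
    dplyr::filter(.data$n >= min_partners) |>
    dplyr::pull("lipid_id")
  keep_proteins <- strong |>
    dplyr::count(.data$protein_id) |>
    dplyr::filter(.data$n >= min_partners) |>
    dplyr::pull("protein_id")
  if (length(keep_lipids) == 0 && length(keep_proteins) == 0) {
    warn("connectivity filter retained nothing")
  }
  out <- dplyr::filter(cm, .data$lipid_id %in% keep_lipids,
                       .data$protein_id %in% keep_proteins)
  attr(out, "profile_mode") <- attr(cm, "profile_mode")
  attr(out, "min_overlap") <- attr(cm, "min_overlap")
  attr(out, "tau_threshold") <- tau_threshold
  attr(out, "min_partners") <- min_partners
  attr(out, "retained_lipids") <- sort(keep_lipids)
  attr(out, "retained_proteins") <- sort(keep_proteins)
  out
}

#' Dense tau matrix from the long form
#'
#' @param cm Long cross-correlation tibble.
#' @param fill Value substituted for missing tau cells (default keeps `NA`).
#' @return Numeric matrix, lipids in rows, proteins in columns.
#' @export
crossome_matrix <- function(cm, fill = NA_real_) {
  lipids <- sort(unique(cm$lipid_id))
  proteins <- sort(unique(cm$protein_id))
  m <- matrix(fill, nrow = length(lipids), ncol = length(proteins),
              dimnames = list(lipids, proteins))
  m[cbind(match(cm$lipid_id, lipids), match(cm$protein_id, proteins))] <-
    ifelse(is.na(cm$tau), fill, cm$tau)
  m
}
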