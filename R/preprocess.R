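#' Median-center each sample column
#'
#' Subtracts every sample's median (over its non-missing values) from that
#' column, putting all samples on a common location without touching
#' missingness. Used before cross-correlation when layers were acquired with
#' uneven loading.
#'
#' @param x Omics tibble.
#' @return The centered omics tibble.
#' @export
median_center <- function(x) {
  validate_omics(x)
  samp <- setdiff(names(x), "feature_id")
  empty <- samp[vapply(x[samp], function(v) all(is.na(v)), logical(1))]
  if (length(empty) > 0) {
    abort(sprintf("sample(s) with no quantified values: %s",
                  paste(empty, collapse = ", ")))
  }
  out <- dplyr::mutate(x, dplyr::across(
    -"feature_id", ~ .x - median(.x, na.rm = TRUE)))
  attr(out, "layer") <- attr(x, "layer")
  out
}

#' Filter features on detection rate
#'
#' Retains features quantified (non-missing) in at least `min_fraction` of the
#' samples. Rank correlations on pairwise-complete data degrade badly once a
#' feature is mostly missing, so the cross-correlation step expects a
#' detection-filtered matrix.
#'
#' @param x Omics tibble.
#' @param min_fraction Minimum fraction of samples with a value, in (0, 1].
#' @return The filtered omics tibble.
#' @export
detection_filter <- function(x, min_fraction = 0.5) {
  validate_omics(x)
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort("`min_fraction` must be in (0, 1]")
  }
  samp <- setdiff(names(x), "feature_id")
  frac <- rowMeans(!is.na(omics_values(x)))
  out <- x[frac >= min_fraction, , drop = FALSE]
  attr(out, "layer") <- attr(x, "layer")
  out
}

#' Per-genotype log2 fold changes versus control
#'
#' For every feature and mutant genotype, the mean over that genotype's
#' non-missing replicate values minus the mean over the control's non-missing
#' values (both already on log2 scale, so the difference is a log2 fold
#' change, KO/control). A cell is reported missing when either side has fewer
#' than `min_reps` quantified replicates.
#'
#' @param x Omics tibble.
#' @param meta Sample metadata; its `"control"` attribute (or `control`)
#'   designates the reference genotype.
#' @param min_reps Minimum quantified replicates required on each side.
#' @param control Control genotype label.
#' @return A long tibble with columns `feature_id`, `genotype`, `log2fc`,
#'   `n_case`, `n_control`; control rows are excluded.
#' @export
log2fc_vs_control <- function(x, meta, min_reps = 2,
                              control = attr(meta, "control") %||% "control") {
  validate_omics(x)
  meta <- validate_metadata(meta, control = control)
  min_reps <- stopifnot_scalar_int(min_reps, "min_reps")
  if (min_reps < 1) abort("`min_reps` must be >= 1")

  vals <- omics_values(x)
  vals <- vals[, intersect(colnames(vals), meta$sample_id), drop = FALSE]
  geno <- meta$genotype[match(colnames(vals), meta$sample_id)]

  ctrl_cols <- which(geno == control)
  ctrl_mean <- rowMeans(vals[, ctrl_cols, drop = FALSE], na.rm = TRUE)
  ctrl_n <- rowSums(!is.na(vals[, ctrl_cols, drop = FALSE]))
  if (any(ctrl_n == 0)) {
    warn(sprintf("%d feature(s) have no control quantification; their rows are all-missing",
                 sum(ctrl_n == 0)))
  }

  mutants <- setdiff(unique(geno), control)
  rows <- purrr::map(mutants, function(g) {
    cols <- which(geno == g)
    case_mean <- rowMeans(vals[, cols, drop = FALSE], na.rm = TRUE)
    case_n <- rowSums(!is.na(vals[, cols, drop = FALSE]))
    ok <- case_n >= min_reps & ctrl_n >= min_reps
    tibble::tibble(
      feature_id = rownames(vals),
      genotype = g,
      log2fc = unname(ifelse(ok, case_mean - ctrl_mean, NA_real_)),
      n_case = unname(as.integer(case_n)),
      n_control = unname(as.integer(ctrl_n))
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "layer") <- attr(x, "layer")
  attr(out, "control") <- control
  out
}

#' Pivot a long differential table to a features-by-genotypes matrix
#'
#' @param diff Long tibble from [log2fc_vs_control()].
#' @return Numeric matrix, features in rows, genotypes in columns.
#' @export
diff_matrix <- function(diff) {
  wide <- tidyr::pivot_wider(diff[, c("feature_id", "genotype", "log2fc")],
                             names_from = "genotype", values_from = "log2fc")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$feature_id
  m
}
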