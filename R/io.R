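#' Read an abundance matrix
#'
#' Reads a delimited features-by-samples table of log2-scale abundances. The
#' first column must be named `feature_id`; remaining columns are samples.
#' Empty cells and the strings in `na` denote missing values.
#'
#' @param path Path to a TSV file.
#' @param layer Omic layer the matrix holds, `"protein"` or `"lipid"`.
#' @param log2_transform If `TRUE`, values are raw positive intensities and
#'   `log2()` is applied on read; non-positive raw values become missing.
#' @param na Strings treated as missing in addition to empty cells.
#'
#' @return A tibble with a `feature_id` column and one numeric column per
#'   sample, carrying a `"layer"` attribute.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2", "P1\t1.5\t2.5", "P2\t\t3.0"), tf)
#' read_omics(tf, layer = "protein")
read_omics <- function(path, layer = c("protein", "lipid"),
                       log2_transform = FALSE, na = c("", "NA")) {
  layer <- match.arg(layer)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "feature_id") {
    abort(sprintf("malformed header in %s: first column must be 'feature_id'",
                  path))
  }
  sample_ids <- header[-1]
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample id(s) in header of %s: %s",
                  path, paste(dup, collapse = ", ")))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE,
                         name_repair = "minimal")
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate feature id(s) in %s: %s",
                  path, paste(dup, collapse = ", ")))
  }
  vals <- lapply(seq_along(sample_ids), function(j) {
    cell <- raw[[j + 1L]]
    miss <- is.na(cell) | cell %in% na
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!miss & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric value '%s' at row %d (feature '%s'), column '%s' of %s",
        cell[bad[1]], bad[1], ids[bad[1]], sample_ids[j], path))
    }
    num[miss] <- NA_real_
    num
  })
  names(vals) <- sample_ids
  out <- tibble::tibble(feature_id = ids, !!!vals)
  if (log2_transform) {
    safe_log2 <- function(v) {
      res <- rep(NA_real_, length(v))
      pos <- !is.na(v) & v > 0
      res[pos] <- log2(v[pos])
      res
    }
    out <- dplyr::mutate(out, dplyr::across(-"feature_id", safe_log2))
  }
  validate_omics(out)
  attr(out, "layer") <- layer
  out
}

#' Write an abundance matrix
#'
#' Missing values are written as empty cells.
#'
#' @param x Omics tibble (`feature_id` plus numeric sample columns).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_omics <- function(x, path) {
  validate_omics(x)
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

validate_omics <- function(x) {
  if (!is.data.frame(x) || !"feature_id" %in% names(x)) {
    abort("an omics table needs a 'feature_id' column")
  }
  dup <- unique(x$feature_id[duplicated(x$feature_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate feature id(s): %s", paste(dup, collapse = ", ")))
  }
  samp <- setdiff(names(x), "feature_id")
  dup <- unique(samp[duplicated(samp)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample id(s): %s", paste(dup, collapse = ", ")))
  }
  num <- vapply(x[samp], is.numeric, logical(1))
  if (!all(num)) {
    abort(sprintf("non-numeric sample column(s): %s",
                  paste(samp[!num], collapse = ", ")))
  }
  bad <- vapply(x[samp], function(v) any(!is.na(v) & !is.finite(v)), logical(1))
  if (any(bad)) {
    abort(sprintf("non-finite values in sample column(s): %s",
                  paste(samp[bad], collapse = ", ")))
  }
  invisible(x)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `genotype`, `replicate` and
#'   optionally `batch`.
#' @param control Genotype label designating the control group.
#' @return A tibble with one row per sample and a `"control"` attribute.
#' @export
read_metadata <- function(path, control = "control") {
  meta <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = "c", genotype = "c", replicate = "i", .default = "c"),
    progress = FALSE)
  validate_metadata(meta, control = control)
}

#' Validate sample metadata
#'
#' @param meta Data frame with `sample_id`, `genotype`, `replicate`.
#' @param control Control genotype label; must be present in `genotype`.
#' @return The validated tibble with a `"control"` attribute.
#' @export
validate_metadata <- function(meta, control = "control") {
  need <- c("sample_id", "genotype", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(sprintf("metadata missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample id(s) in metadata: %s",
                  paste(dup, collapse = ", ")))
  }
  if (any(is.na(meta$replicate)) || any(meta$replicate < 1)) {
    abort("metadata 'replicate' must be a positive integer")
  }
  if (!control %in% meta$genotype) {
    abort(sprintf("control genotype '%s' absent from metadata", control))
  }
  meta <- tibble::as_tibble(meta)
  attr(meta, "control") <- control
  meta
}

#' Read annotation sets (GMT)
#'
#' One term per line: term id, description, then member feature ids, all
#' tab-separated. Members are deduplicated within a term.
#'
#' @param path GMT file path.
#' @param layer Layer the sets annotate (`"protein"` or `"lipid"`).
#' @return A long tibble with columns `term_id`, `description`, `feature_id`.
#' @export
read_gmt <- function(path, layer = c("protein", "lipid")) {
  layer <- match.arg(layer)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble::tibble(term_id = character(), description = character(),
                          feature_id = character())
    attr(out, "layer") <- layer
    return(out)
  }
  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has %d field(s); need term, description, >=1 member",
                    i, length(fields)))
    }
    tibble::tibble(term_id = fields[1], description = fields[2],
                   feature_id = unique(fields[-(1:2)]))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "layer") <- layer
  out
}

#' Write annotation sets (GMT)
#'
#' @param sets Long annotation tibble (`term_id`, `description`, `feature_id`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- sets |>
    dplyr::group_by(.data$term_id, .data$description) |>
    dplyr::summarise(members = paste(unique(.data$feature_id), collapse = "\t"),
                     .groups = "drop") |>
    dplyr::mutate(line = paste(.data$term_id, .data$description,
                               .data$members, sep = "\t"))
  writeLines(lines$line, path)
  invisible(path)
}

#' Align the two omic layers on a shared sample set
#'
#' Restricts both matrices to the samples present in the metadata (and in both
#' layers), in a canonical order sorted by (genotype, replicate). Dropped
#' samples are reported with a message.
#'
#' @param protein,lipid Omics tibbles sharing sample columns.
#' @param meta Sample metadata (see [validate_metadata()]).
#' @return A list with elements `protein`, `lipid`, `meta` (class
#'   `"omics_study"`), all restricted to the shared samples.
#' @export
align_layers <- function(protein, lipid, meta) {
  validate_omics(protein)
  validate_omics(lipid)
  meta <- validate_metadata(meta, control = attr(meta, "control") %||% "control")
  shared <- intersect(intersect(setdiff(names(protein), "feature_id"),
                                setdiff(names(lipid), "feature_id")),
                      meta$sample_id)
  if (length(shared) == 0) {
    abort("no samples shared between the two layers and the metadata")
  }
  all_seen <- union(union(setdiff(names(protein), "feature_id"),
                          setdiff(names(lipid), "feature_id")),
                    meta$sample_id)
  dropped <- setdiff(all_seen, shared)
  if (length(dropped) > 0) {
    inform(sprintf("align_layers: dropping %d sample(s) not shared by all inputs: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  meta <- meta |>
    dplyr::filter(.data$sample_id %in% shared) |>
    dplyr::arrange(.data$genotype, .data$replicate, .data$sample_id)
  ord <- meta$sample_id
  res <- list(
    protein = protein[, c("feature_id", ord)],
    lipid = lipid[, c("feature_id", ord)],
    meta = meta
  )
  attr(res$protein, "layer") <- "protein"
  attr(res$lipid, "layer") <- "lipid"
  structure(res, class = "omics_study")
}

#' @export
print.omics_study <- function(x, ...) {
  cat(sprintf("<omics_study> %d proteins x %d lipids x %d samples (%d genotypes)\n",
              nrow(x$protein), nrow(x$lipid), nrow(x$meta),
              dplyr::n_distinct(x$meta$genotype)))
  invisible(x)
}

# wide omics tibble -> numeric matrix (features x samples)
omics_values <- function(x) {
  m <- as.matrix(x[, setdiff(names(x), "feature_id"), drop = FALSE])
  rownames(m) <- x$feature_id
  storage.mode(m) <- "double"
  m
}

# numeric matrix (features x samples) -> wide omics tibble
omics_from_values <- function(m, layer = NULL) {
  out <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  out <- tibble::tibble(feature_id = rownames(m), !!!out)
  if (!is.null(layer)) attr(out, "layer") <- layer
  out
}
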