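#' Default pipeline configuration
#'
#' Flat key/value configuration for [run_pipeline()]. Path entries name the
#' input files; the remaining keys are stage parameters with the package
#' defaults: connectivity filter at `|tau| > 0.4` with at least 2 partners,
#' 18 protein and 13 lipid clusters, sum signatures for clusters, robust-z
#' outlier cutoff 2.5.
#'
#' @param protein,lipid,metadata Input TSV paths.
#' @param annotations_protein Optional GMT path for protein annotation sets.
#' @param annotations_lipid Optional GMT path; when absent, lipid-class sets
#'   are derived from the lipid names via [lipid_class_sets()].
#' @param out_dir Output directory.
#' @param ... Overrides for any default parameter.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(protein, lipid, metadata, out_dir,
                       annotations_protein = NULL, annotations_lipid = NULL,
                       ...) {
  cfg <- list(
    protein = protein, lipid = lipid, metadata = metadata,
    annotations_protein = annotations_protein,
    annotations_lipid = annotations_lipid,
    out_dir = out_dir,
    control = "control",
    log2_transform = FALSE,
    median_center = FALSE,
    detection_min_fraction = 0.5,
    min_reps = 2,
    profile_mode = "replicate_level",
    min_overlap = 12,
    tau_threshold = 0.4,
    min_partners = 2,
    k_protein = 18,
    k_lipid = 13,
    cluster_seed = 1,
    restarts = 50,
    cluster_signature_mode = "sum",
    top_n = 10,
    outlier_z_cutoff = 2.5,
    outlier_min_genotypes = 10,
    do_enrichment = TRUE,
    do_signatures = TRUE,
    do_outliers = TRUE,
    do_top_partners = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of flat key/value pairs; keys as in [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  vals <- yaml::yaml.load_file(path)
  need <- c("protein", "lipid", "metadata", "out_dir")
  missing_keys <- setdiff(need, names(vals))
  if (length(missing_keys) > 0) {
    abort(sprintf("config missing required key(s): %s",
                  paste(missing_keys, collapse = ", ")))
  }
  do.call(run_config, vals)
}

validate_run_config <- function(cfg) {
  for (key in c("protein", "lipid", "metadata",
                "annotations_protein", "annotations_lipid")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("config error: %s file not found: %s", key, p),
            class = "run_config_error")
    }
  }
  invisible(cfg)
}

#' Run the full cross-ome fingerprinting pipeline
#'
#' Stages, in order: read and align the two layers; detection-filter and
#' (optionally) median-center; per-genotype log2 fold changes; Kendall
#' cross-correlation; connectivity filter; dual-axis clustering; Fisher
#' enrichment (GO-style sets for proteins, lipid classes for lipids);
#' cluster signatures; top-partner frequencies; outlier analysis. Every
#' output is a TSV under `out_dir`, and `provenance.json` echoes every
#' parameter. Reruns with identical config produce byte-identical TSVs.
#'
#' @param cfg A `run_config` (or YAML path).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  stage <- "read"
  res <- list()
  tryCatch({
    protein <- read_omics(cfg$protein, "protein",
                          log2_transform = cfg$log2_transform)
    lipid <- read_omics(cfg$lipid, "lipid",
                        log2_transform = cfg$log2_transform)
    meta <- read_metadata(cfg$metadata, control = cfg$control)
    study <- align_layers(protein, lipid, meta)

    stage <- "preprocess"
    prep <- function(x) {
      x <- detection_filter(x, cfg$detection_min_fraction)
      if (isTRUE(cfg$median_center)) x <- median_center(x)
      x
    }
    protein <- prep(study$protein)
    lipid <- prep(study$lipid)
    diff_p <- log2fc_vs_control(protein, study$meta, min_reps = cfg$min_reps,
                                control = cfg$control)
    diff_l <- log2fc_vs_control(lipid, study$meta, min_reps = cfg$min_reps,
                                control = cfg$control)
    readr::write_tsv(diff_p, out("log2fc_protein.tsv"), progress = FALSE)
    readr::write_tsv(diff_l, out("log2fc_lipid.tsv"), progress = FALSE)

    stage <- "correlate"
    cm <- cross_correlate(protein, lipid, study$meta,
                          mode = cfg$profile_mode,
                          min_overlap = cfg$min_overlap)
    readr::write_tsv(cm, out("crossome.tsv"), progress = FALSE)

    stage <- "filter"
    cmf <- filter_connected(cm, tau_threshold = cfg$tau_threshold,
                            min_partners = cfg$min_partners)
    readr::write_tsv(cmf, out("crossome_filtered.tsv"), progress = FALSE)

    stage <- "cluster"
    n_prot <- length(unique(cmf$protein_id))
    n_lip <- length(unique(cmf$lipid_id))
    clus_p <- cluster_axis(cmf, "protein", k = min(cfg$k_protein, n_prot),
                           seed = cfg$cluster_seed, restarts = cfg$restarts)
    clus_l <- cluster_axis(cmf, "lipid", k = min(cfg$k_lipid, n_lip),
                           seed = cfg$cluster_seed, restarts = cfg$restarts)
    readr::write_tsv(dplyr::bind_rows(tidy(clus_p), tidy(clus_l)),
                     out("clusters.tsv"), progress = FALSE)
    readr::write_tsv(dplyr::bind_rows(
      tibble::tibble(axis = "protein", position = seq_along(clus_p$dendrogram_order),
                     feature_id = clus_p$dendrogram_order),
      tibble::tibble(axis = "lipid", position = seq_along(clus_l$dendrogram_order),
                     feature_id = clus_l$dendrogram_order)),
      out("dendrogram_order.tsv"), progress = FALSE)

    stage <- "enrich"
    enr_p <- enr_l <- NULL
    if (isTRUE(cfg$do_enrichment)) {
      ann_p <- if (!is.null(cfg$annotations_protein)) {
        read_gmt(cfg$annotations_protein, "protein")
      }
      ann_l <- if (!is.null(cfg$annotations_lipid)) {
        read_gmt(cfg$annotations_lipid, "lipid")
      } else {
        # ids that are not shorthand names all land in "unclassified"
        withCallingHandlers(lipid_class_sets(unique(cmf$lipid_id)),
                            warning = function(w) invokeRestart("muffleWarning"))
      }
      if (!is.null(ann_p)) {
        enr_p <- fisher_enrich(clus_p, ann_p)
        readr::write_tsv(enr_p, out("enrichment_protein.tsv"), progress = FALSE)
      }
      if (!is.null(ann_l) && nrow(ann_l) > 0) {
        enr_l <- fisher_enrich(clus_l, ann_l)
        readr::write_tsv(enr_l, out("enrichment_lipid.tsv"), progress = FALSE)
      }
    }

    stage <- "signatures"
    if (isTRUE(cfg$do_signatures)) {
      sigs <- dplyr::bind_rows(
        dplyr::mutate(cluster_signatures(diff_p, clus_p,
                                         mode = cfg$cluster_signature_mode),
                      layer = "protein"),
        dplyr::mutate(cluster_signatures(diff_l, clus_l,
                                         mode = cfg$cluster_signature_mode),
                      layer = "lipid"))
      readr::write_tsv(sigs, out("signatures.tsv"), progress = FALSE)
      res$signatures <- sigs
    }

    stage <- "top_partners"
    if (isTRUE(cfg$do_top_partners)) {
      top <- withCallingHandlers(
        top_partner_frequency(cmf, n_top = cfg$top_n),
        warning = function(w) invokeRestart("muffleWarning"))
      readr::write_tsv(top, out("top_partners.tsv"), progress = FALSE)
      res$top_partners <- top
    }

    stage <- "outliers"
    if (isTRUE(cfg$do_outliers)) {
      outl <- withCallingHandlers(
        outlier_analysis(dplyr::bind_rows(
          dplyr::mutate(diff_p, layer = "protein"),
          dplyr::mutate(diff_l, layer = "lipid")),
          z_cutoff = cfg$outlier_z_cutoff,
          min_genotypes = cfg$outlier_min_genotypes),
        warning = function(w) invokeRestart("muffleWarning"))
      readr::write_tsv(outl$scores, out("outliers.tsv"), progress = FALSE)
      res$outliers <- outl
    }

    stage <- "provenance"
    prov <- unclass(cfg)
    prov$package_version <- as.character(utils::packageVersion("crossome"))
    prov$n_samples <- nrow(study$meta)
    prov$n_proteins <- nrow(protein)
    prov$n_lipids <- nrow(lipid)
    prov$n_proteins_retained <- n_prot
    prov$n_lipids_retained <- n_lip
    jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")

    res <- c(list(study = study, diff_protein = diff_p, diff_lipid = diff_l,
                  crossome = cm, crossome_filtered = cmf,
                  clusters_protein = clus_p, clusters_lipid = clus_l,
                  enrichment_protein = enr_p, enrichment_lipid = enr_l),
             res)
    invisible(res)
  }, error = function(e) {
    writeLines(sprintf("FAILED at stage '%s': %s", stage,
                       conditionMessage(e)),
               out("FAILED"))
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)), parent = e)
  })
}

#' Write a simulated panel to disk in pipeline input formats
#'
#' @param panel List from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_omics(panel$protein, file.path(dir, "protein.tsv"))
  write_omics(panel$lipid, file.path(dir, "lipid.tsv"))
  readr::write_tsv(panel$meta, file.path(dir, "metadata.tsv"),
                   progress = FALSE)
  write_gmt(panel$annotations$protein, file.path(dir, "annotations_protein.gmt"))
  write_gmt(panel$annotations$lipid, file.path(dir, "annotations_lipid.gmt"))
  truth <- panel$truth
  jsonlite::write_json(
    list(modules = truth$modules, affected = truth$affected,
         effect_size = truth$effect_size),
    file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
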