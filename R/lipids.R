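#' Parse lipid shorthand names
#'
#' Parses compact lipid names of the form `CLASS[qualifier] [prefix-]C:D[_C:D...]`
#' into structured descriptors: lipid class (bracket qualifiers such as
#' `Cer[NS]` stay part of the class), total chain carbons, total double bonds,
#' ether linkage (`O-` plasmanyl, `P-` plasmenyl/alkenyl), and the sphingoid
#' hydroxylation prefix (`d`/`t`). Both `_` and `/` chain separators are
#' accepted and treated identically (sn-position is not modeled). Names with a
#' single `C:D` token are sum compositions (`resolution = "species"`); names
#' enumerating chains are molecular species and their totals are the sums over
#' chains.
#'
#' @param names Character vector of lipid names.
#' @param strict If `TRUE`, an unparseable name is an error carrying the
#'   offending name; if `FALSE`, such names yield a row of missing fields and
#'   one warning.
#' @return A tibble with one row per name: `raw_name`, `lipid_class`,
#'   `total_carbons`, `total_double_bonds`, `ether`
#'   (`"none"`/`"plasmanyl"`/`"plasmenyl"`), `sphingoid`
#'   (`"none"`/`"d"`/`"t"`), `resolution` (`"species"`/`"molecular"`),
#'   `chains` (canonical chain string).
#' @export
#' @examples
#' parse_lipid_name(c("PC 16:0_18:1", "LPC 18:1", "Cer[NS] d18:1_16:0"))
parse_lipid_name <- function(names, strict = TRUE) {
  if (length(names) == 0) return(empty_descriptors())
  if (any(!nzchar(names) | is.na(names))) abort("lipid names must be non-empty")
  rows <- purrr::map(names, parse_one_lipid)
  bad <- names[vapply(rows, is.null, logical(1))]
  if (length(bad) > 0) {
    if (strict) {
      abort(sprintf("unparseable lipid name(s): %s",
                    paste(unique(bad), collapse = ", ")),
            class = "lipid_parse_error")
    }
    warn(sprintf("%d lipid name(s) could not be parsed (e.g. '%s')",
                 length(bad), bad[1]))
  }
  rows <- purrr::map2(rows, names, function(r, nm) {
    if (is.null(r)) {
      tibble::tibble(raw_name = nm, lipid_class = NA_character_,
                     total_carbons = NA_integer_,
                     total_double_bonds = NA_integer_, ether = NA_character_,
                     sphingoid = NA_character_, resolution = NA_character_,
                     chains = NA_character_)
    } else {
      r
    }
  })
  dplyr::bind_rows(rows)
}

empty_descriptors <- function() {
  tibble::tibble(raw_name = character(), lipid_class = character(),
                 total_carbons = integer(), total_double_bonds = integer(),
                 ether = character(), sphingoid = character(),
                 resolution = character(), chains = character())
}

# one name -> one-row tibble, or NULL when the grammar does not match
parse_one_lipid <- function(name) {
  nm <- trimws(name)
  m <- regmatches(nm, regexec(
    "^([A-Za-z][A-Za-z0-9]*(?:\\[[^]]+\\])?)[ ]+(.+)$", nm))[[1]]
  if (length(m) == 0) return(NULL)
  cls <- m[2]
  chain_str <- m[3]
  chains <- strsplit(chain_str, "[_/]")[[1]]
  parsed <- purrr::map(chains, function(ch) {
    cm <- regmatches(ch, regexec("^(O-|P-)?([dt])?([0-9]+):([0-9]+)$", ch))[[1]]
    if (length(cm) == 0) return(NULL)
    list(ether = unname(c("O-" = "plasmanyl", "P-" = "plasmenyl")[cm[2]]),
         sphingoid = if (nzchar(cm[3])) cm[3] else NA_character_,
         carbons = as.integer(cm[4]), dbonds = as.integer(cm[5]))
  })
  if (any(vapply(parsed, is.null, logical(1)))) return(NULL)
  carbons <- sum(vapply(parsed, `[[`, integer(1), "carbons"))
  if (carbons <= 0) return(NULL)
  dbonds <- sum(vapply(parsed, `[[`, integer(1), "dbonds"))
  ether <- unlist(purrr::map(parsed, "ether"))
  ether <- ether[!is.na(ether)]
  sph <- unlist(purrr::map(parsed, "sphingoid"))
  sph <- sph[!is.na(sph)]
  tibble::tibble(
    raw_name = name,
    lipid_class = cls,
    total_carbons = carbons,
    total_double_bonds = dbonds,
    ether = if (length(ether) > 0) ether[1] else "none",
    sphingoid = if (length(sph) > 0) sph[1] else "none",
    resolution = if (length(chains) > 1) "molecular" else "species",
    chains = paste(gsub("/", "_", chains, fixed = TRUE), collapse = "_")
  )
}

#' Canonical shorthand for a parsed descriptor
#'
#' Re-formats a descriptor row back to `CLASS chains`; re-parsing the result
#' reproduces the descriptor.
#'
#' @param descriptors Tibble from [parse_lipid_name()].
#' @return Character vector of canonical names.
#' @export
format_lipid_name <- function(descriptors) {
  paste(descriptors$lipid_class, descriptors$chains)
}

#' Derive lipid-class annotation sets from lipid names
#'
#' Groups lipid names by parsed class into GMT-style annotation sets; names
#' the parser cannot handle are collected under an `"unclassified"` term.
#'
#' @param names Character vector of lipid names.
#' @return Long annotation tibble (`term_id`, `description`, `feature_id`)
#'   with a `"lipid"` layer attribute.
#' @export
lipid_class_sets <- function(names) {
  if (length(names) == 0) {
    out <- tibble::tibble(term_id = character(), description = character(),
                          feature_id = character())
    attr(out, "layer") <- "lipid"
    return(out)
  }
  desc <- parse_lipid_name(names, strict = FALSE)
  out <- desc |>
    dplyr::mutate(term_id = dplyr::coalesce(.data$lipid_class, "unclassified"),
                  description = ifelse(is.na(.data$lipid_class), "unparseable lipid names",
                                       paste("lipid class", .data$lipid_class))) |>
    dplyr::distinct(.data$term_id, .data$description,
                    feature_id = .data$raw_name) |>
    dplyr::arrange(.data$term_id, .data$feature_id)
  attr(out, "layer") <- "lipid"
  out
}

#' Chain-length partition of a lipid class's fold changes
#'
#' Splits the members of one lipid class at a total-carbon cutoff and
#' summarises each side's mean log2 fold change in one genotype. Short-chain
#' skews (for example cholesterol esters or lyso-PC species under 20 carbons)
#' show up as a difference between the two group means.
#'
#' @param descriptors Tibble from [parse_lipid_name()] covering the lipid layer.
#' @param diff Long differential tibble from [log2fc_vs_control()] for lipids.
#' @param lipid_class Class label to profile (e.g. `"CE"`, `"LPC"`).
#' @param genotype Genotype whose fold changes are summarised.
#' @param carbon_cutoff Total-carbon boundary; members with
#'   `total_carbons < carbon_cutoff` form the short-chain group.
#' @return A two-row tibble: `group` (`"below"`, `"at_or_above"`),
#'   `n_members`, `n_with_fc`, `mean_log2fc` (missing when a group is empty).
#' @export
chain_length_profile <- function(descriptors, diff, lipid_class, genotype,
                                 carbon_cutoff = 20) {
  if (carbon_cutoff <= 0) abort("`carbon_cutoff` must be positive")
  members <- descriptors |>
    dplyr::filter(!is.na(.data$lipid_class), .data$lipid_class == !!lipid_class)
  if (nrow(members) == 0) {
    abort(sprintf("lipid class '%s' has no members", lipid_class))
  }
  fc <- diff |>
    dplyr::filter(.data$genotype == !!genotype) |>
    dplyr::select("feature_id", "log2fc")
  members |>
    dplyr::mutate(group = ifelse(.data$total_carbons < carbon_cutoff,
                                 "below", "at_or_above")) |>
    dplyr::left_join(fc, by = c(raw_name = "feature_id")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_members = dplyr::n(),
                     n_with_fc = sum(!is.na(.data$log2fc)),
                     mean_log2fc = ifelse(.data$n_with_fc > 0,
                                          mean(.data$log2fc, na.rm = TRUE),
                                          NA_real_),
                     .groups = "drop") |>
    tidyr::complete(group = c("below", "at_or_above"),
                    fill = list(n_members = 0L, n_with_fc = 0L,
                                mean_log2fc = NA_real_)) |>
    dplyr::arrange(match(.data$group, c("below", "at_or_above")))
}
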