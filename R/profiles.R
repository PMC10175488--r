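#' Read a species relative-abundance table with optional sample metadata
#'
#' The abundance TSV has taxon identifiers in the first column and one column
#' per sample, with values in percent (each column summing to at most 100).
#' The metadata TSV is keyed by a `sample` column and may carry `group`
#' (HI/PI/RI), `delivery`, `feeding`, `antibiotics` and `age_days`; samples
#' lacking metadata are flagged with a warning but never dropped.
#'
#' @param path Path to the abundance TSV.
#' @param metadata_path Optional path to the metadata TSV.
#' @return A list with `abundance` (wide tibble), `metadata` (tibble or
#'   `NULL`) and `missing_metadata` (character vector of unmatched samples).
#' @export
read_abundance_table <- function(path, metadata_path = NULL) {
  if (!file.exists(path)) stop("abundance file not found: ", path)
  abundance <- readr::read_tsv(path, show_col_types = FALSE,
                               progress = FALSE)
  names(abundance)[1] <- "taxon"
  m <- abund_matrix(abundance)
  check_abundance(m)
  metadata <- NULL
  missing <- character(0)
  if (!is.null(metadata_path)) {
    if (!file.exists(metadata_path)) {
      stop("metadata file not found: ", metadata_path)
    }
    metadata <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                                progress = FALSE)
    if (!"sample" %in% names(metadata)) {
      stop("metadata must have a 'sample' column")
    }
    missing <- setdiff(colnames(m), metadata$sample)
    if (length(missing) > 0) {
      warning(length(missing), " sample(s) lack metadata: ",
              paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  list(abundance = abundance, metadata = metadata,
       missing_metadata = missing)
}

#' Write an abundance table to TSV
#'
#' @param abundance Wide abundance tibble (`taxon` + sample columns).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_abundance_table <- function(abundance, path) {
  readr::write_tsv(abundance, path, progress = FALSE)
  invisible(path)
}

#' Per-sample species richness
#'
#' Counts, for each sample, the taxa whose relative abundance is strictly
#' greater than the detection threshold (default 0.05 percent).
#'
#' @param abundance Wide abundance tibble or taxa-by-samples matrix.
#' @param detection Detection threshold in percent; strictly exceeded taxa
#'   count.
#' @return Tibble with `sample` and `richness`.
#' @export
richness <- function(abundance, detection = 0.05) {
  if (detection < 0) stop("'detection' must be >= 0")
  m <- abund_matrix(abundance)
  tibble::tibble(sample = colnames(m),
                 richness = unname(colSums(m > detection)))
}

#' Per-taxon prevalence across samples
#'
#' Prevalence is the percentage of samples in which a taxon exceeds the
#' detection threshold (strict inequality).
#'
#' @inheritParams richness
#' @return Tibble with `taxon`, `n_present` and `prevalence` (percent).
#' @export
prevalence <- function(abundance, detection = 0.05) {
  m <- abund_matrix(abundance)
  if (ncol(m) == 0) stop("empty table: no samples")
  n_present <- rowSums(m > detection)
  tibble::tibble(taxon = rownames(m),
                 n_present = as.integer(n_present),
                 prevalence = 100 * n_present / ncol(m))
}

#' Major-player prevalence: how often a taxon ranks in the top abundances
#'
#' For each sample the nonzero taxa are ranked by abundance; a taxon is a
#' "major player" in that sample when its abundance ranks within the top
#' `top_n`. Ties at the boundary rank are counted inclusively (all taxa tied
#' with the `top_n`-th abundance qualify), so the result never depends on
#' taxon identifier order. Zero-abundance taxa never qualify, even when fewer
#' than `top_n` taxa are nonzero.
#'
#' @inheritParams richness
#' @param top_n Rank cutoff (default 3).
#' @return Tibble with `taxon` and `major_player_prevalence` (percent of
#'   samples).
#' @export
major_player_prevalence <- function(abundance, top_n = 3) {
  if (top_n < 1) stop("'top_n' must be >= 1")
  m <- abund_matrix(abundance)
  if (ncol(m) == 0) stop("empty table: no samples")
  hits <- integer(nrow(m))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    nz <- x[x > 0]
    if (length(nz) == 0) next
    cutoff <- if (length(nz) <= top_n) min(nz) else {
      sort(nz, decreasing = TRUE)[top_n]
    }
    hits <- hits + as.integer(x >= cutoff & x > 0)
  }
  tibble::tibble(taxon = rownames(m),
                 major_player_prevalence = 100 * hits / ncol(m))
}

#' Build a core-species report
#'
#' Combines prevalence and major-player prevalence per taxon and flags core
#' species under the default thresholds.
#'
#' @inheritParams richness
#' @param top_n Rank cutoff for major-player status.
#' @param prevalence_min,major_min Strict thresholds in percent used for the
#'   `is_core` flag.
#' @return Tibble with `taxon`, `n_present`, `prevalence`,
#'   `major_player_prevalence`, `is_core`, ordered by descending prevalence.
#' @export
core_species_report <- function(abundance, detection = 0.05, top_n = 3,
                                prevalence_min = 10, major_min = 3) {
  prev <- prevalence(abundance, detection = detection)
  mp <- major_player_prevalence(abundance, top_n = top_n)
  dplyr::left_join(prev, mp, by = "taxon") |>
    dplyr::mutate(is_core = .data$prevalence > prevalence_min &
                    .data$major_player_prevalence > major_min) |>
    dplyr::arrange(dplyr::desc(.data$prevalence), .data$taxon)
}

#' Select core species from a prevalence report
#'
#' A taxon is core when its overall prevalence strictly exceeds
#' `prevalence_min` percent and its major-player prevalence strictly exceeds
#' `major_min` percent. Thresholds are strict following the defining wording
#' "higher than"; a taxon at exactly the threshold is excluded.
#'
#' @param report Data frame with columns `taxon`, `prevalence` and
#'   `major_player_prevalence` (e.g. from [core_species_report()]).
#' @param prevalence_min,major_min Strict thresholds in percent.
#' @return Tibble of core taxa with their two prevalence columns, in
#'   descending prevalence order.
#' @export
select_core_species <- function(report, prevalence_min = 10, major_min = 3) {
  stopifnot(is.data.frame(report))
  if (nrow(report) == 0) {
    return(tibble::tibble(taxon = character(0), prevalence = numeric(0),
                          major_player_prevalence = numeric(0)))
  }
  needed <- c("taxon", "prevalence", "major_player_prevalence")
  if (!all(needed %in% names(report))) {
    stop("report must have columns: ", paste(needed, collapse = ", "))
  }
  report |>
    dplyr::filter(.data$prevalence > prevalence_min,
                  .data$major_player_prevalence > major_min) |>
    dplyr::arrange(dplyr::desc(.data$prevalence), .data$taxon) |>
    dplyr::select(dplyr::all_of(c("taxon", "prevalence",
                                  "major_player_prevalence")))
}

#' Bundled reference summary tables
#'
#' Plain-text copies of summary statistics printed by a large published
#' survey of 10,935 infant gut metagenomes, used as worked-example inputs:
#' `core_prevalence` (37 species with prevalence and major-player prevalence),
#' `icst_composition` (the eight community state types with host-group
#' percentages and health labels) and `ps_profiles` (per-species population
#' subspecies multiplicity distributions by health group).
#'
#' @param name One of `"core_prevalence"`, `"icst_composition"`,
#'   `"ps_profiles"`.
#' @return A tibble.
#' @export
load_reference_table <- function(name = c("core_prevalence",
                                          "icst_composition",
                                          "ps_profiles")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0("infant_", name, ".tsv"),
                      package = "icstools", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
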