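#' Screen a sample's reads against a strain k-mer database
#'
#' Computes the canonical k-mers of the reads and, for every population
#' subspecies (PS) in the database, the fraction of its PS-specific k-mers
#' observed. A PS is called present when that fraction reaches
#' `min_fraction` *and* the absolute number of observed specific k-mers
#' reaches `min_kmers`. Raising `min_fraction` can only remove calls
#' (detection is monotone).
#'
#' @param reads Character vector of read sequences, a tibble with a
#'   `sequence` column, or a precomputed canonical k-mer set (character
#'   vector flagged with `is_kmers = TRUE`).
#' @param db A `strain_db` from [build_database()].
#' @param min_fraction Minimum observed fraction of PS-specific k-mers.
#' @param min_kmers Minimum absolute observed PS-specific k-mer count.
#' @param is_kmers Set `TRUE` when `reads` is already a canonical k-mer set.
#' @return Tibble with `species`, `ps`, `n_specific`, `n_observed`,
#'   `fraction`, `called`.
#' @export
screen_sample <- function(reads, db, min_fraction = 0.10, min_kmers = 50,
                          is_kmers = FALSE) {
  stopifnot(inherits(db, "strain_db"))
  if (length(db$species) == 0) stop("empty database")
  seqs <- if (is.data.frame(reads)) reads$sequence else reads
  obs <- if (is_kmers) unique(seqs) else canonical_kmers(seqs, k = db$k)
  purrr::map_dfr(names(db$species), function(s) {
    ps_sets <- db$species[[s]]$ps
    purrr::map_dfr(names(ps_sets), function(p) {
      n_spec <- length(ps_sets[[p]])
      n_obs <- if (n_spec > 0) sum(ps_sets[[p]] %in% obs) else 0L
      frac <- if (n_spec > 0) n_obs / n_spec else 0
      tibble::tibble(species = s, ps = p, n_specific = n_spec,
                     n_observed = as.integer(n_obs), fraction = frac,
                     called = frac >= min_fraction & n_obs >= min_kmers)
    })
  })
}

#' Screen many samples into a PS call set
#'
#' @param read_sets Named list of read sets (each as accepted by
#'   [screen_sample()]).
#' @inheritParams screen_sample
#' @return Tibble of calls (`sample`, `species`, `ps`, `fraction`), one row
#'   per detected PS.
#' @export
screen_samples <- function(read_sets, db, min_fraction = 0.10,
                           min_kmers = 50, is_kmers = FALSE) {
  stopifnot(!is.null(names(read_sets)))
  purrr::imap_dfr(read_sets, function(reads, nm) {
    res <- screen_sample(reads, db, min_fraction = min_fraction,
                         min_kmers = min_kmers, is_kmers = is_kmers)
    res <- res[res$called, c("species", "ps", "fraction")]
    if (nrow(res) == 0) return(NULL)
    dplyr::bind_cols(tibble::tibble(sample = nm), res)
  })
}

#' Multiplicity distribution of population subspecies in a sample group
#'
#' Counts, within a group of samples, how many samples harbor exactly `m`
#' detected PS of the species, for m = 1..5 with the last bin capped (five
#' or more PS count as 5). Percentages are over *all* group samples, so
#' summing them gives the species' prevalence in the group.
#'
#' @param calls PS call tibble (`sample`, `species`, `ps`), e.g. from
#'   [screen_samples()].
#' @param species Species identifier to summarize.
#' @param group_samples Character vector of all sample ids in the group
#'   (the percentage denominator).
#' @param max_multiplicity Cap for the terminal bin (default 5).
#' @return One-row tibble with `species`, `n_group`, `p1`..`p5` (percent),
#'   `richness_if_present`, `richness_all`, `prevalence` and `raw_counts`
#'   (list column of per-sample PS counts).
#' @export
multiplicity_distribution <- function(calls, species, group_samples,
                                      max_multiplicity = 5) {
  if (length(group_samples) == 0) stop("group is empty")
  sub <- calls[calls$species == species &
                 calls$sample %in% group_samples, , drop = FALSE]
  per_sample <- table(factor(sub$sample, levels = group_samples))
  counts <- as.integer(per_sample)
  capped <- pmin(counts, max_multiplicity)
  p <- vapply(seq_len(max_multiplicity), function(m) {
    100 * sum(capped == m) / length(group_samples)
  }, numeric(1))
  out <- tibble::tibble(species = species,
                        n_group = length(group_samples))
  out[paste0("p", seq_len(max_multiplicity))] <- as.list(p)
  out$richness_if_present <- richness_if_present(p)
  out$richness_all <- richness_all(p)
  out$prevalence <- ps_prevalence(p)
  out$raw_counts <- list(counts)
  out
}

multiplicity_vector <- function(x) {
  if (is.data.frame(x)) {
    p_cols <- grep("^p[0-9]+$", names(x), value = TRUE)
    if (length(p_cols) == 0) stop("no p1..pM columns found")
    as.numeric(x[1, p_cols])
  } else {
    as.numeric(x)
  }
}

#' Mean PS richness among samples where the species is present
#'
#' `sum(m * p_m) / sum(p_m)` over the multiplicity bins m = 1..M. Undefined
#' (returned as `NA`) when the species is absent from every sample.
#'
#' @param dist A multiplicity distribution row from
#'   [multiplicity_distribution()] or a numeric vector of bin percentages
#'   `(p1, ..., pM)`.
#' @return Mean coexisting-PS count among positive samples.
#' @export
richness_if_present <- function(dist) {
  p <- multiplicity_vector(dist)
  if (sum(p) <= 0) return(NA_real_)
  sum(seq_along(p) * p) / sum(p)
}

#' Mean PS richness over all samples of a group
#'
#' `sum(m * p_m) / 100`: absent samples count zero.
#'
#' @inheritParams richness_if_present
#' @return Mean PS count over all group samples.
#' @export
richness_all <- function(dist) {
  p <- multiplicity_vector(dist)
  sum(seq_along(p) * p) / 100
}

#' Species prevalence from a multiplicity distribution
#'
#' `sum(p_m)`: the percentage of group samples harboring at least one PS.
#'
#' @inheritParams richness_if_present
#' @return Prevalence percent.
#' @export
ps_prevalence <- function(dist) {
  p <- multiplicity_vector(dist)
  sum(p)
}

#' Table of multiplicity distributions per species and group
#'
#' @param calls PS call tibble (`sample`, `species`, `ps`).
#' @param groups Named list of character vectors: group name -> member
#'   sample ids.
#' @param species Species to include (default: all in `calls`).
#' @param max_multiplicity Terminal bin cap (default 5).
#' @return Tibble with one row per species x group mirroring the
#'   multiplicity-table layout (`group`, `species`, `p1`..`p5`,
#'   `n_ps_detected`, `n_ps_single_hit`, richness and prevalence columns).
#' @export
ps_multiplicity_table <- function(calls, groups, species = NULL,
                                  max_multiplicity = 5) {
  species <- species %||% sort(unique(calls$species))
  purrr::imap_dfr(groups, function(samples, gname) {
    purrr::map_dfr(species, function(sp) {
      row <- multiplicity_distribution(calls, sp, samples,
                                       max_multiplicity = max_multiplicity)
      sub <- calls[calls$species == sp & calls$sample %in% samples, ]
      ps_counts <- table(sub$ps)
      dplyr::bind_cols(
        tibble::tibble(group = gname),
        dplyr::select(row, -dplyr::all_of("raw_counts")),
        tibble::tibble(n_ps_detected = length(ps_counts),
                       n_ps_single_hit = sum(ps_counts == 1))
      )
    })
  })
}

#' Most prevalent population subspecies of a species within a group
#'
#' Ranks PS by the number of group samples in which they were detected;
#' ties are broken by PS identifier order.
#'
#' @param calls PS call tibble.
#' @param species Species identifier.
#' @param group_samples Sample ids forming the group.
#' @param n Number of PS to return (default 5).
#' @return Tibble with `ps`, `n_samples`, `prevalence` (percent of group),
#'   at most `n` rows.
#' @export
top_prevalent_ps <- function(calls, species, group_samples, n = 5) {
  if (n < 1) stop("'n' must be >= 1")
  if (length(group_samples) == 0) {
    return(tibble::tibble(ps = character(0), n_samples = integer(0),
                          prevalence = numeric(0)))
  }
  sub <- calls[calls$species == species &
                 calls$sample %in% group_samples, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(tibble::tibble(ps = character(0), n_samples = integer(0),
                          prevalence = numeric(0)))
  }
  counts <- table(sub$ps)
  out <- tibble::tibble(ps = names(counts),
                        n_samples = as.integer(counts),
                        prevalence = 100 * as.integer(counts) /
                          length(group_samples))
  out <- dplyr::arrange(out, dplyr::desc(.data$n_samples), .data$ps)
  utils::head(out, n)
}

#' Classify top-prevalent PS as exclusive or shared across groups
#'
#' Each PS appearing in at least one group's top-prevalence list is
#' classified by set membership: `"exclusive"` (one group's list only),
#' `"shared-subset"` (more than one but not all), `"shared-all"` (every
#' group's list).
#'
#' @param top_lists Named list of character vectors: group name -> PS ids in
#'   that group's top-prevalence list. At least two groups.
#' @return A list with `classification` (tibble: `ps`, `n_groups`, `class`,
#'   `groups`), `fraction_exclusive`, and `edges` (tibble: `ps`, `group`)
#'   for network export.
#' @export
exclusivity_summary <- function(top_lists) {
  if (length(top_lists) < 2) stop("need at least 2 groups")
  all_ps <- sort(unique(unlist(top_lists)))
  n_groups <- length(top_lists)
  classification <- purrr::map_dfr(all_ps, function(p) {
    present <- names(top_lists)[vapply(top_lists, function(l) p %in% l,
                                       logical(1))]
    cls <- if (length(present) == 1) {
      "exclusive"
    } else if (length(present) == n_groups) {
      "shared-all"
    } else {
      "shared-subset"
    }
    tibble::tibble(ps = p, n_groups = length(present), class = cls,
                   groups = paste(present, collapse = ","))
  })
  edges <- purrr::imap_dfr(top_lists, function(l, g) {
    if (length(l) == 0) return(NULL)
    tibble::tibble(ps = l, group = g)
  })
  list(
    classification = classification,
    fraction_exclusive = if (length(all_ps) > 0) {
      mean(classification$class == "exclusive")
    } else {
      NA_real_
    },
    edges = edges
  )
}
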