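#' Canonical k-mers of a DNA sequence
#'
#' Every length-`k` window of the sequence is reduced to its canonical form,
#' the lexicographic minimum of the window and its reverse complement, making
#' the resulting set strand-invariant. Windows containing `N` (or any
#' non-ACGT character) are skipped. `k` must be odd so no k-mer equals its
#' own reverse complement ambiguously.
#'
#' @param sequence A DNA string (or character vector of strings whose k-mer
#'   sets are unioned, e.g. reads).
#' @param k Odd k-mer size >= 3 (default 23).
#' @return Character vector: the set of canonical k-mers (unique, unordered).
#' @export
canonical_kmers <- function(sequence, k = 23) {
  if (k < 3 || k %% 2 == 0) stop("'k' must be odd and >= 3")
  sequence <- toupper(sequence)
  out <- lapply(sequence, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1)
    fwd <- substring(s, starts, starts + k - 1)
    rc_full <- chartr("ACGTN", "TGCAN",
                      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                            collapse = ""))
    # reverse complement of window starting at i is the window of rc_full
    # starting at n - k - i + 2
    rc <- substring(rc_full, n - k - starts + 2, n - starts + 1)
    can <- pmin(fwd, rc)
    can[!grepl("[^ACGT]", fwd)]
  })
  unique(unlist(out))
}

#' Estimate nucleotide identity from canonical k-mer sets
#'
#' Uses the Mash-style distance on the full-set Jaccard index `J`:
#' `identity = 100 * (1 + (1/k) * ln(2J / (1 + J)))`, floored at 0 and equal
#' to 100 when the sets coincide. At small divergences this closely tracks
#' average nucleotide identity for substitution-only differences.
#'
#' @param set_a,set_b Canonical k-mer sets (character vectors), nonempty.
#' @param k The k-mer size used to build the sets.
#' @return Estimated identity percent in \[0, 100\].
#' @export
kmer_identity <- function(set_a, set_b, k = 23) {
  if (length(set_a) == 0 || length(set_b) == 0) {
    stop("empty k-mer set: identity undefined")
  }
  inter <- sum(set_a %in% set_b)
  j <- inter / (length(set_a) + length(set_b) - inter)
  if (j == 1) return(100)
  if (j == 0) return(0)
  max(0, 100 * (1 + log(2 * j / (1 + j)) / k))
}

#' Filter genome records on assembly quality statistics
#'
#' Keeps records with completeness strictly above `completeness_min` percent
#' and contamination strictly below `contamination_max` percent. Records
#' lacking either statistic pass with a warning.
#'
#' @param records Tibble with at least `genome`; optional `completeness` and
#'   `contamination` columns in percent.
#' @param completeness_min Strict lower bound on completeness (default 50).
#' @param contamination_max Strict upper bound on contamination
#'   (default 1.95).
#' @return The filtered tibble.
#' @export
filter_records <- function(records, completeness_min = 50,
                           contamination_max = 1.95) {
  stopifnot(is.data.frame(records))
  comp <- if ("completeness" %in% names(records)) {
    records$completeness
  } else {
    rep(NA_real_, nrow(records))
  }
  cont <- if ("contamination" %in% names(records)) {
    records$contamination
  } else {
    rep(NA_real_, nrow(records))
  }
  if (any(!is.na(comp) & (comp < 0 | comp > 100)) ||
      any(!is.na(cont) & (cont < 0 | cont > 100))) {
    stop("completeness/contamination must lie in [0, 100]")
  }
  missing_stats <- is.na(comp) | is.na(cont)
  if (any(missing_stats)) {
    warning(sum(missing_stats),
            " record(s) lack quality statistics and pass unfiltered")
  }
  keep <- missing_stats |
    (comp > completeness_min & cont < contamination_max)
  records[keep, , drop = FALSE]
}

#' Validate claimed species membership against references
#'
#' A genome is kept when its k-mer identity to the reference genome of its
#' claimed species strictly exceeds `ani_min` percent (species boundary,
#' default 94).
#'
#' @param genomes Named character vector of genome sequences.
#' @param species Named character vector mapping genome name to claimed
#'   species.
#' @param references Named character vector of reference sequences, one per
#'   claimed species.
#' @param ani_min Strict identity threshold in percent.
#' @param k k-mer size.
#' @return Tibble with `genome`, `species`, `identity`, `kept`.
#' @export
validate_species <- function(genomes, species, references, ani_min = 94,
                             k = 23) {
  claimed <- unique(unname(species[names(genomes)]))
  missing_ref <- setdiff(claimed, names(references))
  if (length(missing_ref) > 0) {
    stop("missing reference for species: ",
         paste(missing_ref, collapse = ", "))
  }
  ref_kmers <- lapply(references[claimed], canonical_kmers, k = k)
  purrr::map_dfr(names(genomes), function(g) {
    sp <- species[[g]]
    id <- kmer_identity(canonical_kmers(genomes[[g]], k = k),
                        ref_kmers[[sp]], k = k)
    tibble::tibble(genome = g, species = sp, identity = id,
                   kept = id > ani_min)
  })
}

#' Dereplicate genomes of one species into population subspecies
#'
#' Single-linkage clusters over genome pairs whose estimated identity
#' strictly exceeds `identity_min` percent (default 99.8); each cluster
#' becomes one population subspecies (PS), represented by its longest genome
#' (ties broken by identifier order).
#'
#' @param genomes Named character vector of genome sequences (one species).
#' @param identity_min Strict identity threshold in percent.
#' @param k k-mer size.
#' @return A list with `members` (tibble: `genome`, `representative`) and
#'   `representatives` (named character vector of representative sequences).
#' @export
dereplicate <- function(genomes, identity_min = 99.8, k = 23) {
  if (length(genomes) == 0) stop("need at least one genome")
  ids <- names(genomes)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    kmers <- lapply(genomes, canonical_kmers, k = k)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (kmer_identity(kmers[[i]], kmers[[j]], k = k) > identity_min) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  members <- purrr::map_dfr(unique(comp), function(cc) {
    idx <- which(comp == cc)
    lens <- nchar(genomes[idx])
    rep_idx <- idx[order(-lens, ids[idx])][1]
    tibble::tibble(genome = ids[idx], representative = ids[rep_idx])
  })
  members <- members[match(ids, members$genome), ]
  reps <- unique(members$representative)
  list(members = members, representatives = genomes[reps])
}

#' Build a species- and strain-specific k-mer database
#'
#' For each species, the species-specific k-mer set is the union of its
#' representatives' canonical k-mers minus every other species' k-mers; for
#' each population subspecies (PS), the PS-specific set is its own k-mers
#' minus those of every other PS of the same species and minus every other
#' species' k-mers. PS-specific sets within a species are therefore pairwise
#' disjoint, as are species-specific sets across species. A PS whose
#' specific set comes out empty is recorded as undetectable with a warning.
#'
#' @param representatives Named character vector of representative genome
#'   sequences (one entry per PS).
#' @param species Named character vector mapping representative name to
#'   species.
#' @param k Odd k-mer size (default 23).
#' @return An object of class `strain_db`: list with `k`, `species` (a list
#'   keyed by species, each holding `ps` — a list of PS-specific k-mer sets —
#'   and `species_specific`), and `undetectable` (character vector).
#' @export
build_database <- function(representatives, species, k = 23) {
  if (length(representatives) == 0) stop("need at least one representative")
  sp <- unname(species[names(representatives)])
  if (anyNA(sp)) stop("every representative needs a species label")
  kmers <- lapply(representatives, canonical_kmers, k = k)
  species_union <- lapply(split(names(representatives), sp), function(ids) {
    unique(unlist(kmers[ids]))
  })
  species_names <- names(species_union)
  undetectable <- character(0)
  db_species <- stats::setNames(vector("list", length(species_names)),
                                species_names)
  for (s in species_names) {
    other_union <- unique(unlist(species_union[setdiff(species_names, s)]))
    sp_specific <- setdiff(species_union[[s]], other_union)
    ps_ids <- names(representatives)[sp == s]
    ps_sets <- stats::setNames(vector("list", length(ps_ids)), ps_ids)
    for (p in ps_ids) {
      same_sp_other <- unique(unlist(kmers[setdiff(ps_ids, p)]))
      ps_sets[[p]] <- setdiff(kmers[[p]], c(same_sp_other, other_union))
      if (length(ps_sets[[p]]) == 0) undetectable <- c(undetectable, p)
    }
    db_species[[s]] <- list(ps = ps_sets, species_specific = sp_specific)
  }
  if (length(undetectable) > 0) {
    warning("PS with empty specific k-mer set (undetectable): ",
            paste(undetectable, collapse = ", "))
  }
  structure(list(k = as.integer(k), species = db_species,
                 undetectable = undetectable),
            class = "strain_db")
}

#' @export
print.strain_db <- function(x, ...) {
  cat("Strain k-mer database (k = ", x$k, "): ", length(x$species),
      " species, ", sum(lengths(lapply(x$species, `[[`, "ps"))),
      " population subspecies\n", sep = "")
  invisible(x)
}
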