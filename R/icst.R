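#' Pearson correlation distance between samples
#'
#' Distance between two samples is `1 - r`, where `r` is the Pearson
#' correlation of their core-species abundance vectors; values lie in
#' \[0, 2\], with 0 for identical profiles and 2 for perfectly anticorrelated
#' ones. Intended for the core-species table (at least two taxa).
#'
#' @param abundance Wide abundance tibble or taxa-by-samples matrix
#'   (typically restricted to core species).
#' @return A `dist` object over samples.
#' @export
pearson_distance <- function(abundance) {
  m <- abund_matrix(abundance)
  if (nrow(m) < 2) stop("need at least 2 taxa for correlation distance")
  sds <- apply(m, 2, stats::sd)
  bad <- which(sds == 0)
  if (length(bad) > 0) {
    stop("zero-variance sample vector(s): ",
         paste(colnames(m)[bad], collapse = ", "))
  }
  d <- 1 - stats::cor(m)
  d[d < 0] <- 0  # guard tiny negative rounding
  stats::as.dist(d)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(i, j) = 1 - 2 * sum(min(x_ik, x_jk)) / sum(x_ik + x_jk)`, in \[0, 1\].
#' A pair of all-zero samples has an undefined ratio and is reported as 0
#' with a warning.
#'
#' @inheritParams pearson_distance
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(abundance) {
  m <- abund_matrix(abundance)
  if (any(m < 0)) stop("Bray-Curtis requires non-negative abundances")
  # vegdist warns about empty rows itself; we detect and repair them below
  d <- suppressWarnings(vegan::vegdist(t(m), method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): distance set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering with the furthest-neighbor criterion; merge
#' heights are non-decreasing. A Ward-type criterion (`"ward.D2"`) is offered
#' as an alternative.
#'
#' @param dist A `dist` object or symmetric distance matrix.
#' @param method `"complete"` (default) or `"ward.D2"`.
#' @return An `hclust` object.
#' @export
hcl_complete <- function(dist, method = c("complete", "ward.D2")) {
  method <- match.arg(method)
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist), tol = 1e-8)) {
      stop("distance matrix must be symmetric")
    }
    dist <- stats::as.dist(dist)
  }
  stats::hclust(dist, method = method)
}

#' Cut a dendrogram into supported community state types
#'
#' Chooses the flat cut of the tree whose partition maximizes the mean
#' silhouette width on the clustering distances (candidate cluster counts
#' from 2 upward; ties toward fewer clusters), then marks samples in
#' clusters whose support (member count) falls below `min_support` as
#' `"unassigned"`. Mean silhouette rewards cuts whose clusters are compact
#' relative to their separation, so a well-separated state is kept whole
#' rather than split into fragments that each clear the support threshold.
#' When no cluster at the chosen cut reaches the support threshold (no
#' supported structure) a single all-sample cluster is returned.
#'
#' @param hc An `hclust` object.
#' @param dist The `dist` object the tree was built from (used for
#'   silhouette scoring).
#' @param min_support Minimum cluster support: an absolute count (>= 1) or a
#'   fraction of the sample count in (0, 1), rounded up.
#' @param k_max Largest cluster count to scan (default: scales with the
#'   number of samples per support unit).
#' @return Tibble with `sample` and `cluster` (integer id as character, or
#'   `"unassigned"`); the chosen number of flat clusters is in attribute
#'   `"k"`, the resolved support in `"min_support"`.
#' @export
extract_icsts <- function(hc, dist, min_support = 0.0457, k_max = NULL) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels %||% seq_len(length(hc$order)))
  s <- if (min_support < 1) ceiling(min_support * n) else round(min_support)
  s <- max(1L, as.integer(s))
  labels <- hc$labels %||% as.character(seq_len(n))
  single <- function(warn = NULL) {
    if (!is.null(warn)) warning(warn)
    out <- tibble::tibble(sample = labels, cluster = "1")
    attr(out, "k") <- 1L
    attr(out, "min_support") <- s
    out
  }
  if (s > n) {
    return(single("min_support exceeds the number of samples; returning a single cluster"))
  }
  if (n < 3) return(single())
  k_max <- k_max %||% min(n - 1, max(20L, 3L * (n %/% s)))
  sil <- vapply(2:k_max, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cl, dist)[, "sil_width"])
  }, numeric(1))
  best_k <- (2:k_max)[which.max(sil)]
  cl <- stats::cutree(hc, k = best_k)
  if (!any(tabulate(cl) >= s)) return(single())
  sizes <- table(cl)
  supported <- as.integer(names(sizes)[sizes >= s])
  # renumber supported clusters by decreasing size for stable output
  ord <- supported[order(-sizes[as.character(supported)],
                         supported)]
  new_id <- stats::setNames(as.character(seq_along(ord)), ord)
  cluster <- ifelse(cl %in% supported, new_id[as.character(cl)],
                    "unassigned")
  out <- tibble::tibble(sample = names(cl), cluster = unname(cluster))
  attr(out, "k") <- best_k
  attr(out, "min_support") <- s
  out
}

genus_of <- function(taxon) {
  vapply(strsplit(taxon, "\\s+"), `[`, character(1), 1)
}

species_epithet_of <- function(taxon) {
  vapply(strsplit(taxon, "\\s+"), function(x) {
    if (length(x) >= 2) x[2] else ""
  }, character(1))
}

#' Name a community state type after its dominant taxa
#'
#' The name is `"ICST-"` followed by the two-letter uppercase genus codes of
#' every taxon whose within-cluster mean abundance strictly exceeds
#' `dominance` percent, joined by `"/"` in descending mean-abundance order.
#' Repeated codes from the same genus collapse to one; when two *distinct*
#' genera collide on a code within one naming run, the species initial is
#' appended to disambiguate. A cluster with no taxon above the threshold is
#' named `"ICST-NA"` with a warning.
#'
#' @param samples Character vector of member sample ids.
#' @param abundance Wide abundance tibble or matrix.
#' @param dominance Dominance threshold in mean percent (default 10).
#' @param collision_codes Optional character vector of genus codes known to
#'   collide across genera in the current naming run (see [fit_icsts()]).
#' @return A single name string; dominant taxa and their means are attached
#'   as attribute `"dominant"`.
#' @export
name_icst <- function(samples, abundance, dominance = 10,
                      collision_codes = character(0)) {
  if (length(samples) == 0) stop("cluster is empty")
  m <- abund_matrix(abundance)
  samples <- intersect(samples, colnames(m))
  means <- rowMeans(m[, samples, drop = FALSE])
  dom <- sort(means[means > dominance], decreasing = TRUE)
  if (length(dom) == 0) {
    warning("no taxon above the dominance threshold; naming cluster ICST-NA")
    out <- "ICST-NA"
    attr(out, "dominant") <- numeric(0)
    return(out)
  }
  genera <- genus_of(names(dom))
  codes <- toupper(substr(genera, 1, 2))
  needs_suffix <- codes %in% collision_codes
  codes[needs_suffix] <- paste0(
    codes[needs_suffix],
    toupper(substr(species_epithet_of(names(dom))[needs_suffix], 1, 1))
  )
  # same genus appearing twice contributes one code
  keep <- !duplicated(paste(codes, genera))
  out <- paste0("ICST-", paste(unique(codes[keep]), collapse = "/"))
  attr(out, "dominant") <- dom
  out
}

#' Health label for a community state type
#'
#' Labels a cluster by the fraction of its members from the PI (preterm or
#' critically ill) host group, computed over members with known group
#' metadata: `"Unhealthy"` when the PI fraction is at least `unhealthy_min`,
#' `"Healthy"` when it is at most `healthy_max`, otherwise `"Mixed"`. When
#' every member's group is missing the label is `"Unknown"`.
#'
#' @param groups Character vector of host groups (`"HI"`, `"PI"`, `"RI"`,
#'   or `NA`) for the cluster's members.
#' @param unhealthy_min,healthy_max PI-fraction thresholds.
#' @return A single label string with the PI fraction in attribute
#'   `"pi_fraction"`.
#' @export
label_health <- function(groups, unhealthy_min = 0.60, healthy_max = 0.25) {
  known <- groups[!is.na(groups)]
  if (length(known) == 0) {
    out <- "Unknown"
    attr(out, "pi_fraction") <- NA_real_
    return(out)
  }
  pi_frac <- mean(known == "PI")
  out <- if (pi_frac >= unhealthy_min) {
    "Unhealthy"
  } else if (pi_frac <= healthy_max) {
    "Healthy"
  } else {
    "Mixed"
  }
  attr(out, "pi_fraction") <- pi_frac
  out
}

#' Fit infant community state types from a core-species table
#'
#' Runs the full typing chain: Pearson-correlation distance on the
#' core-species profiles, complete-linkage hierarchical clustering, a
#' support-maximizing flat cut, dominant-taxon naming and PI-fraction health
#' labeling.
#'
#' @param abundance Wide abundance tibble restricted to core species.
#' @param metadata Optional tibble with `sample` and `group` columns.
#' @param min_support Minimum cluster support (count or fraction), see
#'   [extract_icsts()].
#' @param dominance Naming threshold in mean percent, see [name_icst()].
#' @param method Linkage criterion, see [hcl_complete()].
#' @param unhealthy_min,healthy_max Health-label thresholds, see
#'   [label_health()].
#' @return An object of class `icst_model`: a list with `assignments`
#'   (tibble: `sample`, `cluster`, `icst`), `clusters` (tibble: `cluster`,
#'   `icst`, `support`, `health`, `pi_fraction`, `dominant_taxa`), `hclust`,
#'   and `params`.
#' @examples
#' sim <- gen_community(community_spec(60, default_icst_defs()[1:3],
#'                                     seed = 7))
#' fit <- fit_icsts(sim$abundance, sim$metadata, min_support = 5)
#' fit$clusters
#' @export
fit_icsts <- function(abundance, metadata = NULL, min_support = 0.0457,
                      dominance = 10, method = "complete",
                      unhealthy_min = 0.60, healthy_max = 0.25) {
  m <- abund_matrix(abundance)
  d <- pearson_distance(m)
  hc <- hcl_complete(d, method = method)
  part <- extract_icsts(hc, d, min_support = min_support)
  cluster_ids <- setdiff(unique(part$cluster), "unassigned")

  # detect genus-code collisions across the whole run's dominant taxa
  dom_by_cluster <- lapply(cluster_ids, function(cid) {
    samples <- part$sample[part$cluster == cid]
    means <- rowMeans(m[, samples, drop = FALSE])
    sort(means[means > dominance], decreasing = TRUE)
  })
  all_dom <- unique(unlist(lapply(dom_by_cluster, names)))
  genera <- unique(genus_of(all_dom))
  codes <- toupper(substr(genera, 1, 2))
  collision_codes <- unique(codes[duplicated(codes)])

  clusters <- purrr::map2_dfr(cluster_ids, dom_by_cluster, function(cid, dom) {
    samples <- part$sample[part$cluster == cid]
    nm <- name_icst(samples, m, dominance = dominance,
                    collision_codes = collision_codes)
    groups <- if (!is.null(metadata)) {
      metadata$group[match(samples, metadata$sample)]
    } else {
      rep(NA_character_, length(samples))
    }
    hl <- label_health(groups, unhealthy_min = unhealthy_min,
                       healthy_max = healthy_max)
    tibble::tibble(
      cluster = cid,
      icst = as.character(nm),
      support = length(samples),
      health = as.character(hl),
      pi_fraction = attr(hl, "pi_fraction"),
      dominant_taxa = paste(names(attr(nm, "dominant")), collapse = "; ")
    )
  })
  clusters <- dplyr::arrange(clusters, dplyr::desc(.data$support))
  assignments <- part |>
    dplyr::left_join(dplyr::select(clusters, dplyr::all_of(c("cluster",
                                                             "icst"))),
                     by = "cluster") |>
    dplyr::mutate(icst = dplyr::coalesce(.data$icst, "unassigned"))
  structure(
    list(assignments = assignments, clusters = clusters, hclust = hc,
         params = list(min_support = attr(part, "min_support"),
                       k_cut = attr(part, "k"), dominance = dominance,
                       method = method, unhealthy_min = unhealthy_min,
                       healthy_max = healthy_max)),
    class = "icst_model"
  )
}

#' @export
print.icst_model <- function(x, ...) {
  cat("ICST model: ", nrow(x$clusters), " supported cluster(s), ",
      sum(x$assignments$cluster == "unassigned"), " unassigned sample(s)\n",
      sep = "")
  print(x$clusters)
  invisible(x)
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling on the double-centered squared distances.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such as
#' Bray-Curtis) are reported, and explained-variance fractions are computed
#' over the positive eigenvalues only.
#'
#' @param dist A `dist` object.
#' @param k Number of axes to return (default 2; must be at most n - 1).
#' @return An object of class `pcoa_ord`: list with `coordinates` (tibble:
#'   `sample`, `Axis1`, ...), `eigenvalues`, `explained` (fractions over
#'   positive eigenvalue mass) and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(dist, k = 2) {
  n <- attr(dist, "Size")
  if (k > n - 1) stop("'k' must be at most n - 1")
  sc <- stats::cmdscale(dist, k = k, eig = TRUE)
  eig <- sc$eig
  pos <- eig[eig > 1e-12]
  coords <- sc$points
  if (is.null(coords) || ncol(coords) < k) {
    # degenerate geometry (fewer positive axes than requested): pad zeros
    pad <- matrix(0, nrow = n, ncol = k - ncol(coords))
    coords <- cbind(coords, pad)
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(
    list(
      coordinates = tibble::as_tibble(coords,
                                      rownames = "sample"),
      eigenvalues = eig,
      explained = if (length(pos) > 0) {
        pmax(eig[seq_len(k)], 0) / sum(pos)
      } else {
        rep(0, k)
      },
      negative_eigenvalues = eig[eig < -1e-12]
    ),
    class = "pcoa_ord"
  )
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions the distance matrix into among- and within-group sums of
#' squares and assesses the pseudo-F statistic by permuting group labels.
#' The p-value counts the observed statistic among the permuted ones:
#' `p = (1 + #permuted F >= observed F) / (1 + n_perm)`, so the smallest
#' attainable p-value is `1 / (n_perm + 1)`.
#'
#' @param dist A `dist` object.
#' @param labels Grouping vector aligned with the distance matrix.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return Tibble with `pseudo_F`, `p_value`, `n_permutations`, `df_among`,
#'   `df_within`.
#' @export
permanova <- function(dist, labels, n_perm = 1000, seed = 1L) {
  labels <- as.character(labels)
  counts <- table(labels)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts < 2)) {
    stop("every group needs at least 2 members")
  }
  df <- data.frame(group = factor(labels))
  fit <- with_seed(seed, vegan::adonis2(dist ~ group, data = df,
                                        permutations = n_perm))
  tibble::tibble(
    pseudo_F = fit$F[1],
    p_value = fit$`Pr(>F)`[1],
    n_permutations = as.integer(n_perm),
    df_among = fit$Df[1],
    df_within = fit$Df[2]
  )
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' @param values Numeric response (e.g. per-sample species richness).
#' @param labels Grouping vector.
#' @return A list with `anova` (tibble: `F_statistic`, `p_value`, `df_among`,
#'   `df_within`) and `tukey` (tibble of pairwise comparisons with adjusted
#'   p-values).
#' @export
richness_anova <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 groups")
  if (any(table(labels) < 2)) stop("every group needs at least 2 members")
  within_var <- tapply(values, labels, stats::var)
  if (all(within_var == 0, na.rm = TRUE)) {
    stop("zero within-group variance in every group; ANOVA undefined")
  }
  fit <- stats::aov(values ~ labels)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$labels
  list(
    anova = tibble::tibble(
      F_statistic = s$`F value`[1],
      p_value = s$`Pr(>F)`[1],
      df_among = s$Df[1],
      df_within = s$Df[2]
    ),
    tukey = tibble::as_tibble(tk, rownames = "comparison") |>
      dplyr::rename(difference = "diff", lower = "lwr", upper = "upr",
                    p_adjusted = "p adj")
  )
}
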