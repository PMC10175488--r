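ec_matrix_of <- function(mat) {
  if (is.matrix(mat)) {
    storage.mode(mat) <- "double"
    return(mat)
  }
  stopifnot(is.data.frame(mat))
  samples <- as.character(mat[[1]])
  m <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- samples
  m
}

#' Cluster samples by enzymatic (EC) profile with silhouette-selected k
#'
#' Complete-linkage hierarchical clustering of samples on the chosen
#' dissimilarity (Bray-Curtis on relative abundances by default, Pearson
#' correlation distance as an alternative). The tree is cut at every k in
#' `k_range`, the mean silhouette width is computed on the same distances,
#' and the k with maximal mean silhouette is selected (ties toward the
#' smaller k).
#'
#' @param mat EC relative-abundance tibble (first column `sample`, one
#'   column per EC number) or samples-by-EC matrix; rows sum to 1.
#' @param k_range Candidate cluster counts (default 2:10).
#' @param metric `"bray"` (default) or `"pearson"`.
#' @return An object of class `ep_model`: list with `k`, `labels` (tibble:
#'   `sample`, `cluster`), `silhouette` (tibble: `k`, `mean_silhouette`),
#'   `metric`, `hclust`.
#' @export
cluster_profiles <- function(mat, k_range = 2:10,
                             metric = c("bray", "pearson")) {
  metric <- match.arg(metric)
  m <- ec_matrix_of(mat)
  n <- nrow(m)
  if (n < max(k_range) + 1) {
    stop("need at least max(k_range) + 1 samples")
  }
  if (all(apply(m, 2, stats::sd) == 0)) {
    stop("no structure: EC matrix is constant")
  }
  d <- if (metric == "bray") {
    vegan::vegdist(m, method = "bray")
  } else {
    pearson_distance(t(m))
  }
  hc <- stats::hclust(d, method = "complete")
  sil <- purrr::map_dfr(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    if (length(unique(cl)) < 2) {
      return(tibble::tibble(k = k, mean_silhouette = NA_real_))
    }
    sw <- cluster::silhouette(cl, d)
    tibble::tibble(k = k, mean_silhouette = mean(sw[, "sil_width"]))
  })
  ok <- which(!is.na(sil$mean_silhouette))
  if (length(ok) == 0) stop("silhouette undefined for every candidate k")
  best <- ok[which.max(sil$mean_silhouette[ok])]  # which.max takes first tie
  k <- sil$k[best]
  cl <- stats::cutree(hc, k = k)
  structure(
    list(k = k,
         labels = tibble::tibble(sample = rownames(m), cluster = unname(cl)),
         silhouette = sil, metric = metric, hclust = hc),
    class = "ep_model"
  )
}

#' @export
print.ep_model <- function(x, ...) {
  cat("Enzymatic-profile model: k = ", x$k, " (", x$metric,
      " distance), mean silhouette = ",
      round(x$silhouette$mean_silhouette[x$silhouette$k == x$k], 3), "\n",
      sep = "")
  invisible(x)
}

#' Multivariable association of EC features with cluster membership
#'
#' For every EC with prevalence of at least `prevalence_min` across samples,
#' fits a linear model of `log10(abundance + pseudo)` on cluster-membership
#' indicators plus the supplied covariates, where `pseudo` is half the EC's
#' minimum nonzero abundance. Each cluster coefficient gets a two-sided
#' t-test p-value; Benjamini-Hochberg q-values are computed across all
#' EC-by-cluster tests. Zero-variance ECs are skipped with a warning.
#'
#' @param mat EC relative-abundance tibble or matrix (see
#'   [cluster_profiles()]).
#' @param labels Tibble with `sample` and `cluster`, or a vector aligned with
#'   the matrix rows.
#' @param covariates Optional tibble keyed by `sample` with numeric or
#'   categorical covariate columns.
#' @param prevalence_min Minimum fraction of samples in which an EC must be
#'   nonzero to be tested (default 0.10).
#' @return Tibble with `ec`, `cluster`, `coef`, `p`, `q`, `direction`
#'   (class `ec_association`).
#' @export
associate <- function(mat, labels, covariates = NULL,
                      prevalence_min = 0.10) {
  m <- ec_matrix_of(mat)
  if (is.data.frame(labels)) {
    cl <- labels$cluster[match(rownames(m), labels$sample)]
  } else {
    cl <- labels
  }
  if (length(cl) != nrow(m) || anyNA(cl)) {
    stop("labels do not align with samples")
  }
  cl <- factor(cl)
  df <- data.frame(.cluster = cl)
  if (!is.null(covariates)) {
    cov <- covariates[match(rownames(m), covariates$sample), , drop = FALSE]
    cov$sample <- NULL
    df <- cbind(df, as.data.frame(cov))
  }
  mm <- stats::model.matrix(~ ., data = df)
  if (qr(mm)$rank < ncol(mm)) {
    # name the aliased columns for the user
    q <- qr(mm)
    aliased <- colnames(mm)[q$pivot[seq(q$rank + 1, ncol(mm))]]
    stop("collinear covariates: ", paste(aliased, collapse = ", "))
  }

  prev <- colMeans(m > 0)
  variances <- apply(m, 2, stats::var)
  skip_zero <- variances == 0
  if (any(skip_zero)) {
    warning(sum(skip_zero), " zero-variance EC(s) skipped")
  }
  testable <- colnames(m)[prev >= prevalence_min & !skip_zero]
  cluster_terms <- grep("^\\.cluster", colnames(mm), value = TRUE)

  rows <- purrr::map_dfr(testable, function(ec) {
    x <- m[, ec]
    nz <- x[x > 0]
    pseudo <- min(nz) / 2
    fit <- stats::lm(log10(x + pseudo) ~ ., data = df)
    co <- summary(fit)$coefficients
    keep <- intersect(rownames(co), cluster_terms)
    if (length(keep) == 0) return(NULL)
    tibble::tibble(
      ec = ec,
      cluster = sub("^\\.cluster", "", keep),
      coef = co[keep, "Estimate"],
      p = co[keep, "Pr(>|t|)"]
    )
  })
  if (nrow(rows) == 0) {
    out <- tibble::tibble(ec = character(0), cluster = character(0),
                          coef = numeric(0), p = numeric(0), q = numeric(0),
                          direction = character(0))
    class(out) <- c("ec_association", class(out))
    return(out)
  }
  rows$q <- stats::p.adjust(rows$p, method = "BH")
  rows$direction <- ifelse(rows$coef > 0, "positive", "negative")
  class(rows) <- c("ec_association", class(rows))
  rows
}

#' Read an EC-to-compound mapping table
#'
#' The mapping TSV has columns `ec`, `compound` and `role`
#' (`"production"` or `"degradation"`). EC identifiers must be four dotted
#' fields of digits or `-`.
#'
#' @param path Path to the mapping TSV.
#' @return Validated tibble.
#' @export
read_compound_map <- function(path) {
  cmap <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_compound_map(cmap)
}

#' @rdname read_compound_map
#' @param cmap A compound-map data frame to validate.
#' @export
validate_compound_map <- function(cmap) {
  needed <- c("ec", "compound", "role")
  if (!all(needed %in% names(cmap))) {
    stop("compound map needs columns: ", paste(needed, collapse = ", "))
  }
  bad <- !grepl("^([0-9]+|-)(\\.([0-9]+|-)){3}$", cmap$ec)
  if (any(bad)) {
    stop("invalid EC identifier(s): ",
         paste(utils::head(cmap$ec[bad], 5), collapse = ", "))
  }
  if (!all(cmap$role %in% c("production", "degradation"))) {
    stop("role must be 'production' or 'degradation'")
  }
  tibble::as_tibble(cmap)
}

#' Map significant EC associations to health-relevant compounds
#'
#' Joins ECs significant at `q <= q_max` to the compound map and summarizes,
#' per compound and cluster, the number of supporting ECs and the net
#' direction: among positively associated ECs, a production-role majority
#' yields `"production-enriched"`, a degradation majority
#' `"degradation-enriched"`, and a tie `"balanced"`.
#'
#' @param assoc An association table from [associate()].
#' @param cmap Compound map tibble (`ec`, `compound`, `role`).
#' @param q_max Significance threshold on q-values (default 0.05).
#' @return Tibble with `compound`, `cluster`, `n_ec`, `n_production`,
#'   `n_degradation`, `direction`; the number of significant but unmapped
#'   ECs is in attribute `"n_unmapped"`.
#' @export
map_compounds <- function(assoc, cmap, q_max = 0.05) {
  cmap <- validate_compound_map(cmap)
  if (nrow(cmap) == 0) stop("compound map is empty")
  sig <- assoc[!is.na(assoc$q) & assoc$q <= q_max, , drop = FALSE]
  unmapped <- setdiff(unique(sig$ec), cmap$ec)
  joined <- dplyr::inner_join(sig, cmap, by = "ec",
                              relationship = "many-to-many")
  out <- joined |>
    dplyr::group_by(.data$compound, .data$cluster) |>
    dplyr::summarise(
      n_ec = dplyr::n_distinct(.data$ec),
      n_production = sum(.data$role == "production" & .data$coef > 0),
      n_degradation = sum(.data$role == "degradation" & .data$coef > 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(direction = dplyr::case_when(
      .data$n_production > .data$n_degradation ~ "production-enriched",
      .data$n_degradation > .data$n_production ~ "degradation-enriched",
      TRUE ~ "balanced"
    ))
  attr(out, "n_unmapped") <- length(unmapped)
  out
}

#' Compare clusterings from two sequencing modalities
#'
#' Cross-tabulates cluster membership of the shared samples between two
#' enzymatic-profile models (e.g. metagenomic vs metatranscriptomic) and
#' reports the adjusted Rand index as a chance-corrected agreement measure
#' in \[-1, 1\]. A modality with a single constant cluster yields agreement
#' 0 by convention, with a warning.
#'
#' @param labels_a,labels_b Tibbles with `sample` and `cluster` (e.g. the
#'   `labels` element of an `ep_model`), or `ep_model` objects.
#' @return A list with `contingency` (table), `agreement` (adjusted Rand
#'   index) and `n_shared`.
#' @export
compare_modalities <- function(labels_a, labels_b) {
  la <- if (inherits(labels_a, "ep_model")) labels_a$labels else labels_a
  lb <- if (inherits(labels_b, "ep_model")) labels_b$labels else labels_b
  shared <- dplyr::inner_join(la, lb, by = "sample",
                              suffix = c("_a", "_b"))
  if (nrow(shared) == 0) stop("no shared samples between modalities")
  tab <- table(shared$cluster_a, shared$cluster_b)
  if (length(unique(shared$cluster_a)) < 2 ||
      length(unique(shared$cluster_b)) < 2) {
    warning("one modality has a single cluster; agreement set to 0")
    agreement <- 0
  } else {
    agreement <- mclust::adjustedRandIndex(shared$cluster_a,
                                           shared$cluster_b)
  }
  list(contingency = tab, agreement = agreement, n_shared = nrow(shared))
}
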