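#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ICST model into its cluster summary
#'
#' @param x An `icst_model` from [fit_icsts()].
#' @param ... Unused.
#' @return Tibble with one row per supported cluster (`cluster`, `icst`,
#'   `support`, `health`, `pi_fraction`, `dominant_taxa`).
#' @method tidy icst_model
#' @export
tidy.icst_model <- function(x, ...) {
  x$clusters
}

#' One-row summary of an ICST model
#'
#' @inheritParams tidy.icst_model
#' @return Tibble with `n_clusters`, `n_samples`, `n_assigned`,
#'   `n_unassigned`, `min_support`, `k_cut`.
#' @method glance icst_model
#' @export
glance.icst_model <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$clusters),
    n_samples = nrow(x$assignments),
    n_assigned = sum(x$assignments$cluster != "unassigned"),
    n_unassigned = sum(x$assignments$cluster == "unassigned"),
    min_support = x$params$min_support,
    k_cut = x$params$k_cut
  )
}

#' Tidy an enzymatic-profile model into its silhouette trace
#'
#' @param x An `ep_model` from [cluster_profiles()].
#' @param ... Unused.
#' @return Tibble with `k` and `mean_silhouette`.
#' @method tidy ep_model
#' @export
tidy.ep_model <- function(x, ...) {
  x$silhouette
}

#' One-row summary of an enzymatic-profile model
#'
#' @inheritParams tidy.ep_model
#' @return Tibble with `k`, `mean_silhouette`, `metric`, `n_samples`.
#' @method glance ep_model
#' @export
glance.ep_model <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    mean_silhouette =
      x$silhouette$mean_silhouette[x$silhouette$k == x$k],
    metric = x$metric,
    n_samples = nrow(x$labels)
  )
}

#' Tidy a PCoA ordination into sample coordinates
#'
#' @param x A `pcoa_ord` from [pcoa_ordination()].
#' @param ... Unused.
#' @return Tibble of sample coordinates.
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) {
  x$coordinates
}

#' One-row summary of a PCoA ordination
#'
#' @inheritParams tidy.pcoa_ord
#' @return Tibble with explained-variance fractions per returned axis and
#'   the count of negative eigenvalues.
#' @method glance pcoa_ord
#' @export
glance.pcoa_ord <- function(x, ...) {
  out <- tibble::as_tibble(as.list(stats::setNames(
    x$explained, paste0("explained_axis", seq_along(x$explained))
  )))
  out$n_negative_eigenvalues <- length(x$negative_eigenvalues)
  out
}
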