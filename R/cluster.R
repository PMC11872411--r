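#' Graph-based clustering of pooled cells
#'
#' Builds a k-nearest-neighbour graph on the pooled (scaled) marker space
#' (Euclidean distance, exact search) and partitions it with Louvain
#' community detection at the given resolution. Cluster granularity is
#' data-dependent: the number of communities is an outcome, not a contract.
#'
#' @param cohort a preprocessed (`scaled`) `cgps_cohort` with at least 2
#'   cells.
#' @param k_neighbors neighbourhood size of the kNN graph (must be smaller
#'   than the number of clustered cells).
#' @param resolution Louvain resolution; higher values give more, smaller
#'   communities.
#' @param seed integer seed for the (randomised) Louvain optimisation.
#' @param cells_per_subject optional per-subject subsample size: clustering
#'   cost grows with pooled cell count, and a few hundred cells per subject
#'   are enough to resolve subpopulations down to ~1% frequency. `NULL`
#'   clusters every cell.
#' @param embedding if `TRUE`, also computes a 2-D UMAP embedding of the
#'   clustered cells (visualisation only; nothing downstream may depend on
#'   it). Requires the `uwot` package.
#' @return A `cgps_clusters` object: `labels` (tibble: `.cell` row index
#'   into the cohort's cell table, `subject_id`, `cluster`), `composition`
#'   (per cluster and subject group: cell count and within-cluster
#'   fraction), the parameters, and optionally `embedding`.
#' @export
cluster_cells <- function(cohort, k_neighbors = 20, resolution = 0.8,
                          seed = 1, cells_per_subject = NULL,
                          embedding = FALSE) {
  stopifnot(inherits(cohort, "cgps_cohort"))
  if (!cohort$scaled) {
    abort("cluster_cells expects a scaled cohort (see scale_and_regress)")
  }
  idx <- seq_len(nrow(cohort$cells))
  if (!is.null(cells_per_subject)) {
    set.seed(seed)
    idx <- unlist(lapply(split(idx, cohort$cells$subject_id), function(ii) {
      if (length(ii) <= cells_per_subject) ii
      else sort(sample(ii, cells_per_subject))
    }), use.names = FALSE)
  }
  x <- as.matrix(cohort$cells[idx, cohort$markers])
  if (nrow(x) < 2) abort("need at least 2 cells to cluster")
  if (k_neighbors >= nrow(x)) {
    abort("k_neighbors must be smaller than the number of clustered cells")
  }
  nn <- BiocNeighbors::findKNN(x, k = k_neighbors)
  edges <- cbind(rep(seq_len(nrow(x)), k_neighbors), as.vector(nn$index))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  cluster <- as.integer(igraph::membership(comm)) - 1L   # clusters 0, 1, ...

  labels <- tibble(
    .cell = idx,
    subject_id = cohort$cells$subject_id[idx],
    cluster = cluster
  )
  grp <- cohort$subjects$group[match(labels$subject_id,
                                     cohort$subjects$subject_id)]
  composition <- labels |>
    mutate(group = grp) |>
    count(.data$cluster, .data$group, name = "n") |>
    group_by(.data$cluster) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()

  emb <- NULL
  if (embedding) {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      abort("the 'uwot' package is required for embedding = TRUE")
    }
    set.seed(seed)
    emb <- uwot::umap(x, n_neighbors = min(k_neighbors, nrow(x) - 1))
    colnames(emb) <- c("umap1", "umap2")
  }
  structure(
    list(labels = labels, composition = composition,
         k_neighbors = k_neighbors, resolution = resolution, seed = seed,
         embedding = emb),
    class = "cgps_clusters"
  )
}

#' @export
print.cgps_clusters <- function(x, ...) {
  cat(sprintf("<cgps_clusters> %d cells in %d clusters (k = %d, resolution = %g)\n",
              nrow(x$labels), length(unique(x$labels$cluster)),
              x$k_neighbors, x$resolution))
  invisible(x)
}

#' Tidy cluster composition
#'
#' @param x a `cgps_clusters`.
#' @param ... unused.
#' @return Tibble: cluster, group, cell count, within-cluster fraction.
#' @method tidy cgps_clusters
#' @export
tidy.cgps_clusters <- function(x, ...) x$composition

#' Identify the disease-associated cluster
#'
#' Returns the cluster with the largest fraction of cells originating from
#' the disease group, provided that fraction reaches `min_fraction`; ties
#' are broken towards the larger absolute disease cell count. Cluster
#' labels are arbitrary, so the answer is invariant under relabelling.
#'
#' @param clusters a `cgps_clusters`.
#' @param disease_group subject group whose cells define the association
#'   (default `"cGVHD"`).
#' @param min_fraction minimum within-cluster fraction of disease-group
#'   cells for a cluster to qualify.
#' @return The cluster id (integer).
#' @export
identify_disease_cluster <- function(clusters, disease_group = "cGVHD",
                                     min_fraction = 0.75) {
  stopifnot(inherits(clusters, "cgps_clusters"))
  comp <- clusters$composition
  if (!disease_group %in% comp$group) {
    abort(paste0("composition table has no cells of group '", disease_group, "'"))
  }
  cand <- comp |>
    group_by(.data$cluster) |>
    summarise(
      frac = sum(.data$fraction[.data$group == disease_group]),
      n_disease = sum(.data$n[.data$group == disease_group]),
      .groups = "drop"
    ) |>
    filter(.data$frac >= min_fraction) |>
    arrange(dplyr::desc(.data$frac), dplyr::desc(.data$n_disease))
  if (nrow(cand) == 0) {
    abort(sprintf(
      "no disease-associated cluster: no cluster reaches %s fraction %.2f",
      disease_group, min_fraction))
  }
  top <- filter(cand, abs(.data$frac - cand$frac[1]) < 1e-12)
  top$cluster[which.max(top$n_disease)]
}

#' Rank markers defining a cluster
#'
#' Per marker, a two-sided Wilcoxon rank-sum test (tie-corrected normal
#' approximation) of in-cluster versus out-of-cluster expression, with the
#' median difference as the effect size. Markers are `selected` when
#' p < `alpha` and |median difference| exceeds `effect_floor`, capped at the
#' `top_n` largest effects.
#'
#' @param cohort the clustered `cgps_cohort`.
#' @param clusters the `cgps_clusters` from [cluster_cells()].
#' @param cluster cluster id whose markers to rank.
#' @param alpha significance cutoff.
#' @param effect_floor minimum |median difference| (scaled units).
#' @param top_n cap on the number of selected markers.
#' @return Tibble: marker, statistic, p_value, direction, median_diff,
#'   selected; ordered by |median_diff| decreasing.
#' @export
rank_cluster_markers <- function(cohort, clusters, cluster, alpha = 1e-4,
                                 effect_floor = 0.5, top_n = 8) {
  stopifnot(inherits(cohort, "cgps_cohort"), inherits(clusters, "cgps_clusters"))
  lab <- clusters$labels
  if (!cluster %in% lab$cluster) abort(paste0("no such cluster: ", cluster))
  in_idx <- lab$.cell[lab$cluster == cluster]
  out_idx <- lab$.cell[lab$cluster != cluster]
  if (length(in_idx) < 2) abort("cluster has fewer than 2 cells")
  res <- purrr::map_dfr(cohort$markers, function(mk) {
    xi <- cohort$cells[[mk]][in_idx]
    xo <- cohort$cells[[mk]][out_idx]
    wt <- wilcoxon_rank_sum(xi, xo, mode = "normal")
    md <- median(xi) - median(xo)
    tibble(marker = mk, statistic = wt$statistic, p_value = wt$p_value,
           direction = ifelse(md >= 0, "up", "down"), median_diff = md)
  })
  res <- arrange(res, dplyr::desc(abs(.data$median_diff)))
  res$selected <- res$p_value < alpha & abs(res$median_diff) > effect_floor &
    seq_len(nrow(res)) <= top_n
  res
}
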