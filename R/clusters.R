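#' Project individuals onto principal components
#'
#' Column-centred PCA of a dosage matrix, components ordered by decreasing
#' explained variance.  Six components is the conventional input to the
#' downstream community detection.
#'
#' @param dosage individuals x variants numeric matrix.
#' @param n_components number of components to return (default 6).
#' @return individuals x `n_components` score matrix.
#' @export
project_principal_components <- function(dosage, n_components = 6L) {
  dosage <- as.matrix(dosage)
  if (n_components < 1) stop("project_principal_components: n_components must be >= 1")
  pc <- stats::prcomp(dosage, center = TRUE, scale. = FALSE)
  if (n_components > ncol(pc$x))
    stop(sprintf(paste0("project_principal_components: requested %d components ",
                        "but the matrix supports at most %d (rank limit)"),
                 n_components, ncol(pc$x)))
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- rownames(dosage)
  scores
}

#' Cluster assignment container
#'
#' @param sample_id,cluster parallel vectors assigning each analyzed
#'   individual to exactly one cluster.
#' @param phenotype optional parallel phenotype vector ("case"/"control");
#'   enables per-cluster case/control tallies and filtering.
#' @return data frame of class `cluster_assignment`.
#' @export
cluster_assignment <- function(sample_id, cluster, phenotype = NULL) {
  if (anyDuplicated(sample_id))
    stop("cluster_assignment: each individual must appear exactly once")
  out <- data.frame(sample_id = as.character(sample_id),
                    cluster = as.character(cluster), stringsAsFactors = FALSE)
  if (!is.null(phenotype)) out$phenotype <- as.character(phenotype)
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d individuals in %d clusters\n",
              nrow(x), length(unique(x$cluster))))
  if (!is.null(x$phenotype)) print(table(x$cluster, x$phenotype))
  invisible(x)
}

#' Louvain community detection on a k-nearest-neighbour graph
#'
#' Builds a symmetric unweighted k-nearest-neighbour graph over the principal
#' component coordinates and partitions it by Louvain modularity
#' optimisation.  The vertex order seen by the algorithm is fixed by `seed`,
#' making the partition reproducible.
#'
#' @param coords individuals x components coordinate matrix (rownames are
#'   sample ids).
#' @param k_neighbors neighbours per individual (default 20; must be >= 1 and
#'   < the number of individuals).
#' @param seed integer seed.
#' @param phenotype optional named phenotype vector for per-cluster tallies.
#' @return a [cluster_assignment()].
#' @export
louvain_cluster <- function(coords, k_neighbors = 20L, seed = 1L,
                            phenotype = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- sprintf("S%05d", seq_len(n))
  if (n == 1L)
    return(cluster_assignment(ids, "C1",
                              if (!is.null(phenotype)) phenotype[ids]))
  if (k_neighbors < 1 || k_neighbors >= n)
    stop("louvain_cluster: k_neighbors must be >= 1 and < number of individuals")
  if (all(stats::dist(coords[seq_len(min(n, 50L)), , drop = FALSE]) < 1e-12) &&
      all(abs(sweep(coords, 2, coords[1, ], `-`)) < 1e-12)) {
    warning("louvain_cluster: all coordinates identical; returning one cluster")
    return(cluster_assignment(ids, rep("C1", n),
                              if (!is.null(phenotype)) phenotype[ids]))
  }
  nn <- knn_indices(coords, k_neighbors)
  edges <- cbind(rep(seq_len(n), each = k_neighbors), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- withr_seed(seed, igraph::cluster_louvain(g))
  memb <- igraph::membership(comm)
  # stable labels: clusters numbered by decreasing size, ties by first member
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  cluster_assignment(ids, paste0("C", relab[as.character(memb)]),
                     if (!is.null(phenotype)) phenotype[ids])
}

# k nearest neighbours by blocked Euclidean distance (avoids forming the
# full n x n matrix for large cohorts).
knn_indices <- function(coords, k, block = 1024L) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, `+`) - 2 * coords[idx, , drop = FALSE] %*% t(coords)
    d2[cbind(seq_along(idx), idx)] <- Inf     # exclude self
    out[idx, ] <- t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
  }
  out
}

#' Drop clusters with too few cases or controls
#'
#' Clusters failing the minima are removed and their individuals excluded
#' from association tests.
#'
#' @param assignment a [cluster_assignment()] with phenotype.
#' @param min_cases,min_controls per-cluster minima (default 1 each).
#' @return the filtered [cluster_assignment()].
#' @export
filter_clusters <- function(assignment, min_cases = 1L, min_controls = 1L) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            !is.null(assignment$phenotype))
  tab <- table(assignment$cluster, assignment$phenotype)
  cases <- if ("case" %in% colnames(tab)) tab[, "case"] else rep(0L, nrow(tab))
  ctrls <- if ("control" %in% colnames(tab)) tab[, "control"] else rep(0L, nrow(tab))
  keep <- rownames(tab)[cases >= min_cases & ctrls >= min_controls]
  if (length(keep) == 0)
    stop("filter_clusters: no cluster satisfies the case/control minima")
  dropped <- setdiff(rownames(tab), keep)
  if (length(dropped))
    message(sprintf("filter_clusters: dropped %d cluster(s) (%s), %d individuals",
                    length(dropped), paste(dropped, collapse = ", "),
                    sum(assignment$cluster %in% dropped)))
  out <- assignment[assignment$cluster %in% keep, , drop = FALSE]
  class(out) <- c("cluster_assignment", "data.frame")
  out
}
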