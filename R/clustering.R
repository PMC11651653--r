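#' Build the response-profile feature matrix
#'
#' Concatenates each neuron's trial-averaged miss trace after its hit trace,
#' giving `2 * L` features per neuron (386 at the standard L = 193).
#'
#' @param averages An `outcome_averages` object, or a list of them (one per
#'   session) sharing the same `L`, which are stacked row-wise.
#' @return neurons x (2L) numeric matrix.
#' @export
build_features <- function(averages) {
  if (inherits(averages, "outcome_averages")) averages <- list(averages)
  Ls <- vapply(averages, `[[`, numeric(1), "L")
  stop_if_not(length(unique(Ls)) == 1, "all sessions must share the same L")
  X <- do.call(rbind, lapply(averages, function(a) cbind(a$hit, a$miss)))
  stop_if_not(all(is.finite(X)), "feature matrix contains missing values")
  X
}

#' PCA reduction of profile features
#'
#' Column-centred principal components capturing the temporal response
#' profiles. Returns the score matrix, explained-variance fractions for a
#' scree plot, and an advisory elbow suggestion (largest second difference of
#' the scree); the component count itself is a user choice (default 9).
#'
#' @param X neurons x features matrix.
#' @param n_components Number of components to keep (default 9).
#' @return List `scores`, `explained_var` (all components), `rotation`,
#'   `center`, `elbow_suggestion`.
#' @export
pca_reduce <- function(X, n_components = 9) {
  stop_if_not(n_components >= 1 && n_components <= min(dim(X)),
              "n_components must be <= min(n, p)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  elbow <- if (length(ev) >= 3) which.max(diff(diff(ev))) + 1L else 1L
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_var = ev,
       rotation = pc$rotation[, seq_len(n_components), drop = FALSE],
       center = pc$center,
       elbow_suggestion = elbow)
}

# kNN affinity matrix, symmetrized by union (an edge exists if either point
# lists the other among its n_neighbors nearest).
knn_affinity <- function(scores, n_neighbors) {
  D <- as.matrix(stats::dist(scores))
  n <- nrow(D)
  stop_if_not(n_neighbors >= 1 && n_neighbors < n,
              "n_neighbors must be in [1, n - 1]")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])
    nb <- setdiff(nb, i)[seq_len(n_neighbors)]
    A[i, nb] <- 1
  }
  pmax(A, t(A))
}

#' Spectral clustering on a nearest-neighbour graph
#'
#' Builds a symmetrized kNN affinity graph, embeds it with the eigenvectors of
#' the symmetric normalized graph Laplacian belonging to the `n_clusters`
#' smallest eigenvalues (rows normalized to unit length), and partitions the
#' embedding with k-means under a fixed seed.
#'
#' @param scores neurons x dims matrix (typically PCA scores).
#' @param n_neighbors Neighbours per point for the affinity graph.
#' @param n_clusters Number of clusters (>= 2).
#' @param seed Integer seed for the k-means initialisation.
#' @param nstart k-means restarts (default 10).
#' @return Integer label vector (1-based).
#' @export
spectral_cluster <- function(scores, n_neighbors, n_clusters, seed,
                             nstart = 10) {
  stop_if_not(n_clusters >= 2, "n_clusters must be >= 2")
  A <- knn_affinity(scores, n_neighbors)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  n_comp <- igraph::components(g)$no
  if (n_comp > n_clusters)
    stop(sprintf(paste("kNN graph has %d connected components but only %d",
                       "clusters requested; raise n_neighbors"),
                 n_comp, n_clusters), call. = FALSE)
  d <- rowSums(A)
  d_inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- diag(nrow(A)) - (d_inv_sqrt %o% d_inv_sqrt) * A
  ei <- eigen(L, symmetric = TRUE)
  k <- n_clusters
  emb <- ei$vectors[, ncol(ei$vectors):(ncol(ei$vectors) - k + 1L), drop = FALSE]
  norms <- sqrt(rowSums(emb^2))
  emb <- emb / ifelse(norms > 0, norms, 1)
  km <- with_seed_(seed, stats::kmeans(emb, centers = k, nstart = nstart,
                                       iter.max = 100))
  as.integer(km$cluster)
}

#' Mean silhouette score with the per-sample breakdown
#'
#' For sample `i` in cluster `C_I`: `a_i` is its mean distance to the other
#' members of `C_I`, `b_i` the smallest mean distance to any other cluster,
#' and `s_i = (b_i - a_i) / max(a_i, b_i)`. Euclidean distance in the supplied
#' space; singleton clusters get `s_i = 0`.
#'
#' @param X Points (rows) in the space the clustering was done in.
#' @param labels Integer cluster labels.
#' @return List `mean_s` and `breakdown` (data.frame `label`, `a`, `b`, `s`).
#' @export
silhouette_mean <- function(X, labels) {
  labels <- as.integer(labels)
  stop_if_not(length(unique(labels)) >= 2, "need at least two clusters")
  D <- as.matrix(stats::dist(X))
  n <- nrow(D)
  stop_if_not(length(labels) == n, "labels do not match rows of X")
  uniq <- sort(unique(labels))
  # mean distance from each point to each cluster
  sums <- vapply(uniq, function(cl) rowSums(D[, labels == cl, drop = FALSE]),
                 numeric(n))
  sizes <- vapply(uniq, function(cl) sum(labels == cl), integer(1))
  a <- b <- s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], uniq)
    if (sizes[ci] > 1) {
      a[i] <- sums[i, ci] / (sizes[ci] - 1)
      b[i] <- min(sums[i, -ci] / sizes[-ci])
      s[i] <- (b[i] - a[i]) / max(a[i], b[i])
    } else {
      a[i] <- 0
      b[i] <- min(sums[i, -ci] / sizes[-ci])
      s[i] <- 0
    }
  }
  list(mean_s = mean(s),
       breakdown = data.frame(label = labels, a = a, b = b, s = s))
}

#' Silhouette-maximizing grid search over clustering hyperparameters
#'
#' Runs [spectral_cluster()] for every (n_neighbors, n_clusters) grid cell and
#' keeps the model with the highest mean silhouette (computed in the same
#' space as the clustering). Ties are broken toward fewer clusters, then fewer
#' neighbours; cells that fail (e.g. a disconnected graph) are recorded as NA.
#'
#' @param scores neurons x dims matrix.
#' @param n_neighbors_grid Candidate neighbour counts (default `seq(5, 50, 5)`).
#' @param n_clusters_grid Candidate cluster counts (default `2:15`).
#' @param seed Seed for the k-means stage (shared across cells).
#' @return A `cluster_model` list: `labels`, `n_neighbors`, `n_clusters`,
#'   `mean_silhouette`, `grid` (the full search table), `silhouette`.
#' @export
hyperparameter_search <- function(scores,
                                  n_neighbors_grid = seq(5, 50, by = 5),
                                  n_clusters_grid = 2:15,
                                  seed = 1) {
  n_neighbors_grid <- n_neighbors_grid[n_neighbors_grid < nrow(scores)]
  stop_if_not(length(n_neighbors_grid) > 0 && length(n_clusters_grid) > 0,
              "empty hyperparameter grid")
  grid <- expand.grid(n_neighbors = n_neighbors_grid,
                      n_clusters = n_clusters_grid)
  grid$mean_silhouette <- NA_real_
  labels_list <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    lab <- tryCatch(
      spectral_cluster(scores, grid$n_neighbors[g], grid$n_clusters[g], seed),
      error = function(e) NULL)
    if (is.null(lab) || length(unique(lab)) < 2) next
    labels_list[[g]] <- lab
    grid$mean_silhouette[g] <- silhouette_mean(scores, lab)$mean_s
  }
  ok <- which(is.finite(grid$mean_silhouette))
  stop_if_not(length(ok) > 0, "every grid cell failed; raise n_neighbors")
  ord <- ok[order(-grid$mean_silhouette[ok], grid$n_clusters[ok],
                  grid$n_neighbors[ok])]
  best <- ord[1]
  structure(list(labels = labels_list[[best]],
                 n_neighbors = grid$n_neighbors[best],
                 n_clusters = grid$n_clusters[best],
                 mean_silhouette = grid$mean_silhouette[best],
                 grid = grid,
                 silhouette = silhouette_mean(scores, labels_list[[best]]),
                 seed = seed),
            class = "cluster_model")
}

#' Cluster-composition test against the population group ratio
#'
#' For each cluster, tests whether its proportion of lesioned-group neurons
#' differs from the population proportion (two-sided one-proportion Z test)
#' and reports a display proportion normalized to the overall sample, so 0.5
#' means the cluster mirrors the population mix:
#' `norm = (p/p0) / (p/p0 + (1-p)/(1-p0))`.
#'
#' @param labels Integer cluster labels per neuron.
#' @param lesioned Logical per neuron (TRUE = lesioned group).
#' @return data.frame per cluster: `cluster`, `n`, `n_lesioned`, `prop`,
#'   `norm_prop`, `z`, `p_value` (NA rows for empty clusters are skipped).
#' @export
composition_test <- function(labels, lesioned) {
  stop_if_not(any(lesioned) && any(!lesioned),
              "both groups must be present overall")
  p0 <- mean(lesioned)
  uniq <- sort(unique(labels))
  rows <- lapply(uniq, function(cl) {
    in_cl <- labels == cl
    n <- sum(in_cl)
    if (n == 0) return(NULL)
    x <- sum(lesioned[in_cl])
    p <- x / n
    z <- (p - p0) / sqrt(p0 * (1 - p0) / n)
    norm_prop <- (p / p0) / (p / p0 + (1 - p) / (1 - p0))
    data.frame(cluster = cl, n = n, n_lesioned = x, prop = p,
               norm_prop = norm_prop, z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  do.call(rbind, rows)
}
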