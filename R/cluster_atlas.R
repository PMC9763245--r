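#' Embed disease risk profiles in 2D with UMAP
#'
#' Nonlinear projection of the diseases x biomarkers log-HR matrix to two
#' dimensions (Euclidean metric on the input rows). The run is deterministic
#' given the seed (single-threaded optimization).
#'
#' @param submatrix Diseases x biomarkers log-HR matrix.
#' @param n_neighbors UMAP neighborhood size (2 <= n_neighbors <= m).
#' @param min_dist UMAP minimum embedding distance.
#' @param seed Integer seed.
#' @return m x 2 coordinate matrix (rownames preserved).
#' @export
embed_2d <- function(submatrix, n_neighbors = 15L, min_dist = 0.1, seed = 1L) {
  m <- nrow(submatrix)
  if (n_neighbors < 2) stop("n_neighbors must be >= 2")
  if (m < n_neighbors)
    stop("number of diseases (", m, ") is smaller than n_neighbors (",
         n_neighbors, ")")
  set.seed(seed)
  emb <- suppressMessages(uwot::umap(
    submatrix, n_neighbors = n_neighbors, min_dist = min_dist,
    n_components = 2L, metric = "euclidean",
    n_threads = 1L, n_sgd_threads = 0L, verbose = FALSE
  ))
  rownames(emb) <- rownames(submatrix)
  colnames(emb) <- c("x", "y")
  emb
}

#' Density-based clustering (DBSCAN)
#'
#' Standard DBSCAN: points with at least `min_samples` neighbors within
#' radius `eps` (the point itself included) are core points; clusters are the
#' connected components of density-reachability; points reachable from no
#' core point are labeled 0 (noise).
#'
#' @param embedding Numeric matrix of coordinates (rows = points).
#' @param eps Neighborhood radius (> 0).
#' @param min_samples Minimum neighborhood size for a core point (>= 1).
#' @return Integer label vector (0 = noise), named by rownames.
#' @export
density_cluster <- function(embedding, eps, min_samples = 5L) {
  if (eps <= 0) stop("eps must be > 0")
  if (min_samples < 1) stop("min_samples must be >= 1")
  m <- nrow(embedding)
  d <- as.matrix(stats::dist(embedding))
  nb <- lapply(seq_len(m), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- integer(m)
  cl <- 0L
  for (i in seq_len(m)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(nb[[i]], i)
    while (length(frontier)) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- union(frontier, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  names(labels) <- rownames(embedding)
  labels
}

#' Internal cluster-quality indices
#'
#' Silhouette coefficient (mean over points; via [cluster::silhouette()]),
#' Calinski-Harabasz index and Davies-Bouldin score, computed on the supplied
#' coordinates. With `noise = "own_cluster"` (default) the noise-labeled
#' points form one additional group, so labelings that discard many points as
#' noise are penalized by the scattered noise group; with `noise = "exclude"`
#' noise points are dropped before scoring. All three indices are invariant
#' to relabeling clusters. At least 2 non-noise clusters are required.
#'
#' @param embedding Coordinate matrix.
#' @param labels Integer labels, 0 = noise.
#' @param noise How noise points enter the scores.
#' @return Named list `silhouette`, `calinski_harabasz`, `davies_bouldin`
#'   (all `NA` when fewer than 2 non-noise clusters remain).
#' @export
cluster_quality <- function(embedding, labels,
                            noise = c("own_cluster", "exclude")) {
  noise <- match.arg(noise)
  k_real <- length(setdiff(unique(labels), 0L))
  if (noise == "own_cluster") {
    keep <- rep(TRUE, length(labels))
    # relabel noise as its own group (max label + 1) for scoring
    l_all <- labels
    l_all[l_all == 0L] <- max(labels) + 1L
  } else {
    keep <- labels != 0L
    l_all <- labels
  }
  x <- embedding[keep, , drop = FALSE]
  l <- l_all[keep]
  k <- length(unique(l))
  if (k_real < 2L || k < 2L || nrow(x) <= k)
    return(list(silhouette = NA_real_, calinski_harabasz = NA_real_,
                davies_bouldin = NA_real_))
  sil <- mean(cluster::silhouette(as.integer(factor(l)), stats::dist(x))[, 3])
  n <- nrow(x)
  centroids <- apply(x, 2L, function(col) tapply(col, l, mean))
  centroids <- matrix(centroids, nrow = k)
  grand <- colMeans(x)
  sizes <- as.integer(table(l))
  wss <- 0; dispersion <- numeric(k)
  lv <- sort(unique(l))
  for (i in seq_len(k)) {
    pts <- x[l == lv[i], , drop = FALSE]
    dd <- sweep(pts, 2L, centroids[i, ], "-")
    wss <- wss + sum(dd^2)
    dispersion[i] <- mean(sqrt(rowSums(dd^2)))
  }
  bss <- sum(sizes * rowSums(sweep(centroids, 2L, grand, "-")^2))
  ch <- (bss / (k - 1)) / (wss / (n - k))
  cd <- as.matrix(stats::dist(centroids))
  db <- mean(vapply(seq_len(k), function(i) {
    max((dispersion[i] + dispersion[-i]) / cd[i, -i])
  }, numeric(1)))
  list(silhouette = sil, calinski_harabasz = ch, davies_bouldin = db)
}

#' Grid-searched UMAP + DBSCAN clustering of the disease atlas
#'
#' Evaluates the full Cartesian product of UMAP (`n_neighbors`, `min_dist`)
#' and DBSCAN (`eps`, `min_samples`) parameters, scoring each grid point by
#' the silhouette coefficient on the 2D embedding (see [cluster_quality()]
#' for how noise points enter the scores). Grid points yielding fewer than 2
#' clusters score `-Inf`. The winner is the maximal silhouette, with ties
#' broken by higher Calinski-Harabasz, then lower Davies-Bouldin, then
#' first-in-grid order.
#'
#' @param submatrix Diseases x biomarkers log-HR matrix.
#' @param umap_grid List with vectors `n_neighbors` and `min_dist`.
#' @param dbscan_grid List with vectors `eps` and `min_samples`.
#' @param seed Integer seed (shared by every embedding run).
#' @param noise Noise handling in the quality scores (see
#'   [cluster_quality()]).
#' @return Object of class `cluster_assignment`: `embedding` (winner's m x 2
#'   coordinates), `labels` (0 = noise), `n_clusters` (non-noise), `quality`
#'   (silhouette/CH/DB of the winner), `chosen_params`, and `grid_log`
#'   (one row per evaluated grid point).
#' @export
grid_search_clustering <- function(submatrix,
                                   umap_grid = list(
                                     n_neighbors = c(5, 10, 15, 30),
                                     min_dist = c(0, 0.1, 0.25, 0.5)),
                                   dbscan_grid = list(
                                     eps = seq(0.1, 1, by = 0.1),
                                     min_samples = c(2, 3, 5)),
                                   seed = 1L,
                                   noise = c("own_cluster", "exclude")) {
  noise <- match.arg(noise)
  if (!length(umap_grid$n_neighbors) || !length(umap_grid$min_dist) ||
      !length(dbscan_grid$eps) || !length(dbscan_grid$min_samples))
    stop("grids must be non-empty")
  m <- nrow(submatrix)
  nn_grid <- unique(umap_grid$n_neighbors)
  valid_nn <- nn_grid[nn_grid <= m & nn_grid >= 2]
  if (length(valid_nn) < length(nn_grid))
    warning("skipping n_neighbors values outside [2, ", m, "]")
  if (!length(valid_nn)) stop("no valid n_neighbors value for ", m, " diseases")
  ug <- expand.grid(n_neighbors = valid_nn,
                    min_dist = unique(umap_grid$min_dist))
  dg <- expand.grid(eps = unique(dbscan_grid$eps),
                    min_samples = unique(dbscan_grid$min_samples))
  log_rows <- vector("list", nrow(ug) * nrow(dg))
  best <- NULL; r <- 0L
  for (u in seq_len(nrow(ug))) {
    emb <- embed_2d(submatrix, ug$n_neighbors[u], ug$min_dist[u], seed = seed)
    for (v in seq_len(nrow(dg))) {
      labels <- density_cluster(emb, dg$eps[v], dg$min_samples[v])
      k <- length(setdiff(unique(labels), 0L))
      q <- cluster_quality(emb, labels, noise = noise)
      score <- if (k < 2 || is.na(q$silhouette)) -Inf else q$silhouette
      r <- r + 1L
      log_rows[[r]] <- data.frame(
        n_neighbors = ug$n_neighbors[u], min_dist = ug$min_dist[u],
        eps = dg$eps[v], min_samples = dg$min_samples[v],
        n_clusters = k, n_noise = sum(labels == 0L),
        silhouette = q$silhouette, calinski_harabasz = q$calinski_harabasz,
        davies_bouldin = q$davies_bouldin
      )
      cand <- list(score = score, q = q, emb = emb, labels = labels, k = k,
                   params = log_rows[[r]][1, 1:4])
      if (is.null(best) || .better_grid_point(cand, best)) best <- cand
    }
  }
  if (!is.finite(best$score))
    stop("every grid point yielded fewer than 2 clusters; widen the grids")
  structure(list(embedding = best$emb, labels = best$labels,
                 n_clusters = best$k, quality = best$q,
                 chosen_params = as.list(best$params),
                 grid_log = do.call(rbind, log_rows)),
            class = "cluster_assignment")
}

# Tie-break order: silhouette desc, CH desc, DB asc, first-in-grid.
.better_grid_point <- function(cand, best) {
  if (cand$score != best$score) return(cand$score > best$score)
  if (!is.finite(cand$score)) return(FALSE)
  ch_c <- cand$q$calinski_harabasz; ch_b <- best$q$calinski_harabasz
  if (!isTRUE(all.equal(ch_c, ch_b))) return(isTRUE(ch_c > ch_b))
  db_c <- cand$q$davies_bouldin; db_b <- best$q$davies_bouldin
  if (!isTRUE(all.equal(db_c, db_b))) return(isTRUE(db_c < db_b))
  FALSE
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("UMAP+DBSCAN atlas:", x$n_clusters, "clusters over",
      length(x$labels), "diseases (", sum(x$labels == 0L), "noise );",
      "silhouette", round(x$quality$silhouette, 3), "\n")
  invisible(x)
}

#' Mean hazard-ratio profile per cluster
#'
#' Per-cluster arithmetic mean of the log hazard ratios for every covariate,
#' reported back on the hazard-ratio scale (i.e. the geometric mean HR).
#' Noise-labeled diseases are excluded.
#'
#' @param labels Integer cluster labels named by disease (0 = noise).
#' @param hazards A `hazard_matrix`, or a diseases x covariates HR matrix.
#' @return Clusters x covariates matrix of mean hazard ratios.
#' @export
cluster_profile <- function(labels, hazards) {
  hr <- if (inherits(hazards, "hazard_matrix")) hazards$hr else hazards
  labels <- labels[rownames(hr)]
  keep <- !is.na(labels) & labels != 0L
  if (!any(keep)) stop("no non-noise cluster to profile")
  lhr <- log(hr[keep, , drop = FALSE])
  l <- labels[keep]
  prof <- apply(lhr, 2L, function(col) tapply(col, l, mean))
  prof <- matrix(prof, nrow = length(unique(l)),
                 dimnames = list(sort(unique(l)), colnames(hr)))
  exp(prof)
}
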