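# Two well-separated Gaussian blobs in biomarker space, as a clustering
# fixture with known membership.
make_blobs <- function(m_per = 10, p = 8, sep = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(m_per * p), m_per, p),
             matrix(rnorm(m_per * p, mean = sep), m_per, p))
  rownames(x) <- sprintf("D%03d", seq_len(2 * m_per))
  list(x = x, truth = rep(1:2, each = m_per))
}

test_that("2D embedding is deterministic and separates distant blobs", {
  b <- make_blobs(seed = 2)
  e1 <- embed_2d(b$x, n_neighbors = 5, min_dist = 0.1, seed = 3)
  e2 <- embed_2d(b$x, n_neighbors = 5, min_dist = 0.1, seed = 3)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(20L, 2L))
  expect_identical(rownames(e1), rownames(b$x))
  # blob separation survives the projection: distance between the two
  # embedded centroids exceeds the mean within-blob spread
  c1 <- colMeans(e1[b$truth == 1, ]); c2 <- colMeans(e1[b$truth == 2, ])
  spread <- mean(c(dist(e1[b$truth == 1, ]), dist(e1[b$truth == 2, ])))
  expect_gt(sqrt(sum((c1 - c2)^2)), spread)
  expect_error(embed_2d(b$x, n_neighbors = 21), "smaller than n_neighbors")
  expect_error(embed_2d(b$x, n_neighbors = 1), "n_neighbors")
})

test_that("DBSCAN matches hand-worked configurations", {
  # two tight pairs far apart, plus one isolated point
  pts <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1), c(50, 50))
  rownames(pts) <- letters[1:5]
  l <- density_cluster(pts, eps = 0.5, min_samples = 2)
  expect_identical(unname(l), c(1L, 1L, 2L, 2L, 0L))
  expect_identical(names(l), letters[1:5])

  # min_samples = 1: every point is core, singleton clusters instead of noise
  l1 <- density_cluster(pts, eps = 0.5, min_samples = 1)
  expect_identical(unname(l1), c(1L, 1L, 2L, 2L, 3L))

  # huge eps: one cluster
  expect_identical(unname(density_cluster(pts, eps = 1000, min_samples = 2)),
                   rep(1L, 5))
  # tiny eps with min_samples > 1: all noise
  expect_identical(unname(density_cluster(pts, eps = 1e-6, min_samples = 2)),
                   rep(0L, 5))

  # chain reachability: consecutive points 1 apart form a single cluster
  chain <- cbind(0:6, 0)
  expect_identical(unname(density_cluster(chain, eps = 1.1, min_samples = 2)),
                   rep(1L, 7))

  # border point: within eps of a core point but not core itself
  border <- rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1.9, 0))
  lb <- density_cluster(border, eps = 1, min_samples = 3)
  expect_identical(unname(lb), c(1L, 1L, 1L, 1L))

  expect_error(density_cluster(pts, eps = 0), "eps")
  expect_error(density_cluster(pts, eps = 1, min_samples = 0), "min_samples")
})

test_that("DBSCAN recovers two clean blobs in an embedding", {
  b <- make_blobs(seed = 4)
  emb <- embed_2d(b$x, n_neighbors = 5, min_dist = 0, seed = 5)
  # eps from the embedding scale: half the centroid separation is generous
  # for within-blob hops, far below the between-blob gap
  l <- density_cluster(emb, eps = mean(dist(emb)) / 4, min_samples = 3)
  expect_equal(length(setdiff(unique(l), 0L)), 2)
  expect_gt(mclust::adjustedRandIndex(l, b$truth), 0.9)
})

test_that("quality indices are relabel-invariant and rank obvious cases", {
  b <- make_blobs(seed = 6)
  emb <- embed_2d(b$x, n_neighbors = 5, min_dist = 0, seed = 6)
  good <- b$truth
  q1 <- cluster_quality(emb, good)
  perm <- c(2L, 1L)[good]            # swap the labels
  q2 <- cluster_quality(emb, perm)
  expect_equal(q1, q2)

  # random labels score worse on all three indices
  set.seed(7)
  bad <- sample(good)
  qb <- cluster_quality(emb, bad)
  expect_gt(q1$silhouette, qb$silhouette)
  expect_gt(q1$calinski_harabasz, qb$calinski_harabasz)
  expect_lt(q1$davies_bouldin, qb$davies_bouldin)

  # fewer than 2 real clusters -> NA scores
  expect_true(all(is.na(unlist(cluster_quality(emb, rep(1L, 20))))))
  expect_true(all(is.na(unlist(
    cluster_quality(emb, c(rep(1L, 19), 0L))))))

  # noise handling: "exclude" drops noise points, "own_cluster" keeps them
  lab_noise <- good; lab_noise[1] <- 0L
  q_ex <- cluster_quality(emb, lab_noise, noise = "exclude")
  q_ref <- cluster_quality(emb[-1, ], good[-1])
  expect_equal(q_ex, q_ref)
  q_own <- cluster_quality(emb, lab_noise, noise = "own_cluster")
  expect_false(isTRUE(all.equal(q_own$silhouette, q_ex$silhouette)))
})

test_that("grid search obeys its contract on a controlled fixture", {
  b <- make_blobs(m_per = 8, seed = 8)
  grid_u <- list(n_neighbors = c(5, 8), min_dist = c(0, 0.25))
  grid_d <- list(eps = c(0.3, 0.6, 1), min_samples = c(2, 3))
  asn <- grid_search_clustering(b$x, grid_u, grid_d, seed = 9)
  expect_s3_class(asn, "cluster_assignment")
  expect_equal(nrow(asn$grid_log), 2 * 2 * 3 * 2)
  # the winner's silhouette is the grid maximum
  expect_equal(asn$quality$silhouette,
               max(asn$grid_log$silhouette, na.rm = TRUE))
  # reported quality matches recomputation from the winner's own output
  expect_equal(asn$quality,
               cluster_quality(asn$embedding, asn$labels))
  # chosen params actually reproduce the winning labels
  emb <- embed_2d(b$x, asn$chosen_params$n_neighbors,
                  asn$chosen_params$min_dist, seed = 9)
  expect_identical(
    density_cluster(emb, asn$chosen_params$eps,
                    asn$chosen_params$min_samples),
    asn$labels)
  # determinism
  asn2 <- grid_search_clustering(b$x, grid_u, grid_d, seed = 9)
  expect_identical(asn$labels, asn2$labels)
  expect_identical(asn$chosen_params, asn2$chosen_params)

  # size-1 grid equals the direct pipeline
  one <- grid_search_clustering(
    b$x, list(n_neighbors = 5, min_dist = 0),
    list(eps = asn$chosen_params$eps, min_samples = 2), seed = 9)
  expect_equal(nrow(one$grid_log), 1)

  # out-of-range n_neighbors are skipped with a warning
  expect_warning(
    grid_search_clustering(b$x, list(n_neighbors = c(5, 99), min_dist = 0),
                           grid_d, seed = 9),
    "skipping n_neighbors")
  expect_error(
    suppressWarnings(
      grid_search_clustering(b$x, list(n_neighbors = 99, min_dist = 0),
                             grid_d)),
    "no valid n_neighbors")
  expect_error(
    grid_search_clustering(b$x, list(n_neighbors = 5, min_dist = numeric(0)),
                           grid_d),
    "non-empty")
})

test_that("cluster profiles are per-cluster geometric means of hazard ratios", {
  hr <- rbind(D001 = c(a = 2, b = 0.5),
              D002 = c(a = 8, b = 0.5),
              D003 = c(a = 1, b = 4),
              D004 = c(a = 3, b = 1))   # noise: excluded
  labels <- c(D001 = 1L, D002 = 1L, D003 = 2L, D004 = 0L)
  prof <- cluster_profile(labels, hr)
  expect_equal(dim(prof), c(2L, 2L))
  # geometric mean of 2 and 8 is 4; single-member cluster passes through
  expect_equal(prof["1", "a"], 4)
  expect_equal(prof["1", "b"], 0.5)
  expect_equal(prof["2", ], c(a = 1, b = 4))
  # sign symmetry: inverting all HRs inverts the profile
  prof_inv <- cluster_profile(labels, 1 / hr)
  expect_equal(prof_inv, 1 / prof)
  expect_error(cluster_profile(c(D001 = 0L), hr[1, , drop = FALSE]),
               "no non-noise")
})
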