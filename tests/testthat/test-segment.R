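# well-separated Gaussian blobs for clustering tests
make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  set.seed(seed)
  F <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per),
          2, centers[i, ], "+")))
  rownames(F) <- sprintf("p%03d", seq_len(nrow(F)))
  colnames(F) <- paste0("f", seq_len(ncol(F)))
  attr(F, "truth") <- rep(seq_len(nrow(centers)), each = n_per)
  F
}

test_that("k-means on well-separated blobs is perfectly stable", {
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5))
  F <- make_blobs(50, centers)
  res <- run_kmeans_stable(F, 4, n_runs = 10, seed = 3)
  expect_equal(res$stability, 1)
  expect_equal(ari(res$labels, attr(F, "truth")), 1)
  # determinism given seed
  res2 <- run_kmeans_stable(F, 4, n_runs = 10, seed = 3)
  expect_identical(res$labels, res2$labels)
  expect_identical(res$model$centroids, res2$model$centroids)
})

test_that("k = 1 gives a single label with stability 1 by convention", {
  F <- make_blobs(30, rbind(c(0, 0), c(3, 3)))
  res <- run_kmeans_stable(F, 1, seed = 1)
  expect_equal(unname(unique(res$labels)), "segment_1")
  expect_equal(res$stability, 1)
  expect_error(run_kmeans_stable(F, 100), "exceed")
})

test_that("overlapping blobs report stability below 1 without error", {
  F <- make_blobs(80, rbind(c(0, 0), c(0.4, 0), c(0, 0.4)), sd = 0.8,
                  seed = 5)
  res <- run_kmeans_stable(F, 3, n_runs = 8, seed = 5)
  expect_lt(res$stability, 1)
  expect_gte(res$stability, -1)
})

test_that("classical MDS reproduces 2-D configurations exactly", {
  set.seed(6)
  P <- matrix(rnorm(40), 20, 2)
  coords <- embed_mds(P)
  expect_equal(as.matrix(dist(coords)), as.matrix(dist(P)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(colMeans(coords), c(dim1 = 0, dim2 = 0), tolerance = 1e-10)
})

test_that("three equidistant points embed as an equilateral triangle", {
  D <- matrix(1, 3, 3) - diag(3)
  coords <- embed_mds(D)
  d <- as.matrix(dist(coords))
  expect_equal(d[upper.tri(d)], rep(1, 3), tolerance = 1e-8)
  expect_error(embed_mds(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("MDS of factor-space distances preserves centroid geometry", {
  C <- default_factor_centroids()
  coords <- embed_mds(C)
  true_d <- as.matrix(dist(C))
  emb_d <- as.matrix(dist(coords))
  expect_gte(cor(true_d[upper.tri(true_d)], emb_d[upper.tri(emb_d)]), 0.9)
})

test_that("polar sectoring follows the half-open convention", {
  coords <- rbind(origin = c(0, 0), east = c(2, 0), north = c(0, 2),
                  west = c(-2, 0))
  res <- polar_sector_segments(coords, radius_cutoff = 0.5, n_sectors = 36)
  expect_true(res["origin", "central"])
  expect_true(is.na(res["origin", "sector"]))
  expect_equal(res["east", "sector"], 0)      # theta = 0 -> sector 0
  expect_equal(res["north", "sector"], 9)     # 90 degrees
  expect_equal(res["west", "sector"], 18)     # 180 degrees
  expect_error(polar_sector_segments(coords, 0.5, n_sectors = 1),
               "at least 2")
})

test_that("uniform angles fill the 36 sectors uniformly", {
  set.seed(8)
  n <- 36000
  theta <- runif(n, 0, 2 * pi)
  r <- runif(n, 1, 2)
  coords <- cbind(r * cos(theta), r * sin(theta))
  res <- polar_sector_segments(coords, radius_cutoff = 0.5)
  counts <- table(factor(res$sector, levels = 0:35))
  p <- 1 / 36
  expect_true(all(abs(counts - n * p) <= 4 * sqrt(n * p * (1 - p))))
})

test_that("central excision marks exactly the requested fraction", {
  F <- make_blobs(100, rbind(c(0, 0)), sd = 1, seed = 9)
  expect_equal(sum(excise_central(F, 0)), 0)
  m <- excise_central(F, 0.02)
  expect_equal(sum(m), 2)
  # marked points are the innermost ones
  r <- sqrt(rowSums(scale(F, scale = FALSE)^2))
  expect_true(max(r[m]) <= min(r[!m]))
  # n = 5000, fraction 0.02 -> exactly 100
  F2 <- matrix(rnorm(10000), 5000)
  expect_equal(sum(excise_central(F2, 0.02)), 100)
  # degenerate: all identical points are all central
  F3 <- matrix(1, 7, 2, dimnames = list(paste0("r", 1:7), NULL))
  expect_equal(sum(excise_central(F3, 0.5)), 4)   # ceiling(0.5 * 7)
  expect_true(all(names(which(excise_central(F3, 0.5))) ==
                    paste0("r", 1:4)))            # id tie-break
})

test_that("nearest-centroid assignment equals the brute-force oracle", {
  set.seed(10)
  for (rep in 1:50) {
    k <- sample(2:6, 1)
    d <- sample(2:8, 1)
    F <- matrix(rnorm(200 * d), 200,
                dimnames = list(sprintf("r%03d", 1:200), NULL))
    C <- matrix(rnorm(k * d, sd = 2), k,
                dimnames = list(paste0("segment_", 1:k), NULL))
    model <- segment_model(C)
    asg <- assign_nearest_centroid(F, model)
    expect_identical(asg$labels, oracle_nearest(F, C))
  }
})

test_that("distance ties break to the lowest segment index", {
  C <- rbind(segment_1 = c(-1, 0), segment_2 = c(1, 0),
             segment_3 = c(1, 0))
  F <- rbind(r1 = c(0, 0),   # equidistant between 1 and 2 (and 3)
             r2 = c(1, 0))   # exactly at centroid 2 (== centroid 3)
  asg <- assign_nearest_centroid(F, segment_model(C))
  expect_equal(unname(asg$labels["r1"]), "segment_1")
  expect_equal(unname(asg$labels["r2"]), "segment_2")
  expect_equal(unname(asg$distances["r2", "segment_2"]), 0)
  expect_error(assign_nearest_centroid(F[, 1, drop = FALSE],
                                       segment_model(C)), "dimension")
})

test_that("one_step_reassign equals one textbook k-means iteration", {
  set.seed(11)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    d <- sample(2:6, 1)
    F <- matrix(rnorm(150 * d), 150,
                dimnames = list(sprintf("r%03d", 1:150), NULL))
    C <- F[sample(150, k), , drop = FALSE]
    rownames(C) <- paste0("segment_", 1:k)
    labels <- setNames(sample(rownames(C), 150, TRUE), rownames(F))
    step <- suppressWarnings(one_step_reassign(F, labels, segment_model(C)))
    oracle <- oracle_kmeans_step(F, C)
    expect_identical(step$labels, oracle$labels)
    expect_equal(step$model$centroids, oracle$centroids, tolerance = 1e-12)
    expect_equal(step$n_moved, sum(labels != oracle$labels))
  }
})

test_that("converged k-means labels are a fixed point of reassignment", {
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  F <- make_blobs(40, centers, seed = 12)
  km <- run_kmeans_stable(F, 3, n_runs = 5, seed = 12)
  step <- one_step_reassign(F, km$labels, km$model)
  expect_equal(step$n_moved, 0)
  expect_identical(step$labels, km$labels)
  # a single deliberately mislabeled respondent moves back
  labs <- km$labels
  labs[1] <- setdiff(km$model$segment_names, labs[1])[1]
  step2 <- one_step_reassign(F, labs, km$model)
  expect_equal(step2$n_moved, 1)
})

test_that("bootstrap move threshold is ~0 for separated data and monotone", {
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  F <- make_blobs(60, centers, sd = 0.01, seed = 13)
  labels <- setNames(paste0("segment_", attr(F, "truth")), rownames(F))
  delta <- bootstrap_move_threshold(F, labels, n_boot = 100, seed = 13)
  expect_lt(delta, 1e-6 * max(dist(centers)))
  # monotone in the quantile, on the same draws
  F2 <- make_blobs(60, centers, sd = 1.5, seed = 14)
  labels2 <- setNames(paste0("segment_", attr(F2, "truth")), rownames(F2))
  d90 <- bootstrap_move_threshold(F2, labels2, n_boot = 100,
                                  quantile = 0.90, seed = 14)
  d99 <- bootstrap_move_threshold(F2, labels2, n_boot = 100,
                                  quantile = 0.99, seed = 14)
  expect_gte(d99, d90)
  # deterministic given seed
  expect_identical(
    bootstrap_move_threshold(F2, labels2, n_boot = 50, seed = 15),
    bootstrap_move_threshold(F2, labels2, n_boot = 50, seed = 15))
})

test_that("rebuild match rate counts threshold-protected moves as matches", {
  set.seed(16)
  F <- matrix(rnorm(100), 50, 2,
              dimnames = list(sprintf("r%02d", 1:50), NULL))
  C <- rbind(segment_1 = c(-2, 0), segment_2 = c(2, 0))
  model <- segment_model(C)
  a <- assign_nearest_centroid(F, model)
  expect_equal(rebuild_match_rate(a, a, 0), 1)
  # move one respondent far across the boundary: improvement > delta
  b <- a
  i <- which.max(abs(F[, 1]))
  other <- setdiff(rownames(C), a$labels[i])
  b$labels[i] <- other
  # a's label improves on b's label by more than delta = 0 for that one
  expect_equal(rebuild_match_rate(b, a, 0), 49 / 50)
  # with a generous threshold the edge move no longer counts
  big_delta <- max(a$distances) * 2
  expect_equal(rebuild_match_rate(b, a, big_delta), 1)
})

test_that("QDA separates well-separated classes and is self-consistent", {
  centers <- rbind(c(0, 0, 0), c(6, 6, 6))
  F <- make_blobs(100, centers, sd = 0.5, seed = 17)
  labels <- setNames(paste0("segment_", attr(F, "truth")), rownames(F))
  res <- qda_allocate(F, labels, F)
  expect_gte(res$training_accuracy, 0.99)
  expect_identical(res$labels_new, res$labels_core_pred)
})

test_that("QDA matches MASS::qda on a well-conditioned instance", {
  centers <- rbind(c(0, 0), c(2.5, 0), c(0, 2.5))
  F <- make_blobs(120, centers, sd = 1, seed = 18)
  labels <- setNames(paste0("segment_", attr(F, "truth")), rownames(F))
  F_new <- make_blobs(40, centers, sd = 1, seed = 19)
  ours <- qda_allocate(F, labels, F_new)
  ref <- MASS::qda(F, grouping = labels)
  expect_identical(unname(ours$labels_new),
                   as.character(predict(ref, F_new)$class))
  expect_identical(unname(ours$labels_core_pred),
                   as.character(predict(ref, F)$class))
})

test_that("a degenerate class is ridge-regularized with a warning", {
  F <- rbind(matrix(rnorm(60), 30, 2), c(5, 5))
  rownames(F) <- sprintf("r%02d", 1:31)
  labels <- setNames(c(rep("segment_1", 30), "segment_2"), rownames(F))
  expect_warning(res <- qda_allocate(F, labels, F[1:2, , drop = FALSE]),
                 "regularized")
  expect_length(res$labels_new, 2)
})

test_that("reinstating a segment leaves other labels unchanged", {
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  F <- make_blobs(40, centers, seed = 20)
  km <- run_kmeans_stable(F, 2, n_runs = 5, seed = 20)
  seeds <- rownames(F)[101:120]
  res <- reinstate_segment(F, km$labels, seeds, "reborn")
  others <- setdiff(rownames(F), seeds)
  expect_identical(res$labels[others], km$labels[others])
  expect_true(all(res$labels[seeds] == "reborn"))
  expect_error(reinstate_segment(F, km$labels, "nope", "x"), "unknown")
})

test_that("central excision + reinstatement is label-preserving on clean geometry", {
  # separated blobs plus a tight central cluster: after excising the central
  # group, clustering the rest, appending the central segment and one
  # nearest-centroid pass, non-central respondents keep their labels
  centers <- rbind(c(-6, -6), c(6, -6), c(0, 7))
  F <- rbind(make_blobs(50, centers, sd = 0.3, seed = 21),
             matrix(rnorm(30, sd = 0.05), 15, 2))
  rownames(F) <- sprintf("q%03d", seq_len(nrow(F)))
  res <- build_segments(F, k = 3, central_fraction = 15 / nrow(F),
                        n_runs = 5, seed = 21)
  non_central <- !res$central_mask
  km <- run_kmeans_stable(F[non_central, ], 3, n_runs = 5, seed = 21)
  expect_equal(res$n_moved, 0)
  expect_identical(res$labels[non_central], km$labels)
  expect_true(all(res$labels[res$central_mask] == "central"))
})

test_that("segment recovery on default synthetic data reaches ARI 0.8", {
  pop <- shared_population()
  res <- qc_screen(pop$responses)
  Z <- standardize_responses(res$responses)
  sc <- score_factors(Z, default_factor_models())
  seg <- build_segments(sc, k = 7, seed = 17)
  expect_gte(ari(seg$labels, truth_labels(pop, names(seg$labels))), 0.8)
})
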