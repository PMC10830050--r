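# Shared fixtures and independent oracles for the test suite.

# small two-factor questionnaire for fast unit tests
mini_item_spec <- function() {
  data.frame(
    item = c(paste0("a_", 1:4), paste0("b_", 1:4), paste0("c_", 1:3)),
    factor = c(rep("fA", 4), rep("fB", 4), rep("fA", 3)),
    loading = c(0.8, 0.7, -0.75, 0.8, 0.8, -0.7, 0.75, 0.8, 0.7, 0.75, -0.7),
    block = c(rep("blk1", 4), rep("blk2", 4), rep("blk3", 3)),
    stringsAsFactors = FALSE
  )
}

mini_blocks <- function(respondent_std = "blk1", exempt = "blk3") {
  s <- mini_item_spec()
  block_spec(stats::setNames(s$block, s$item),
             filter_exempt = exempt, respondent_std = respondent_std)
}

mini_config <- function(n = 400, seed = 1, ...) {
  centroids <- rbind(seg_a = c(1.2, -1), seg_b = c(-1.2, 1))
  colnames(centroids) <- c("fA", "fB")
  args <- modifyList(list(
    n_respondents = n, n_segments = 2,
    mixing_proportions = c(0.5, 0.5),
    factor_centroids = centroids,
    item_spec = mini_item_spec(), blocks = mini_blocks(),
    outcome_rates = rbind(seg_a = c(out_yes = 0.8),
                          seg_b = c(out_yes = 0.2)),
    demographic_profiles = NULL,
    acquiescence_fraction = 0, straightliner_fraction = 0,
    central_fraction = 0, booster_fraction = 0, telephone_fraction = 0,
    seed = seed), list(...))
  do.call(synth_config, args)
}

# one default-condition population, generated once and reused across tests
shared_env <- new.env(parent = emptyenv())
shared_population <- function() {
  if (is.null(shared_env$pop))
    shared_env$pop <- generate_population(
      synth_config(n_respondents = 5000, seed = 20240117))
  shared_env$pop
}

# brute-force nearest-centroid oracle: explicit loops, lowest index on ties
oracle_nearest <- function(F, centroids) {
  labs <- character(nrow(F))
  for (i in seq_len(nrow(F))) {
    best <- Inf
    pick <- NA_integer_
    for (j in seq_len(nrow(centroids))) {
      dij <- sqrt(sum((F[i, ] - centroids[j, ])^2))
      if (dij < best - 1e-12) {
        best <- dij
        pick <- j
      }
    }
    labs[i] <- rownames(centroids)[pick]
  }
  stats::setNames(labs, rownames(F))
}

# one textbook k-means iteration from given centroids: assign then update
oracle_kmeans_step <- function(F, centroids) {
  labs <- oracle_nearest(F, centroids)
  C <- centroids
  for (s in rownames(centroids)) {
    rows <- which(labs == s)
    if (length(rows)) C[s, ] <- colMeans(F[rows, , drop = FALSE])
  }
  list(labels = labs, centroids = C)
}

# data matrix whose sample covariance is exactly Sigma (columns zero-mean)
exact_cov_data <- function(n, Sigma, seed = 1) {
  set.seed(seed)
  p <- ncol(Sigma)
  M <- matrix(stats::rnorm(n * (p + 1)), n)
  Q <- qr.Q(qr(cbind(1, M)))[, -1, drop = FALSE][, seq_len(p), drop = FALSE]
  X <- sqrt(n - 1) * Q %*% chol(Sigma)
  colnames(X) <- paste0("x", seq_len(p))
  X
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

truth_labels <- function(pop, ids) {
  pop$truth$true_segment[match(ids, pop$truth$respondent_id)]
}
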