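#' Segment model: centroids in factor space
#'
#' @param centroids segment x factor numeric matrix (rownames are segment
#'   names).
#' @param central_segment_id optional name of the neutral central segment.
#' @param mds_coords optional cached respondent x 2 MDS embedding.
#' @param move_threshold optional bootstrap move threshold (see
#'   [bootstrap_move_threshold()]).
#' @return an object of class `segment_model`.
#' @export
segment_model <- function(centroids, central_segment_id = NULL,
                          mds_coords = NULL, move_threshold = NULL) {
  centroids <- as.matrix(centroids)
  if (!all(is.finite(centroids))) stop("centroids must be finite")
  if (is.null(rownames(centroids)))
    rownames(centroids) <- paste0("segment_", seq_len(nrow(centroids)))
  if (!is.null(central_segment_id) &&
      !central_segment_id %in% rownames(centroids))
    stop("central_segment_id is not a segment name")
  if (!is.null(move_threshold) && move_threshold < 0)
    stop("move_threshold must be nonnegative")
  structure(list(centroids = centroids, k = nrow(centroids),
                 segment_names = rownames(centroids),
                 central_segment_id = central_segment_id,
                 mds_coords = mds_coords, move_threshold = move_threshold),
            class = "segment_model")
}

#' @export
print.segment_model <- function(x, ...) {
  cat("<segment_model> k = ", x$k, " segments in ", ncol(x$centroids),
      "-dimensional factor space\n", sep = "")
  cat("  segments: ", paste(x$segment_names, collapse = ", "), "\n", sep = "")
  if (!is.null(x$central_segment_id))
    cat("  central segment: ", x$central_segment_id, "\n", sep = "")
  if (!is.null(x$move_threshold))
    cat("  move threshold: ", signif(x$move_threshold, 4), "\n", sep = "")
  invisible(x)
}

# n x k Euclidean distance matrix between rows of F and centroid rows
dist_to_centroids <- function(F, centroids) {
  F <- as.matrix(F)
  C <- as.matrix(centroids)
  if (ncol(F) != ncol(C))
    stop("factor dimension (", ncol(F), ") does not match centroid dimension (",
         ncol(C), ")")
  d2 <- outer(rowSums(F^2), rep(1, nrow(C))) +
    outer(rep(1, nrow(F)), rowSums(C^2)) - 2 * F %*% t(C)
  d <- sqrt(pmax(d2, 0))
  dimnames(d) <- list(rownames(F), rownames(C))
  d
}

#' Stability-checked k-means
#'
#' Runs k-means `n_runs` times from different random starts, returns the
#' best-inertia solution and a stability score: the mean pairwise adjusted
#' Rand agreement of the run labelings. Deterministic given `seed`.
#'
#' @param F respondents x factors score matrix.
#' @param k number of clusters.
#' @param n_runs number of clustering runs compared (>= 2 for a meaningful
#'   stability score; `k = 1` returns a single label with stability 1 by
#'   convention).
#' @param seed integer seed.
#' @param iter_max k-means iteration cap per run.
#' @param nstart random initialisations within each run (default 5), so a
#'   run reports its own best solution and stability reflects structural
#'   ambiguity rather than single-start initialisation luck.
#' @return list with `model` ([segment_model]), `labels` (character vector
#'   of segment names), `stability` (mean pairwise ARI) and `inertia`
#'   (total within-cluster sum of squares of the returned solution).
#' @export
run_kmeans_stable <- function(F, k, n_runs = 20, seed = 1L, iter_max = 50L,
                              nstart = 5L) {
  F <- as.matrix(F)
  if (k > nrow(F)) stop("k cannot exceed the number of respondents")
  if (k < 1) stop("k must be positive")
  seg_names <- paste0("segment_", seq_len(k))
  if (k == 1) {
    C <- matrix(colMeans(F), 1, dimnames = list(seg_names, colnames(F)))
    return(list(model = segment_model(C),
                labels = stats::setNames(rep(seg_names, nrow(F)),
                                         rownames(F)),
                stability = 1, inertia = sum(scale(F, scale = FALSE)^2)))
  }
  if (n_runs < 2) stop("n_runs must be at least 2")
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(stage_seed(seed, paste0("kmeans_run_", i)))
    runs[[i]] <- stats::kmeans(F, centers = k, iter.max = iter_max,
                               nstart = nstart)
  }
  inertia <- vapply(runs, `[[`, numeric(1), "tot.withinss")
  best <- runs[[which.min(inertia)]]
  pairs <- utils::combn(n_runs, 2)
  ari <- apply(pairs, 2, function(p)
    mclust::adjustedRandIndex(runs[[p[1]]]$cluster, runs[[p[2]]]$cluster))
  C <- best$centers
  rownames(C) <- seg_names
  labels <- stats::setNames(seg_names[best$cluster], rownames(F))
  list(model = segment_model(C), labels = labels,
       stability = mean(ari), inertia = min(inertia))
}

#' Classical multidimensional scaling to two dimensions
#'
#' Torgerson (classical) scaling of a point configuration or a symmetric
#' distance matrix; the embedding is centered at the origin and is
#' deterministic up to rotation/reflection.
#'
#' @param x points matrix (Euclidean distances are computed) or a symmetric
#'   nonnegative distance matrix with zero diagonal (or a `dist`).
#' @param k embedding dimension (default 2).
#' @return n x k coordinate matrix.
#' @export
embed_mds <- function(x, k = 2) {
  if (inherits(x, "dist")) {
    d <- x
  } else {
    x <- as.matrix(x)
    if (nrow(x) == ncol(x) && isTRUE(all.equal(diag(x), rep(0, nrow(x)))) &&
        all(x >= 0)) {
      if (!isSymmetric(unname(x), tol = 1e-8))
        stop("distance matrix must be symmetric")
      d <- stats::as.dist(x)
    } else if (nrow(x) == ncol(x) && any(x < 0)) {
      stop("distance matrix must be nonnegative with zero diagonal")
    } else {
      d <- stats::dist(x)
    }
  }
  coords <- stats::cmdscale(d, k = k)
  coords <- scale(coords, scale = FALSE)
  attr(coords, "scaled:center") <- NULL
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  coords
}

#' Polar sectoring of a 2-D map
#'
#' Assigns polar coordinates to centered 2-D points; points with radius at
#' or below the cutoff are masked central, the rest fall into `n_sectors`
#' equal angular sectors with the half-open convention `sector =
#' floor(theta / (360 / n_sectors))`, `theta` in [0, 360) degrees.
#'
#' @param coords centered n x 2 coordinate matrix.
#' @param radius_cutoff nonnegative radius below or at which a point is
#'   central.
#' @param n_sectors number of sectors (default 36; must be >= 2).
#' @return data.frame: radius, theta (degrees), sector (integer in
#'   0..n_sectors-1, NA for central points), central (logical).
#' @export
polar_sector_segments <- function(coords, radius_cutoff, n_sectors = 36) {
  if (n_sectors < 2) stop("n_sectors must be at least 2")
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2, radius_cutoff >= 0)
  r <- sqrt(rowSums(coords^2))
  theta <- atan2(coords[, 2], coords[, 1]) * 180 / pi
  theta <- ifelse(theta < 0, theta + 360, theta)
  theta <- ifelse(theta >= 360, 0, theta)
  central <- r <= radius_cutoff
  sector <- ifelse(central, NA_integer_,
                   pmin(floor(theta / (360 / n_sectors)), n_sectors - 1L))
  data.frame(radius = r, theta = theta, sector = as.integer(sector),
             central = central, row.names = rownames(coords))
}

#' Mark the neutral central group
#'
#' The `ceiling(target_fraction * n)` respondents of smallest radius (from
#' the centroid of the configuration) are marked central; radius ties are
#' broken by respondent id.
#'
#' @param x respondents x d factor scores or 2-D coordinates.
#' @param target_fraction fraction to mark, in [0, 1) (default 0.02).
#' @return named logical mask.
#' @export
excise_central <- function(x, target_fraction = 0.02) {
  if (target_fraction < 0 || target_fraction >= 1)
    stop("target_fraction must lie in [0, 1)")
  x <- as.matrix(x)
  n <- nrow(x)
  mask <- stats::setNames(rep(FALSE, n), rownames(x))
  m <- ceiling(target_fraction * n)
  if (m == 0 || n == 0) return(mask)
  r <- sqrt(rowSums(scale(x, scale = FALSE)^2))
  ids <- if (is.null(rownames(x))) as.character(seq_len(n)) else rownames(x)
  ord <- order(r, ids)
  mask[ord[seq_len(m)]] <- TRUE
  mask
}

#' Nearest-centroid assignment
#'
#' Assigns every respondent to the segment with the nearest centroid
#' (Euclidean distance; ties go to the lowest segment index). When current
#' labels are supplied, a confusion matrix (rows = current, columns =
#' nearest) is attached.
#'
#' @param F respondents x factors score matrix.
#' @param model a [segment_model] whose centroid dimension matches `F`.
#' @param current optional character vector of current labels.
#' @return object of class `segment_assignment`: list with `labels`
#'   (named character), `distances` (n x k matrix), `source`
#'   (`"nearest"`), and optionally `confusion` and `n_moved`.
#' @export
assign_nearest_centroid <- function(F, model, current = NULL) {
  stopifnot(inherits(model, "segment_model"))
  d <- dist_to_centroids(F, model$centroids)
  idx <- apply(d, 1, which.min)        # which.min takes the lowest index on ties
  labels <- stats::setNames(model$segment_names[idx], rownames(d))
  out <- list(labels = labels, distances = d, source = "nearest")
  if (!is.null(current)) {
    out$confusion <- table(
      current = factor(current, levels = model$segment_names),
      nearest = factor(labels, levels = model$segment_names))
    out$n_moved <- sum(current != labels)
  }
  class(out) <- "segment_assignment"
  out
}

#' @export
print.segment_assignment <- function(x, ...) {
  cat("<segment_assignment> ", length(x$labels), " respondents, source = ",
      x$source, "\n", sep = "")
  print(table(x$labels))
  if (!is.null(x$n_moved)) cat("  moved: ", x$n_moved, "\n", sep = "")
  invisible(x)
}

#' One nearest-centroid reassignment pass
#'
#' Moves every respondent to its nearest centroid and recomputes the
#' centroids once from the new labels — one iteration of k-means from the
#' model's centroids. A segment left empty retains its previous centroid
#' (with a warning).
#'
#' @param F respondents x factors score matrix.
#' @param labels current segment labels (named by respondent).
#' @param model a [segment_model].
#' @return list with `labels`, `model` (updated centroids), `n_moved` and
#'   the `confusion` matrix of the move.
#' @export
one_step_reassign <- function(F, labels, model) {
  stopifnot(inherits(model, "segment_model"))
  if (!all(labels %in% model$segment_names))
    stop("labels contain unknown segment names")
  asg <- assign_nearest_centroid(F, model, current = labels)
  C <- model$centroids
  for (s in model$segment_names) {
    rows <- which(asg$labels == s)
    if (length(rows) == 0) {
      warning("segment '", s, "' is empty after reassignment; centroid kept")
      next
    }
    C[s, ] <- colMeans(F[rows, , drop = FALSE])
  }
  model2 <- segment_model(C, central_segment_id = model$central_segment_id,
                          move_threshold = model$move_threshold)
  list(labels = asg$labels, model = model2, n_moved = asg$n_moved,
       confusion = asg$confusion)
}

#' Bootstrap move threshold
#'
#' Estimates how much a respondent's assignment margin can change under
#' sampling variability alone. For each bootstrap resample (respondents
#' drawn with replacement), segment centroids are recomputed from the
#' resample's original labels and every original respondent's potential
#' improvement — distance to its assigned centroid minus distance to its
#' nearest centroid — is recorded. The threshold is the requested quantile
#' of that null distribution; a rebuild is only counted as a disagreement
#' when a respondent moves by more than this. Deterministic given `seed`.
#'
#' @param F respondents x factors score matrix.
#' @param labels current segment labels.
#' @param n_boot number of bootstrap resamples (default 500).
#' @param quantile quantile of the null distribution (default 0.95).
#' @param seed integer seed.
#' @return the threshold (scalar, >= 0).
#' @export
bootstrap_move_threshold <- function(F, labels, n_boot = 500, quantile = 0.95,
                                     seed = 1L) {
  if (n_boot < 2) stop("n_boot must be at least 2")
  F <- as.matrix(F)
  n <- nrow(F)
  segs <- sort(unique(labels))
  set.seed(stage_seed(seed, "bootstrap_threshold"))
  gaps <- numeric(0)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    C <- t(vapply(segs, function(s) {
      rows <- idx[labels[idx] == s]
      if (!length(rows)) rep(NA_real_, ncol(F))
      else colMeans(F[rows, , drop = FALSE])
    }, numeric(ncol(F))))
    rownames(C) <- segs
    C <- C[stats::complete.cases(C), , drop = FALSE]
    d <- dist_to_centroids(F, C)
    own <- d[cbind(seq_len(n), match(labels, rownames(C)))]
    nearest <- apply(d, 1, min)
    imp <- own - nearest
    gaps <- c(gaps, imp[is.finite(imp)])
  }
  unname(stats::quantile(gaps, probs = quantile, names = FALSE))
}

#' Agreement rate between two segmentations under a move threshold
#'
#' A respondent counts as matched when both assignments give the same label
#' or when the labels differ but the distance improvement from the first
#' assignment's label to the second's (measured in the second assignment's
#' distances) does not exceed `delta` — edge respondents making only a
#' small move are not counted as disagreements.
#'
#' @param assign_a,assign_b `segment_assignment` objects over the same
#'   respondents.
#' @param delta nonnegative move threshold.
#' @return fraction matched, in [0, 1].
#' @export
rebuild_match_rate <- function(assign_a, assign_b, delta = 0) {
  ids <- names(assign_a$labels)
  if (!setequal(ids, names(assign_b$labels)))
    stop("assignments cover different respondents")
  la <- assign_a$labels[ids]
  lb <- assign_b$labels[ids]
  same <- la == lb
  db <- assign_b$distances[ids, , drop = FALSE]
  common <- la %in% colnames(db)
  improvement <- rep(Inf, length(ids))
  improvement[common] <-
    db[cbind(which(common), match(la[common], colnames(db)))] -
    db[cbind(which(common), match(lb[common], colnames(db)))]
  mean(same | improvement <= delta)
}

#' Quadratic discriminant allocation of new respondents
#'
#' Fits a per-class Gaussian with class-specific covariance (priors = class
#' frequencies) on the core sample and allocates new respondents to the
#' class of highest posterior. A singular or deficient class covariance is
#' ridge-regularized (`lambda * I`) with a warning. Reports training
#' accuracy (fraction of core respondents whose prediction matches their
#' label) and, for misallocated core respondents, how often the predicted
#' segment is the one adjacent (next-nearest by centroid distance) to the
#' true one.
#'
#' @param F_core core respondents x factors matrix.
#' @param labels_core core segment labels.
#' @param F_new new (e.g. booster) respondents x factors matrix.
#' @param lambda ridge added to a non-invertible class covariance
#'   (default 1e-6, escalated as needed).
#' @return list with `labels_new`, `labels_core_pred`,
#'   `training_accuracy`, `confusion` (train), and `adjacency` (fraction of
#'   misallocations landing in the segment adjacent to the true one).
#' @export
qda_allocate <- function(F_core, labels_core, F_new, lambda = 1e-6) {
  F_core <- as.matrix(F_core)
  F_new <- as.matrix(F_new)
  segs <- sort(unique(labels_core))
  d <- ncol(F_core)
  fits <- lapply(segs, function(s) {
    rows <- which(labels_core == s)
    X <- F_core[rows, , drop = FALSE]
    mu <- colMeans(X)
    S <- if (nrow(X) > 1) stats::cov(X) else matrix(0, d, d)
    lam <- 0
    repeat {
      ch <- tryCatch(chol(S + diag(lam, d)), error = function(e) NULL)
      if (!is.null(ch)) break
      lam <- if (lam == 0) lambda else lam * 100
      if (lam > 1e6) stop("class covariance could not be regularized")
    }
    if (lam > 0)
      warning("class '", s, "' covariance regularized with lambda = ", lam)
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         logprior = log(length(rows) / length(labels_core)))
  })
  names(fits) <- segs
  score <- function(X) {
    sc <- vapply(fits, function(f) {
      z <- forwardsolve(t(f$chol), t(X) - f$mu)
      f$logprior - 0.5 * f$logdet - 0.5 * colSums(z^2)
    }, numeric(nrow(X)))
    if (nrow(X) == 1) sc <- matrix(sc, 1, dimnames = list(NULL, segs))
    segs[max.col(sc, ties.method = "first")]
  }
  pred_core <- stats::setNames(score(F_core), rownames(F_core))
  pred_new <- stats::setNames(
    if (nrow(F_new)) score(F_new) else character(0), rownames(F_new))
  acc <- mean(pred_core == labels_core)
  confusion <- table(truth = labels_core, predicted = pred_core)
  # adjacency of misallocations: predicted segment is the nearest other
  # segment (by centroid distance) to the true segment
  centroids <- t(vapply(segs, function(s)
    colMeans(F_core[labels_core == s, , drop = FALSE]), numeric(d)))
  cd <- as.matrix(stats::dist(centroids))
  mis <- which(pred_core != labels_core)
  adjacency <- if (length(mis)) {
    adj <- vapply(mis, function(i) {
      truth <- match(labels_core[i], segs)
      pred <- match(pred_core[i], segs)
      ord <- order(cd[truth, ])   # 1st entry is the segment itself
      which(ord == pred) <= 3     # predicted among the 2 nearest neighbours
    }, logical(1))
    mean(adj)
  } else NA_real_
  list(labels_new = pred_new, labels_core_pred = pred_core,
       training_accuracy = acc, confusion = confusion,
       adjacency = adjacency)
}

#' Reinstate a segment from designated seed respondents
#'
#' Re-creates a segment that an earlier clustering pass lost: the
#' designated respondents are relabelled as a new segment whose centroid is
#' their factor-space mean. Used in the audit-trail workflow where a
#' judgment-designated seed set rebuilds a segment before nearest-centroid
#' refinement.
#'
#' @param F respondents x factors matrix.
#' @param labels current labels (named by respondent).
#' @param seed_ids respondent ids forming the new segment.
#' @param name name of the reinstated segment.
#' @return list with updated `labels` and `model`.
#' @export
reinstate_segment <- function(F, labels, seed_ids, name) {
  miss <- setdiff(seed_ids, names(labels))
  if (length(miss)) stop("unknown respondent id(s) in seed set")
  if (name %in% labels) stop("segment '", name, "' already exists")
  labels[seed_ids] <- name
  segs <- sort(unique(labels))
  C <- t(vapply(segs, function(s)
    colMeans(F[names(labels)[labels == s], , drop = FALSE]),
    numeric(ncol(F))))
  rownames(C) <- segs
  list(labels = labels, model = segment_model(C))
}

#' Default hybrid segmentation path
#'
#' The package's standard segmentation procedure: mark the
#' `central_fraction` most neutral respondents (smallest radius in factor
#' space), run stability-checked k-means on the remainder, append the
#' central group as its own segment (centroid = mean of its members), then
#' apply one nearest-centroid reassignment pass over all respondents and
#' all segments. Optionally estimates the bootstrap move threshold.
#'
#' @param F respondents x factors score matrix.
#' @param k number of non-central clusters.
#' @param central_fraction fraction marked central before clustering
#'   (default 0.02; 0 disables the central segment).
#' @param n_runs k-means random starts (default 20).
#' @param seed integer seed.
#' @param move_threshold logical: estimate the bootstrap move threshold on
#'   the final labels (default FALSE).
#' @return list with `model` ([segment_model]), `labels`, `stability`,
#'   `central_mask`, `n_moved` (final reassignment pass) and `assignment`
#'   (final `segment_assignment`).
#' @export
build_segments <- function(F, k, central_fraction = 0.02, n_runs = 20,
                           seed = 1L, move_threshold = FALSE) {
  F <- as.matrix(F)
  central <- excise_central(F, central_fraction)
  km <- run_kmeans_stable(F[!central, , drop = FALSE], k,
                          n_runs = n_runs, seed = seed)
  labels <- stats::setNames(rep(NA_character_, nrow(F)), rownames(F))
  labels[!central] <- km$labels
  C <- km$model$centroids
  central_id <- NULL
  if (any(central)) {
    central_id <- "central"
    labels[central] <- central_id
    C <- rbind(C, central = colMeans(F[central, , drop = FALSE]))
  }
  model <- segment_model(C, central_segment_id = central_id)
  step <- one_step_reassign(F, labels, model)
  model <- step$model
  if (move_threshold)
    model$move_threshold <- bootstrap_move_threshold(F, step$labels,
                                                     seed = seed)
  asg <- assign_nearest_centroid(F, model)
  list(model = model, labels = step$labels, stability = km$stability,
       central_mask = central, n_moved = step$n_moved, assignment = asg)
}
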