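# Exploratory factor analysis: principal-axis factoring with optional
# varimax (orthogonal, via stats::varimax) or oblimin (oblique, gradient
# projection) rotation. Implemented here because the extraction/rotation
# machinery is not otherwise available in the package's dependency set.

#' Exploratory factor analysis by principal-axis factoring
#'
#' Iterated principal-axis extraction on the (regularized) correlation
#' matrix: communalities start at squared multiple correlations and are
#' updated from the leading eigenpairs until convergence. Rotation is
#' oblimin (default; attitude factors are expected to correlate), varimax,
#' or none. Columns are sign-normalised so the largest-magnitude loading of
#' each factor is positive. Deterministic given the data and settings.
#'
#' @param Z a `standardized_matrix` or numeric matrix (respondents x items).
#' @param n_factors number of factors to extract (must be < number of
#'   items).
#' @param rotation `"oblimin"`, `"varimax"` or `"none"`.
#' @param max_iter maximum principal-axis iterations.
#' @param tol convergence tolerance on communality change.
#' @param ridge added to the correlation-matrix diagonal when it is
#'   numerically singular.
#' @return item x factor loading matrix (pattern matrix for oblimin), with
#'   attributes `communalities`, `iterations`, `rotation` and (oblimin)
#'   `phi`, the factor correlation matrix.
#' @export
fit_efa <- function(Z, n_factors, rotation = c("oblimin", "varimax", "none"),
                    max_iter = 200L, tol = 1e-6, ridge = 1e-8) {
  rotation <- match.arg(rotation)
  M <- if (inherits(Z, "standardized_matrix")) Z$values else as.matrix(Z)
  p <- ncol(M)
  if (n_factors >= p)
    stop("n_factors must be smaller than the number of items")
  if (n_factors < 1) stop("n_factors must be positive")
  R <- stats::cor(M, use = "pairwise.complete.obs")
  if (anyNA(R)) stop("correlation matrix contains NA (insufficient overlap)")
  # regularize until invertible
  lambda <- ridge
  repeat {
    Rr <- R + diag(lambda, p)
    Rr <- stats::cov2cor(Rr)
    inv <- tryCatch(solve(Rr), error = function(e) NULL)
    if (!is.null(inv)) break
    lambda <- max(lambda * 10, 1e-6)
    if (lambda > 1) stop("correlation matrix could not be regularized")
  }
  h2 <- 1 - 1 / diag(inv)          # squared multiple correlations
  h2 <- pmin(pmax(h2, 0.05), 0.995)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Rh <- Rr
    diag(Rh) <- h2
    e <- eigen(Rh, symmetric = TRUE)
    d <- pmax(e$values[seq_len(n_factors)], 0)
    L <- e$vectors[, seq_len(n_factors), drop = FALSE] %*%
      diag(sqrt(d), n_factors)
    h2_new <- pmin(rowSums(L^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) { h2 <- h2_new; break }
    h2 <- h2_new
    if (iter >= max_iter)
      stop("principal-axis factoring did not converge in ", iter,
           " iterations")
  }
  phi <- NULL
  if (rotation == "varimax" && n_factors > 1) {
    L <- stats::varimax(L, normalize = TRUE)$loadings[, , drop = FALSE]
  } else if (rotation == "oblimin" && n_factors > 1) {
    rot <- rotate_oblimin(L)
    L <- rot$loadings
    phi <- rot$phi
  }
  # sign convention: largest-magnitude loading of each factor positive
  for (j in seq_len(ncol(L))) {
    s <- sign(L[which.max(abs(L[, j])), j])
    if (s < 0) {
      L[, j] <- -L[, j]
      if (!is.null(phi)) {
        phi[j, ] <- -phi[j, ]
        phi[, j] <- -phi[, j]
      }
    }
  }
  dimnames(L) <- list(colnames(M), paste0("F", seq_len(ncol(L))))
  attr(L, "communalities") <- stats::setNames(h2, colnames(M))
  attr(L, "iterations") <- iter
  attr(L, "rotation") <- rotation
  if (!is.null(phi)) attr(L, "phi") <- phi
  L
}

# Oblimin (quartimin, gamma = 0) rotation by gradient projection on the
# oblique manifold (columns of T of unit length); returns the pattern
# matrix and factor correlations.
rotate_oblimin <- function(A, max_iter = 500L, tol = 1e-6) {
  k <- ncol(A)
  N <- matrix(1, k, k) - diag(k)
  crit <- function(L) {
    L2 <- L^2
    sum(L2 * (L2 %*% N)) / 4
  }
  grad_L <- function(L) L * (L^2 %*% N)
  Tm <- diag(k)
  L <- A
  f <- crit(L)
  al <- 1
  for (it in seq_len(max_iter)) {
    Ti <- solve(Tm)
    L <- A %*% t(Ti)
    Gq <- grad_L(L)
    G <- -t(t(L) %*% Gq %*% Ti)
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    for (half in 1:30) {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Lt <- A %*% t(solve(Tt))
      ft <- crit(Lt)
      if (ft < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt
    f <- ft
  }
  Ti <- solve(Tm)
  list(loadings = A %*% t(Ti), phi = t(Tm) %*% Tm)
}

#' Tucker congruence between two loading matrices
#'
#' Mean per-factor Tucker coefficient after greedy sign/permutation
#' alignment of the columns of `L` to `target`. Used to assess recovery of
#' a known loading structure.
#'
#' @param L,target item x factor loading matrices with equal dimensions.
#' @return mean absolute congruence over aligned factor pairs.
#' @export
tucker_congruence <- function(L, target) {
  stopifnot(all(dim(L) == dim(target)))
  k <- ncol(L)
  cong <- abs(crossprod(L, target) /
                sqrt(outer(colSums(L^2), colSums(target^2))))
  # greedy assignment of estimated factors to target factors
  used <- rep(FALSE, k)
  total <- 0
  for (j in order(-apply(cong, 2, max))) {
    i <- which.max(ifelse(used, -Inf, cong[, j]))
    total <- total + cong[i, j]
    used[i] <- TRUE
  }
  total / k
}
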