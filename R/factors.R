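#' Construct a factor model
#'
#' A named factor defined by its items and signed loadings. Negative
#' loadings act as reverse-coding: the item enters the factor score with
#' flipped sign, and is flipped before reliability computation.
#'
#' @param name factor name.
#' @param items character vector of item ids (at least 2 for a base
#'   factor).
#' @param loadings signed, finite, nonzero loadings, one per item.
#' @param alpha Cronbach alpha of the item set (NA until computed).
#' @param role `"base"` or `"meta"`.
#' @param parents for meta-factors, names of the base factors combined.
#' @return an object of class `factor_model`.
#' @export
factor_model <- function(name, items, loadings, alpha = NA_real_,
                         role = c("base", "meta"), parents = character()) {
  role <- match.arg(role)
  if (length(items) != length(loadings))
    stop("items and loadings must have equal length")
  if (role == "base" && length(items) < 2)
    stop("a base factor needs at least 2 items")
  if (!all(is.finite(loadings)) || any(loadings == 0))
    stop("loadings must be finite and nonzero")
  if (!is.na(alpha) && alpha > 1) stop("alpha cannot exceed 1")
  structure(list(name = name, items = as.character(items),
                 loadings = as.numeric(loadings), alpha = alpha,
                 role = role, parents = as.character(parents)),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> ", x$name, " (", x$role, "): ", length(x$items),
      " items", sep = "")
  if (!is.na(x$alpha)) cat(", alpha = ", round(x$alpha, 3), sep = "")
  if (length(x$parents)) cat(", parents: ", paste(x$parents, collapse = ", "),
                             sep = "")
  cat("\n")
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability: `alpha = k/(k-1) * (1 - sum(item
#' variances) / variance of the item sum)`. Reverse-coded items must be
#' flipped beforehand (done automatically when a `factor_model` with signed
#' loadings is supplied via `model`).
#'
#' @param item_matrix respondents x items numeric matrix (>= 2 items,
#'   >= 2 respondents).
#' @param model optional `factor_model`; its items are selected and
#'   negatively-loaded items sign-flipped before computing alpha.
#' @return alpha (scalar); `NaN` with a warning when the total score has
#'   zero variance.
#' @export
cronbach_alpha <- function(item_matrix, model = NULL) {
  M <- if (inherits(item_matrix, "standardized_matrix"))
    item_matrix$values else as.matrix(item_matrix)
  if (!is.null(model)) {
    stopifnot(inherits(model, "factor_model"))
    M <- M[, model$items, drop = FALSE]
    flip <- model$loadings < 0
    M[, flip] <- -M[, flip, drop = FALSE]
  }
  k <- ncol(M)
  if (k < 2 || nrow(M) < 2)
    stop("cronbach_alpha needs at least 2 items and 2 respondents")
  total_var <- stats::var(rowSums(M))
  if (!is.finite(total_var) || total_var == 0) {
    warning("zero total-score variance; alpha undefined")
    return(NaN)
  }
  item_vars <- apply(M, 2, stats::var)
  k / (k - 1) * (1 - sum(item_vars) / total_var)
}

#' Score respondents on a set of factor models
#'
#' Each factor score is the signed-loading-weighted sum of the
#' standardized item values, renormalized to unit sample sd over
#' respondents. Missing standardized values contribute 0 (the standardized
#' mean). Scoring is linear in the input before renormalization.
#'
#' @param Z a `standardized_matrix` or numeric matrix.
#' @param models list of [factor_model]s (or a single one).
#' @param renormalize rescale each score column to unit sd (default TRUE).
#' @return respondents x factors numeric matrix of class `factor_scores`.
#' @export
score_factors <- function(Z, models, renormalize = TRUE) {
  M <- if (inherits(Z, "standardized_matrix")) Z$values else as.matrix(Z)
  if (inherits(models, "factor_model")) models <- list(models)
  M[is.na(M)] <- 0
  scores <- matrix(NA_real_, nrow(M), length(models),
                   dimnames = list(rownames(M),
                                   vapply(models, `[[`, "", "name")))
  for (i in seq_along(models)) {
    mod <- models[[i]]
    miss <- setdiff(mod$items, colnames(M))
    if (length(miss))
      stop("factor '", mod$name, "' references missing item(s): ",
           paste(miss, collapse = ", "))
    s <- drop(M[, mod$items, drop = FALSE] %*% mod$loadings)
    if (renormalize) {
      sdv <- stats::sd(s)
      if (is.finite(sdv) && sdv > 0) s <- s / sdv
    }
    scores[, i] <- s
  }
  class(scores) <- c("factor_scores", class(scores))
  scores
}

#' Combine correlated factors into meta-factors
#'
#' Second-order factor analysis: an EFA (see [fit_efa()]) on the
#' base-factor score correlations; each meta-factor's score is the
#' loading-weighted sum of its parent factor scores, renormalized to unit
#' sd. Parents are the base factors with absolute loading at or above
#' `parent_cut`.
#'
#' @param scores a `factor_scores` matrix of base factors.
#' @param n_meta number of meta-factors (< number of base factors).
#' @param rotation rotation passed to [fit_efa()].
#' @param parent_cut absolute-loading threshold for recording parenthood.
#' @return list with `scores` (respondents x meta-factors) and `models`
#'   (list of meta [factor_model]s holding the full loading weights).
#' @export
build_meta_factors <- function(scores, n_meta, rotation = "oblimin",
                               parent_cut = 0.3) {
  if (n_meta >= ncol(scores))
    stop("n_meta must be smaller than the number of base factors")
  L <- fit_efa(unclass(scores), n_meta, rotation = rotation)
  models <- vector("list", n_meta)
  meta <- matrix(NA_real_, nrow(scores), n_meta,
                 dimnames = list(rownames(scores),
                                 paste0("meta_", seq_len(n_meta))))
  for (j in seq_len(n_meta)) {
    w <- L[, j]
    parents <- rownames(L)[abs(w) >= parent_cut]
    if (!length(parents)) parents <- rownames(L)[which.max(abs(w))]
    models[[j]] <- factor_model(paste0("meta_", j), names(w), unname(w),
                                role = "meta", parents = parents)
    s <- drop(unclass(scores) %*% w)
    sdv <- stats::sd(s)
    meta[, j] <- if (is.finite(sdv) && sdv > 0) s / sdv else s
  }
  class(meta) <- c("factor_scores", class(meta))
  list(scores = meta, models = models)
}

#' Refine a factor to adequate reliability
#'
#' Greedy search over single-item moves (drop an item, or add a candidate
#' item keyed by its correlation with the current scale score) that
#' maximises Cronbach alpha. Stops as soon as `alpha_min` is reached;
#' otherwise returns the best model found with `reliable = FALSE`.
#'
#' @param model a base [factor_model].
#' @param candidate_items pool of item ids that may be added (may overlap
#'   the current items; may be empty).
#' @param alpha_min target reliability, in (0, 1) (default 0.7).
#' @param Z `standardized_matrix` or numeric matrix holding all items.
#' @param max_moves safety cap on accepted moves.
#' @return the refined `factor_model` with its `alpha` set and an added
#'   `reliable` flag (TRUE when `alpha >= alpha_min`).
#' @export
refine_to_reliable <- function(model, candidate_items, alpha_min = 0.7, Z,
                               max_moves = 50L) {
  stopifnot(inherits(model, "factor_model"),
            alpha_min > 0, alpha_min < 1)
  M <- if (inherits(Z, "standardized_matrix")) Z$values else as.matrix(Z)
  M[is.na(M)] <- 0
  alpha_of <- function(items, loadings) {
    sub <- M[, items, drop = FALSE]
    flip <- loadings < 0
    sub[, flip] <- -sub[, flip, drop = FALSE]
    tv <- stats::var(rowSums(sub))
    if (!is.finite(tv) || tv == 0) return(-Inf)
    k <- length(items)
    k / (k - 1) * (1 - sum(apply(sub, 2, stats::var)) / tv)
  }
  items <- model$items
  loadings <- model$loadings
  best <- alpha_of(items, loadings)
  moves <- 0L
  while (best < alpha_min && moves < max_moves) {
    # candidate single-item moves
    cand_alpha <- -Inf
    cand <- NULL
    if (length(items) > 2) {
      for (i in seq_along(items)) {
        a <- alpha_of(items[-i], loadings[-i])
        if (a > cand_alpha) {
          cand_alpha <- a
          cand <- list(items = items[-i], loadings = loadings[-i])
        }
      }
    }
    score <- drop(M[, items, drop = FALSE] %*% loadings)
    for (it in setdiff(candidate_items, items)) {
      if (!it %in% colnames(M)) next
      r <- suppressWarnings(stats::cor(M[, it], score))
      if (!is.finite(r) || r == 0) next
      a <- alpha_of(c(items, it), c(loadings, sign(r)))
      if (a > cand_alpha) {
        cand_alpha <- a
        cand <- list(items = c(items, it), loadings = c(loadings, sign(r)))
      }
    }
    if (is.null(cand) || cand_alpha <= best) break
    items <- cand$items
    loadings <- cand$loadings
    best <- cand_alpha
    moves <- moves + 1L
  }
  out <- factor_model(model$name, items, loadings, alpha = best,
                      role = model$role, parents = model$parents)
  out$reliable <- is.finite(best) && best >= alpha_min
  out
}

#' The ten shipped default factor models
#'
#' Factor definitions matching the default synthetic questionnaire design:
#' manageability of Covid-19 risks (22 items), effectiveness of protective
#' behaviours (35), concern about Covid-19 risks (14), personal well-being
#' (12), self-care (4), sociability/sensation-seeking (6), Covid-19
#' self-reliance (5), anxiety about the world (6), comprehension/trust in
#' official guidance (3) and personal health anxiety (5), each with signed
#' item loadings. The information-use filler items belong to no model.
#'
#' @param compute_alpha optional `standardized_matrix`; when supplied, each
#'   model's alpha is computed on it.
#' @return named list of [factor_model]s.
#' @export
default_factor_models <- function(compute_alpha = NULL) {
  spec <- default_item_spec()
  spec <- spec[!startsWith(spec$item, "info_"), ]
  models <- lapply(split(spec, spec$factor), function(s)
    factor_model(s$factor[1], s$item, s$loading))
  models <- models[default_factor_names()]
  if (!is.null(compute_alpha))
    models <- lapply(models, function(m) {
      m$alpha <- cronbach_alpha(compute_alpha, model = m)
      m
    })
  models
}

#' Write / read factor models as JSON
#'
#' @param models list of [factor_model]s.
#' @param path JSON path.
#' @return `path` (write) or a list of `factor_model`s (read).
#' @export
write_factor_models <- function(models, path) {
  if (inherits(models, "factor_model")) models <- list(models)
  obj <- lapply(unname(models), function(m)
    list(name = m$name,
         items = data.frame(id = m$items, loading = m$loadings),
         alpha = m$alpha, role = m$role, parents = m$parents))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_factor_models
#' @export
read_factor_models <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  lapply(seq_len(length(obj$name)), function(i)
    factor_model(obj$name[i], obj$items[[i]]$id, obj$items[[i]]$loading,
                 alpha = if (is.null(obj$alpha[[i]])) NA_real_ else obj$alpha[[i]],
                 role = obj$role[i],
                 parents = unlist(obj$parents[[i]])))
}
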