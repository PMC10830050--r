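#' Per-respondent per-block response statistics
#'
#' Computes each respondent's mean and sample variance (denominator n-1)
#' over the non-missing items of every block, plus the same statistics over
#' all items of non-exempt blocks pooled (`overall`). Blocks in which a
#' respondent answered fewer than two items yield an undefined (`NA`)
#' variance; a respondent with zero answered items is recorded with `NA`
#' statistics rather than raising an error.
#'
#' @param X a [response_matrix].
#' @param blocks a [block_spec]; defaults to `X`'s own block map.
#' @return an object of class `block_stats`: list with respondent x block
#'   matrices `means`, `variances`, `n_answered`, vectors `overall_mean`,
#'   `overall_variance`, and the `block_spec` used.
#' @export
block_stats <- function(X, blocks = X$blocks) {
  stopifnot(inherits(X, "response_matrix"), inherits(blocks, "block_spec"))
  uncovered <- setdiff(colnames(X$responses), blocks$items$item)
  if (length(uncovered))
    stop("items not covered by the block spec: ",
         paste(utils::head(uncovered, 5), collapse = ", "))
  ids <- respondent_ids(X)
  bl <- blocks$blocks$block
  means <- vars <- nans <- matrix(NA_real_, length(ids), length(bl),
                                  dimnames = list(ids, bl))
  for (b in bl) {
    items <- intersect(block_items(blocks, b), colnames(X$responses))
    sub <- X$responses[, items, drop = FALSE]
    nans[, b] <- rowSums(!is.na(sub))
    means[, b] <- rowMeans(sub, na.rm = TRUE)
    vars[, b] <- apply(sub, 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r) < 2) NA_real_ else stats::var(r)
    })
  }
  means[nans == 0] <- NA_real_
  screened_items <- intersect(block_items(blocks, screened_blocks(blocks)),
                              colnames(X$responses))
  allsub <- X$responses[, screened_items, drop = FALSE]
  ov_n <- rowSums(!is.na(allsub))
  ov_mean <- ifelse(ov_n > 0, rowMeans(allsub, na.rm = TRUE), NA_real_)
  ov_var <- apply(allsub, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) < 2) NA_real_ else stats::var(r)
  })
  structure(list(means = means, variances = vars, n_answered = nans,
                 overall_mean = ov_mean, overall_variance = ov_var,
                 blocks = blocks, likert_levels = X$likert_levels),
            class = "block_stats")
}

#' Default respondent-screening rules
#'
#' The screening thresholds are analyst choices (no canonical numeric values
#' exist): `var_eps = 0` flags only strictly invariant blocks;
#' `min_invariant_blocks = 3` non-exempt blocks (or zero overall variance)
#' triggers removal; `high_mean_quantile` is the scale maximum minus 0.25,
#' so an invariant block at (or essentially at) the agreement pole marks an
#' extreme acquiescer.
#'
#' @param likert_levels scale points, used for the high-mean cut.
#' @return list of rule parameters.
#' @export
default_qc_rules <- function(likert_levels = 5L) {
  list(var_eps = 0, min_invariant_blocks = 3,
       high_mean_quantile = likert_levels - 0.25)
}

#' Flag low-variability and extreme-acquiescent respondents
#'
#' Applies the screening rules to per-block statistics computed over
#' non-exempt blocks: `flag_invariant` when the respondent's variance is at
#' or below `var_eps` in at least `min_invariant_blocks` non-exempt blocks,
#' or overall; `flag_acquiescent_extreme` when some non-exempt block is both
#' low-variability and has a mean above `high_mean_quantile` (low
#' variability, high mean — agreement with almost every statement).
#'
#' @param stats a [block_stats] object.
#' @param rules list with `var_eps`, `min_invariant_blocks`,
#'   `high_mean_quantile` (see [default_qc_rules()]).
#' @return data.frame of class `respondent_flags`: respondent_id, counts,
#'   flags, and `removal_reason` (one of `none`, `multi_block_invariant`,
#'   `global_invariant`, `high_mean_low_var`).
#' @export
flag_low_variability <- function(stats,
                                 rules = default_qc_rules(stats$likert_levels)) {
  stopifnot(inherits(stats, "block_stats"))
  keep <- screened_blocks(stats$blocks)
  v <- stats$variances[, keep, drop = FALSE]
  m <- stats$means[, keep, drop = FALSE]
  inv <- !is.na(v) & v <= rules$var_eps
  n_invariant <- rowSums(inv)
  global_inv <- !is.na(stats$overall_variance) &
    stats$overall_variance <= rules$var_eps
  multi_inv <- n_invariant >= rules$min_invariant_blocks
  high_mean <- rowSums(inv & !is.na(m) & m >= rules$high_mean_quantile) > 0
  reason <- rep("none", nrow(v))
  reason[high_mean] <- "high_mean_low_var"
  reason[multi_inv] <- "multi_block_invariant"
  reason[global_inv] <- "global_invariant"
  out <- data.frame(
    respondent_id = rownames(v),
    n_invariant_blocks = n_invariant,
    overall_variance = stats$overall_variance,
    flag_invariant = multi_inv | global_inv,
    flag_acquiescent_extreme = high_mean,
    removal_reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("respondent_flags", class(out))
  out
}

#' Remove flagged respondents
#'
#' Restricts a response matrix to respondents whose `removal_reason` is
#' `none` and reports removal counts per reason. The input matrix is not
#' modified.
#'
#' @param X a [response_matrix].
#' @param flags a `respondent_flags` table aligned with `X` (same ids).
#' @return list with `responses` (filtered [response_matrix]) and `report`
#'   (list: n_before, n_after, n_removed, removed_by_reason, removed_ids).
#' @export
apply_filter <- function(X, flags) {
  stopifnot(inherits(X, "response_matrix"))
  if (!setequal(flags$respondent_id, respondent_ids(X)))
    stop("flags do not align with the response matrix (id mismatch)")
  flags <- flags[match(respondent_ids(X), flags$respondent_id), ]
  keep <- flags$removal_reason == "none"
  reasons <- c("multi_block_invariant", "global_invariant",
               "high_mean_low_var")
  by_reason <- vapply(reasons,
                      function(r) sum(flags$removal_reason == r), integer(1))
  if (!any(keep))
    warning("all respondents removed by the screening rules")
  out <- X[which(keep)]
  list(
    responses = out,
    report = list(n_before = n_respondents(X), n_after = n_respondents(out),
                  n_removed = sum(!keep),
                  removed_by_reason = as.list(by_reason),
                  removed_ids = flags$respondent_id[!keep])
  )
}

#' One-call respondent screening
#'
#' Convenience wrapper: [block_stats()] then [flag_low_variability()] then
#' [apply_filter()].
#'
#' @param X a [response_matrix].
#' @param rules screening rules (see [default_qc_rules()]).
#' @return as [apply_filter()], plus the `flags` table and `stats`.
#' @export
qc_screen <- function(X, rules = default_qc_rules(X$likert_levels)) {
  stats <- block_stats(X)
  flags <- flag_low_variability(stats, rules)
  res <- apply_filter(X, flags)
  res$flags <- flags
  res$stats <- stats
  res
}
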