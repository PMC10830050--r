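#' Two-proportion z test (pooled)
#'
#' Pooled two-sample z statistic for percentages, two-sided p-value — the
#' standard market-research column test.
#'
#' @param p1,p2 sample proportions in [0, 1].
#' @param n1,n2 base sizes (>= 1).
#' @return list with `z` and `p_value`.
#' @export
two_proportion_z <- function(p1, n1, p2, n2) {
  if (n1 < 1 || n2 < 1) stop("base sizes must be at least 1")
  if (min(p1, p2) < 0 || max(p1, p2) > 1)
    stop("proportions must lie in [0, 1]")
  pooled <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  if (se == 0) {
    z <- if (p1 == p2) 0 else Inf * sign(p1 - p2)
  } else {
    z <- (p1 - p2) / se
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  list(z = z, p_value = p)
}

#' Welch two-sample t test from summary statistics
#'
#' Unpooled (Welch) t statistic with Welch-Satterthwaite degrees of
#' freedom, two-sided p-value.
#'
#' @param m1,m2 sample means.
#' @param s1,s2 sample standard deviations (>= 0).
#' @param n1,n2 sample sizes (>= 2).
#' @return list with `t`, `df` and `p_value`.
#' @export
pairwise_mean_t <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2 || n2 < 2) stop("sample sizes must be at least 2")
  if (s1 < 0 || s2 < 0) stop("standard deviations must be nonnegative")
  v1 <- s1^2 / n1
  v2 <- s2^2 / n2
  if (v1 + v2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p_value = 1))
    return(list(t = Inf * sign(m1 - m2), df = n1 + n2 - 2, p_value = 0))
  }
  tstat <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Significance-letter annotation of a profile row
#'
#' Each column (segment) is labelled a, b, c, ... in fixed order. Column
#' j's letter string collects, in sorted order, the letters of every
#' column whose statistic is smaller than j's and whose pairwise test
#' against j is significant at `alpha`. The column with the row's smallest
#' statistic therefore always has an empty string.
#'
#' @param stats numeric vector of per-column statistics (one per segment).
#' @param p_values symmetric matrix of pairwise two-sided p-values.
#' @param alpha per-comparison significance level (default 0.05; no
#'   multiplicity correction, per market-research convention).
#' @return character vector of letter strings, one per column.
#' @export
letter_annotation <- function(stats, p_values, alpha = 0.05) {
  k <- length(stats)
  stopifnot(nrow(p_values) == k, ncol(p_values) == k)
  letters_k <- letters[seq_len(k)]
  out <- character(k)
  for (j in seq_len(k)) {
    if (is.na(stats[j])) { out[j] <- NA_character_; next }
    beat <- which(stats < stats[j] & !is.na(stats) &
                    p_values[, j] < alpha)
    out[j] <- paste(sort(letters_k[beat]), collapse = "")
  }
  out
}

#' Kish effective base size
#'
#' Effective sample size of a weighted base: `(sum w)^2 / sum(w^2)`.
#'
#' @param w positive weights.
#' @return effective n.
#' @export
kish_neff <- function(w) sum(w)^2 / sum(w^2)

#' Segment profile table with significance letters
#'
#' Builds the variable-by-segment table used to characterize segments:
#' per-segment percentages for each level of a categorical variable (or
#' binary indicator) and per-segment means for numeric variables, with
#' base sizes and pairwise significance letters (z test for percentages,
#' Welch t for means, per-comparison `alpha`). When weights are supplied,
#' statistics are weighted and tests use Kish effective base sizes.
#'
#' @param data data.frame with one row per respondent, containing the
#'   variables to profile.
#' @param segments character/factor vector of segment labels, aligned with
#'   `data`; its factor level order fixes the a, b, c, ... letter order.
#' @param variables character vector of column names in `data`.
#' @param weights optional positive weights.
#' @param alpha per-comparison significance level (default 0.05).
#' @param use_effective_base use Kish effective base sizes for weighted
#'   tests (default TRUE).
#' @return an object of class `profile_table`: data.frame with columns
#'   `variable`, `level`, `type`, then per-segment statistic / base /
#'   letters columns.
#' @export
build_profile_table <- function(data, segments, variables, weights = NULL,
                                alpha = 0.05, use_effective_base = TRUE) {
  if (nrow(data) != length(segments))
    stop("segments must align with data rows")
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (any(weights <= 0)) stop("weights must be positive")
  miss <- setdiff(variables, names(data))
  if (length(miss)) stop("variables not in data: ",
                         paste(miss, collapse = ", "))
  segs <- if (is.factor(segments)) levels(segments) else
    sort(unique(as.character(segments)))
  segments <- as.character(segments)
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.numeric(x) && length(unique(stats::na.omit(x))) > 2) {
      rows[[length(rows) + 1]] <- profile_numeric_row(
        v, x, segments, segs, weights, alpha, use_effective_base)
    } else {
      lv <- if (is.numeric(x)) sort(unique(stats::na.omit(x))) else
        sort(unique(as.character(stats::na.omit(x))))
      for (l in lv)
        rows[[length(rows) + 1]] <- profile_percent_row(
          v, l, (x == l) * 1, segments, segs, weights, alpha,
          use_effective_base)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "segments") <- segs
  attr(out, "alpha") <- alpha
  class(out) <- c("profile_table", class(out))
  out
}

profile_percent_row <- function(variable, level, ind, segments, segs,
                                weights, alpha, use_eff) {
  k <- length(segs)
  p <- n <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    sel <- segments == segs[j] & !is.na(ind)
    if (!any(sel)) next
    w <- weights[sel]
    p[j] <- sum(w * ind[sel]) / sum(w)
    n[j] <- if (use_eff) kish_neff(w) else sum(sel)
  }
  pv <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.na(p[i]) || is.na(p[j])) next
    pv[i, j] <- pv[j, i] <- two_proportion_z(p[i], n[i], p[j], n[j])$p_value
  }
  mk_profile_row(variable, as.character(level), "percent", 100 * p, n,
                 letter_annotation(p, pv, alpha), segs)
}

profile_numeric_row <- function(variable, x, segments, segs, weights,
                                alpha, use_eff) {
  k <- length(segs)
  m <- s <- n <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    sel <- segments == segs[j] & !is.na(x)
    if (sum(sel) < 2) next
    w <- weights[sel]
    m[j] <- sum(w * x[sel]) / sum(w)
    s[j] <- sqrt(sum(w * (x[sel] - m[j])^2) / (sum(w) - 1))
    n[j] <- if (use_eff) kish_neff(w) else sum(sel)
  }
  pv <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.na(m[i]) || is.na(m[j])) next
    pv[i, j] <- pv[j, i] <-
      pairwise_mean_t(m[i], s[i], n[i], m[j], s[j], n[j])$p_value
  }
  mk_profile_row(variable, "mean", "mean", m, n,
                 letter_annotation(m, pv, alpha), segs)
}

mk_profile_row <- function(variable, level, type, stat, base, letters_str,
                           segs) {
  row <- data.frame(variable = variable, level = level, type = type,
                    stringsAsFactors = FALSE)
  for (j in seq_along(segs)) {
    row[[paste0(segs[j], "_stat")]] <- stat[j]
    row[[paste0(segs[j], "_n")]] <- base[j]
    row[[paste0(segs[j], "_letters")]] <- letters_str[j]
  }
  row
}

#' @export
print.profile_table <- function(x, digits = 1, ...) {
  segs <- attr(x, "segments")
  cat("Profile table (", length(segs), " segments: ",
      paste(letters[seq_along(segs)], segs, sep = "=", collapse = ", "),
      "; per-comparison alpha = ", attr(x, "alpha"), ")\n\n", sep = "")
  for (i in seq_len(nrow(x))) {
    lab <- if (x$type[i] == "mean") paste0(x$variable[i], " (mean)") else
      paste0(x$variable[i], " = ", x$level[i], " (%)")
    stats <- vapply(segs, function(s)
      x[[paste0(s, "_stat")]][i], numeric(1))
    lets <- vapply(segs, function(s)
      x[[paste0(s, "_letters")]][i], character(1))
    cat(format(lab, width = 42),
        paste(format(round(stats, digits), width = 6), collapse = " "), "\n")
    cat(format("", width = 42),
        paste(format(ifelse(is.na(lets), "", lets), width = 6),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Write a profile table as CSV
#'
#' @param x a `profile_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
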