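#' Question-level standardization (column z-scaling)
#'
#' Centers every item column by its mean and divides by its sample
#' (denominator n-1) standard deviation, so that question means are zero
#' and standard deviations are one. Missing values are excluded pairwise
#' and remain missing in the output.
#'
#' @param X a [response_matrix] or a numeric matrix.
#' @param items item columns to standardize (default: all).
#' @param constant how to treat constant columns: `"zero"` (set to 0 with a
#'   warning) or `"error"`.
#' @return an object of class `standardized_matrix`: list with `values`
#'   (numeric matrix), `modes` (named character, `"question"` /
#'   `"respondent"` per item) and `flagged_respondents`.
#' @export
standardize_by_question <- function(X, items = NULL,
                                    constant = c("zero", "error")) {
  constant <- match.arg(constant)
  M <- response_values(X)
  if (!is.null(items)) M <- M[, items, drop = FALSE]
  mu <- colMeans(M, na.rm = TRUE)
  sd <- apply(M, 2, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sd) | sd == 0
  if (any(zero)) {
    if (constant == "error")
      stop("constant column(s): ",
           paste(colnames(M)[zero], collapse = ", "))
    warning(sum(zero), " constant column(s) set to 0")
    sd[zero] <- 1
    mu[zero] <- mu[zero]  # column becomes all zero after centering
  }
  Z <- sweep(sweep(M, 2, mu), 2, sd, "/")
  Z[, zero] <- 0
  new_standardized(Z, rep("question", ncol(Z)), character())
}

#' Respondent-level (ipsative) standardization
#'
#' Within the designated blocks, centers each respondent's values by that
#' respondent's own mean over those items and divides by the respondent's
#' own sample standard deviation. This removes individual response-style
#' location (acquiescence bias): adding any constant to a respondent's raw
#' answers leaves the output unchanged. Respondents with zero
#' within-person spread are set to 0 and flagged.
#'
#' @param X a [response_matrix] or numeric matrix.
#' @param block_subset block ids defining the designated items (for a
#'   `response_matrix`; default: its respondent-standardized blocks), or
#'   NULL to use all columns of a plain matrix.
#' @return a `standardized_matrix` over the designated items only.
#' @export
standardize_by_respondent <- function(X, block_subset = NULL) {
  if (inherits(X, "response_matrix")) {
    if (is.null(block_subset))
      block_subset <- X$blocks$blocks$block[
        X$blocks$blocks$standardization_mode == "respondent"]
    items <- block_items(X$blocks, block_subset)
    M <- response_values(X)[, items, drop = FALSE]
  } else {
    M <- as.matrix(X)
  }
  mu <- rowMeans(M, na.rm = TRUE)
  sd <- apply(M, 1, stats::sd, na.rm = TRUE)
  zero <- !is.finite(sd) | sd == 0
  sd[zero] <- 1
  Z <- sweep(sweep(M, 1, mu), 1, sd, "/")
  Z[zero, ] <- 0
  flagged <- rownames(M)[zero]
  new_standardized(Z, rep("respondent", ncol(Z)), flagged)
}

#' Dual-mode standardization of a response matrix
#'
#' Applies the block map's standardization modes: items of
#' respondent-standardized blocks are ipsatively scaled (jointly over those
#' blocks), all other items are z-scaled by question.
#'
#' @param X a [response_matrix].
#' @param respondent_level if `FALSE`, every block is question-standardized
#'   (the uncorrected comparison pipeline).
#' @return a `standardized_matrix` over all items, in the original column
#'   order.
#' @export
standardize_responses <- function(X, respondent_level = TRUE) {
  stopifnot(inherits(X, "response_matrix"))
  resp_blocks <- X$blocks$blocks$block[
    X$blocks$blocks$standardization_mode == "respondent"]
  if (!respondent_level || !length(resp_blocks))
    return(standardize_by_question(X))
  resp_items <- intersect(block_items(X$blocks, resp_blocks),
                          colnames(X$responses))
  q_items <- setdiff(colnames(X$responses), resp_items)
  Zq <- standardize_by_question(X, items = q_items)
  Zr <- standardize_by_respondent(X, block_subset = resp_blocks)
  vals <- cbind(Zq$values, Zr$values)[, colnames(X$responses), drop = FALSE]
  modes <- c(Zq$modes, Zr$modes)[colnames(X$responses)]
  new_standardized(vals, modes, Zr$flagged_respondents)
}

new_standardized <- function(values, modes, flagged) {
  names(modes) <- colnames(values)
  structure(list(values = values, modes = modes,
                 flagged_respondents = flagged),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat("<standardized_matrix> ", nrow(x$values), " x ", ncol(x$values),
      " (", sum(x$modes == "respondent"), " respondent-mode items, ",
      length(x$flagged_respondents), " zero-spread respondents)\n", sep = "")
  invisible(x)
}

#' Post-hoc column diagnostics of a standardized matrix
#'
#' Reports each column's realized mean and sd, and the worst deviations
#' from (0, 1) separately for question-mode and respondent-mode columns —
#' respondent-mode columns are only approximately standardized at the
#' question level, and this report quantifies how close they come.
#'
#' @param Z a `standardized_matrix`.
#' @return list with `columns` (data.frame: item, mode, mean, sd) and the
#'   per-mode maxima `max_abs_mean` and `max_abs_sd_minus_1`.
#' @export
standardization_diagnostics <- function(Z) {
  stopifnot(inherits(Z, "standardized_matrix"))
  if (!ncol(Z$values))
    return(list(columns = data.frame(item = character(), mode = character(),
                                     mean = numeric(), sd = numeric()),
                max_abs_mean = numeric(0), max_abs_sd_minus_1 = numeric(0)))
  cols <- data.frame(
    item = colnames(Z$values), mode = unname(Z$modes),
    mean = colMeans(Z$values, na.rm = TRUE),
    sd = apply(Z$values, 2, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL
  )
  by_mode <- function(stat) vapply(
    split(stat, cols$mode), function(v) max(abs(v)), numeric(1))
  list(columns = cols,
       max_abs_mean = by_mode(cols$mean),
       max_abs_sd_minus_1 = by_mode(cols$sd - 1))
}

response_values <- function(X) {
  if (inherits(X, "response_matrix")) {
    M <- X$responses
    storage.mode(M) <- "double"
    M
  } else {
    as.matrix(X) * 1.0
  }
}
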