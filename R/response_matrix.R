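#' Block specification for a questionnaire
#'
#' Maps every Likert item to exactly one block of related items, and records
#' two per-block properties used downstream: whether the block is exempt from
#' low-variability screening (blocks where a constant response is reasonable,
#' e.g. satisfaction ratings), and which standardization mode applies to its
#' items (`"question"` for column z-scaling, `"respondent"` for ipsative
#' within-person scaling of acquiescence-prone blocks).
#'
#' @param item_block named character vector or data.frame with columns
#'   `item`, `block`: the item-to-block map.
#' @param filter_exempt character vector of block ids exempt from
#'   variability screening.
#' @param respondent_std character vector of block ids standardized at the
#'   respondent level (typically the two acquiescence-prone blocks).
#' @return An object of class `block_spec` with components `items`
#'   (data.frame: item, block) and `blocks` (data.frame: block,
#'   filter_exempt, standardization_mode).
#' @export
block_spec <- function(item_block, filter_exempt = character(),
                       respondent_std = character()) {
  if (is.data.frame(item_block)) {
    items <- data.frame(item = as.character(item_block$item),
                        block = as.character(item_block$block),
                        stringsAsFactors = FALSE)
  } else {
    if (is.null(names(item_block)))
      stop("item_block must be a named vector (item -> block) or a data.frame")
    items <- data.frame(item = names(item_block),
                        block = as.character(item_block),
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(items$item))
    stop("every item must map to exactly one block")
  block_ids <- unique(items$block)
  unknown <- setdiff(c(filter_exempt, respondent_std), block_ids)
  if (length(unknown))
    stop("unknown block id(s): ", paste(unknown, collapse = ", "))
  blocks <- data.frame(
    block = block_ids,
    filter_exempt = block_ids %in% filter_exempt,
    standardization_mode = ifelse(block_ids %in% respondent_std,
                                  "respondent", "question"),
    stringsAsFactors = FALSE
  )
  if (all(blocks$filter_exempt))
    stop("at least one block must be subject to variability screening")
  structure(list(items = items, blocks = blocks), class = "block_spec")
}

#' @export
print.block_spec <- function(x, ...) {
  cat("<block_spec> ", nrow(x$items), " items in ", nrow(x$blocks),
      " blocks (", sum(x$blocks$filter_exempt), " filter-exempt, ",
      sum(x$blocks$standardization_mode == "respondent"),
      " respondent-standardized)\n", sep = "")
  invisible(x)
}

#' Items belonging to given blocks
#'
#' @param blocks a `block_spec`.
#' @param block_ids block ids; if missing, all blocks.
#' @return character vector of item ids.
#' @export
block_items <- function(blocks, block_ids = NULL) {
  stopifnot(inherits(blocks, "block_spec"))
  if (is.null(block_ids)) return(blocks$items$item)
  unknown <- setdiff(block_ids, blocks$blocks$block)
  if (length(unknown))
    stop("unknown block id(s): ", paste(unknown, collapse = ", "))
  blocks$items$item[blocks$items$block %in% block_ids]
}

#' Non-exempt block ids of a block specification
#' @param blocks a `block_spec`.
#' @return character vector of block ids subject to variability screening.
#' @export
screened_blocks <- function(blocks) {
  stopifnot(inherits(blocks, "block_spec"))
  blocks$blocks$block[!blocks$blocks$filter_exempt]
}

#' Respondent-by-item survey response container
#'
#' Bundles the integer Likert response matrix with its block map, per
#' respondent demographics, binary outcome indicators, sample-source flags
#' and optional weights, aligned by respondent id.
#'
#' @param responses integer matrix, respondents x items; rownames are
#'   respondent ids, colnames item ids. Missing responses are `NA`.
#' @param blocks a [block_spec] covering all items.
#' @param demographics data.frame of per-respondent demographics (or NULL).
#' @param outcomes data.frame/matrix of binary (0/1) outcome indicators
#'   (or NULL).
#' @param sample_source character vector, one of `"core"`, `"booster"`,
#'   `"telephone"` per respondent.
#' @param weights optional positive per-respondent weights (default 1).
#' @param likert_levels number of scale points (default 5).
#' @return An object of class `response_matrix`.
#' @export
response_matrix <- function(responses, blocks, demographics = NULL,
                            outcomes = NULL, sample_source = NULL,
                            weights = NULL, likert_levels = 5L) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  n <- nrow(responses)
  if (is.null(rownames(responses)))
    rownames(responses) <- if (n) paste0("r", seq_len(n)) else character()
  if (anyDuplicated(rownames(responses)))
    stop("duplicate respondent ids")
  stopifnot(inherits(blocks, "block_spec"))
  missing_items <- setdiff(colnames(responses), blocks$items$item)
  if (length(missing_items))
    stop("items not covered by the block spec: ",
         paste(utils::head(missing_items, 5), collapse = ", "))
  if (likert_levels < 2) stop("likert_levels must be >= 2")
  if (n && ncol(responses) && !all(is.na(responses))) {
    rng <- range(responses, na.rm = TRUE)
    if (rng[1] < 1 || rng[2] > likert_levels)
      stop("responses outside the 1..", likert_levels, " Likert range")
  }
  if (is.null(sample_source)) sample_source <- rep("core", n)
  if (length(sample_source) != n)
    stop("sample_source must have one entry per respondent")
  sample_source <- validate_source(sample_source)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0))
    stop("weights must be positive, one per respondent")
  if (!is.null(demographics)) {
    demographics <- as.data.frame(demographics)
    if (nrow(demographics) != n) stop("demographics rows must match respondents")
    rownames(demographics) <- rownames(responses)
  }
  if (!is.null(outcomes)) {
    outcomes <- as.data.frame(outcomes)
    if (nrow(outcomes) != n) stop("outcome rows must match respondents")
    ok <- vapply(outcomes, function(v) all(v %in% c(0L, 1L, NA)), logical(1))
    if (!all(ok)) stop("outcomes must be binary 0/1 indicators")
    rownames(outcomes) <- rownames(responses)
  }
  structure(
    list(responses = responses, blocks = blocks,
         demographics = demographics, outcomes = outcomes,
         sample_source = sample_source, weights = as.numeric(weights),
         likert_levels = as.integer(likert_levels)),
    class = "response_matrix"
  )
}

validate_source <- function(ss) {
  ss <- as.character(ss)
  bad <- setdiff(unique(ss), c("core", "booster", "telephone"))
  if (length(bad)) stop("invalid sample_source value(s): ",
                        paste(bad, collapse = ", "))
  ss
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("<response_matrix> ", nrow(x$responses), " respondents x ",
      ncol(x$responses), " items, ", nrow(x$blocks$blocks), " blocks, ",
      x$likert_levels, "-point scale\n", sep = "")
  if (!is.null(x$demographics))
    cat("  demographics: ", paste(names(x$demographics), collapse = ", "), "\n",
        sep = "")
  if (!is.null(x$outcomes))
    cat("  outcomes: ", paste(names(x$outcomes), collapse = ", "), "\n",
        sep = "")
  src <- table(x$sample_source)
  cat("  sources: ", paste(names(src), src, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Respondent ids of a response matrix
#' @param x a `response_matrix`.
#' @return character vector of ids.
#' @export
respondent_ids <- function(x) {
  stopifnot(inherits(x, "response_matrix"))
  rownames(x$responses)
}

#' Number of respondents
#' @param x a `response_matrix`.
#' @return integer count.
#' @export
n_respondents <- function(x) length(respondent_ids(x))

#' Subset a response matrix by respondents
#'
#' @param x a `response_matrix`.
#' @param i respondent ids, logical mask or integer indices.
#' @param ... unused.
#' @return a `response_matrix` restricted to the selected respondents.
#' @export
`[.response_matrix` <- function(x, i, ...) {
  if (is.character(i)) {
    miss <- setdiff(i, respondent_ids(x))
    if (length(miss)) stop("unknown respondent id(s): ",
                           paste(utils::head(miss, 5), collapse = ", "))
    i <- match(i, respondent_ids(x))
  }
  out <- x
  out$responses <- x$responses[i, , drop = FALSE]
  if (!is.null(x$demographics))
    out$demographics <- x$demographics[i, , drop = FALSE]
  if (!is.null(x$outcomes))
    out$outcomes <- x$outcomes[i, , drop = FALSE]
  out$sample_source <- x$sample_source[i]
  out$weights <- x$weights[i]
  out
}

#' Write survey responses to a delimited text file
#'
#' One row per respondent: `respondent_id`, item columns, demographic
#' columns, outcome columns, `sample_source`, `weight`. Missing Likert cells
#' are written empty. The block map travels separately (see
#' [write_block_spec()]), mirroring the usual survey-data convention of a
#' data file plus a questionnaire map.
#'
#' @param x a `response_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path) {
  stopifnot(inherits(x, "response_matrix"))
  df <- data.frame(respondent_id = respondent_ids(x),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(x$responses))
  if (!is.null(x$demographics)) df <- cbind(df, x$demographics)
  if (!is.null(x$outcomes)) df <- cbind(df, x$outcomes)
  df$sample_source <- x$sample_source
  df$weight <- x$weights
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read survey responses from a delimited text file
#'
#' Inverse of [write_responses()]: item columns are identified through the
#' supplied block spec; remaining columns become demographics/outcomes.
#'
#' @param path CSV path with a `respondent_id` column.
#' @param blocks the [block_spec] naming the item columns.
#' @param outcome_cols character vector of outcome column names (binary 0/1);
#'   default: columns whose name starts with `"out_"`.
#' @param likert_levels scale points (default 5).
#' @return a `response_matrix`.
#' @export
read_responses <- function(path, blocks, outcome_cols = NULL,
                           likert_levels = 5L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"respondent_id" %in% names(df))
    stop("file must declare a respondent_id column")
  ids <- as.character(df$respondent_id)
  if (anyDuplicated(ids)) stop("duplicate respondent ids in ", path)
  item_cols <- intersect(blocks$items$item, names(df))
  if (!length(item_cols)) stop("no item columns from the block spec found")
  resp <- as.matrix(df[item_cols])
  bad <- !is.na(resp) & resp != round(resp)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer Likert value at row %d, column %s",
                 w[1], item_cols[w[2]]))
  }
  rownames(resp) <- ids
  if (is.null(outcome_cols))
    outcome_cols <- grep("^out_", names(df), value = TRUE)
  rest <- setdiff(names(df), c("respondent_id", item_cols, outcome_cols,
                               "sample_source", "weight"))
  response_matrix(
    resp, blocks,
    demographics = if (length(rest)) df[rest] else NULL,
    outcomes = if (length(outcome_cols)) df[outcome_cols] else NULL,
    sample_source = if ("sample_source" %in% names(df)) df$sample_source,
    weights = if ("weight" %in% names(df)) df$weight,
    likert_levels = likert_levels
  )
}

#' Write / read a block specification as JSON
#'
#' @param blocks a [block_spec].
#' @param path JSON path.
#' @return `path` (write) or a `block_spec` (read).
#' @export
write_block_spec <- function(blocks, path) {
  stopifnot(inherits(blocks, "block_spec"))
  jsonlite::write_json(
    list(items = blocks$items, blocks = blocks$blocks),
    path, dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_block_spec
#' @export
read_block_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  block_spec(
    obj$items,
    filter_exempt = obj$blocks$block[obj$blocks$filter_exempt],
    respondent_std =
      obj$blocks$block[obj$blocks$standardization_mode == "respondent"]
  )
}
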