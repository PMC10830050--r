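#' Configuration for the synthetic survey generator
#'
#' Defines a synthetic population of Likert survey respondents with known
#' latent segments, response styles, demographics and outcomes. All defaults
#' describe the package's reference study conditions: ~5,500 respondents,
#' 7 attitudinal segments (shares patterned on published rounded segment
#' percentages, normalised to sum to one), a 2% neutral central group drawn
#' at the grand centroid, 5% straight-liners, and a 15% acquiescent
#' subpopulation whose designated-block responses are shifted toward the
#' agreement pole.
#'
#' @param n_respondents number of respondents to generate.
#' @param n_segments number of latent segments (default 7).
#' @param mixing_proportions simplex weights over segments (must sum to 1,
#'   tolerance 1e-9).
#' @param factor_centroids segment x factor matrix of latent factor means.
#' @param item_spec data.frame with columns `item`, `factor`, `loading`
#'   (signed), `block`: the measurement design.
#' @param blocks a [block_spec] consistent with `item_spec`.
#' @param likert_levels number of scale points (default 5; minimum 2).
#' @param noise_sd standard deviation of both the within-segment factor
#'   spread and the item-level noise (default 0.4); 0 gives deterministic
#'   within-segment response vectors.
#' @param acquiescence_fraction fraction of respondents with acquiescent
#'   response style (default 0.15).
#' @param acquiescence_shift additive shift toward the agreement pole on the
#'   designated blocks, in scale points (default 2).
#' @param acquiescence_blocks block ids receiving the full shift; default:
#'   the respondent-standardized blocks of `blocks` (where the bias is most
#'   evident and the ipsative remedy is applied).
#' @param acquiescence_secondary_shift weaker shift applied to every other
#'   non-exempt (attitudinal) block, in scale points (default 1):
#'   acquiescers lean toward agreement across all agree/disagree batteries,
#'   while behaviour-frequency and satisfaction blocks are unaffected.
#' @param straightliner_fraction fraction of straight-lining respondents
#'   (default 0.05).
#' @param central_fraction fraction of neutral central respondents drawn at
#'   the grand centroid (default 0.02).
#' @param outcome_rates segment x outcome probability matrix; must contain a
#'   row per segment (a `central` row is added at population-average rates
#'   when absent).
#' @param demographic_profiles per-segment demographic distributions (see
#'   [default_demographic_profiles()] for the expected structure), or NULL
#'   to skip demographics.
#' @param booster_fraction fraction of respondents flagged as booster sample
#'   (default 0.2).
#' @param telephone_fraction fraction flagged as telephone sample
#'   (default 0.02).
#' @param seed integer master seed; every stage derives its own substream.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_respondents = 5525,
                         n_segments = 7,
                         mixing_proportions = default_mixing_proportions(),
                         factor_centroids = default_factor_centroids(),
                         item_spec = default_item_spec(),
                         blocks = default_block_spec(),
                         likert_levels = 5L,
                         noise_sd = 0.4,
                         acquiescence_fraction = 0.15,
                         acquiescence_shift = 2,
                         acquiescence_blocks = NULL,
                         acquiescence_secondary_shift = 1,
                         straightliner_fraction = 0.05,
                         central_fraction = 0.02,
                         outcome_rates = default_outcome_rates(),
                         demographic_profiles = default_demographic_profiles(),
                         booster_fraction = 0.2,
                         telephone_fraction = 0.02,
                         seed = 1L) {
  if (n_respondents < 0) stop("n_respondents must be nonnegative")
  if (n_segments < 1) stop("n_segments must be positive")
  if (length(mixing_proportions) != n_segments)
    stop("mixing_proportions must have one weight per segment")
  if (any(mixing_proportions < 0) ||
      abs(sum(mixing_proportions) - 1) > 1e-9)
    stop("mixing_proportions must be a simplex (nonnegative, sum 1)")
  if (nrow(factor_centroids) != n_segments)
    stop("factor_centroids must have one row per segment")
  if (is.null(rownames(factor_centroids)))
    rownames(factor_centroids) <- paste0("segment_", seq_len(n_segments))
  if (likert_levels < 2) stop("likert_levels must be >= 2")
  stopifnot(noise_sd >= 0, acquiescence_shift >= 0,
            acquiescence_secondary_shift >= 0)
  for (f in c(acquiescence_fraction, straightliner_fraction,
              central_fraction, booster_fraction, telephone_fraction))
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  unknown <- setdiff(item_spec$factor, colnames(factor_centroids))
  if (length(unknown))
    stop("item loading references unknown factor(s): ",
         paste(unique(unknown), collapse = ", "))
  if (!all(is.finite(item_spec$loading)) || any(item_spec$loading == 0))
    stop("item loadings must be finite and nonzero")
  stopifnot(inherits(blocks, "block_spec"))
  if (!setequal(item_spec$item, blocks$items$item))
    stop("item_spec and blocks must cover the same items")
  if (is.null(acquiescence_blocks))
    acquiescence_blocks <- blocks$blocks$block[
      blocks$blocks$standardization_mode == "respondent"]
  segs <- rownames(factor_centroids)
  if (!all(segs %in% rownames(outcome_rates)))
    stop("outcome_rates must contain a row per segment")
  if (any(outcome_rates < 0 | outcome_rates > 1))
    stop("outcome probabilities must lie in [0, 1]")
  if (!"central" %in% rownames(outcome_rates)) {
    central <- drop(mixing_proportions %*% outcome_rates[segs, , drop = FALSE])
    outcome_rates <- rbind(outcome_rates, central = central)
  }
  structure(
    list(n_respondents = as.integer(n_respondents),
         n_segments = as.integer(n_segments),
         mixing_proportions = mixing_proportions,
         factor_centroids = factor_centroids,
         item_spec = item_spec, blocks = blocks,
         likert_levels = as.integer(likert_levels),
         noise_sd = noise_sd,
         acquiescence_fraction = acquiescence_fraction,
         acquiescence_shift = acquiescence_shift,
         acquiescence_blocks = acquiescence_blocks,
         acquiescence_secondary_shift = acquiescence_secondary_shift,
         straightliner_fraction = straightliner_fraction,
         central_fraction = central_fraction,
         outcome_rates = outcome_rates,
         demographic_profiles = demographic_profiles,
         booster_fraction = booster_fraction,
         telephone_fraction = telephone_fraction,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# derive a reproducible per-stage substream seed from the master seed
# (double arithmetic: products stay far below 2^53, result below 2^31)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(((as.numeric(seed) %% 2147483629) * 1009 + h * 97) %% 2147483629)
}

#' Generate a synthetic survey population
#'
#' Draws latent segment membership, latent factor values (segment centroid
#' plus Gaussian spread), item values through the signed-loading linear
#' factor model plus item noise, and discretizes each item onto the Likert
#' scale with equal-width bins over its mean +/- 3 sd (clipped). Central
#' respondents are drawn at the grand (mixture-mean) centroid. Response
#' styles are then injected ([inject_acquiescence()],
#' [inject_straightliners()]) and outcomes attached ([attach_outcomes()]).
#'
#' @param config a [synth_config].
#' @return list with components `responses` (a [response_matrix]) and
#'   `truth` (data.frame: respondent_id, true_segment, acquiescent,
#'   straightliner, sample_source), aligned by respondent id. Deterministic
#'   given `config` (including its seed).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_respondents
  spec <- config$item_spec
  segs <- rownames(config$factor_centroids)
  if (n == 0) {
    resp <- matrix(integer(), 0, nrow(spec),
                   dimnames = list(NULL, spec$item))
    truth <- data.frame(respondent_id = character(),
                        true_segment = character(),
                        acquiescent = logical(), straightliner = logical(),
                        sample_source = character(),
                        stringsAsFactors = FALSE)
    X <- response_matrix(resp, config$blocks,
                         likert_levels = config$likert_levels)
    return(list(responses = X, truth = truth))
  }

  ids <- sprintf("r%05d", seq_len(n))

  # -- latent segment membership ------------------------------------------
  set.seed(stage_seed(config$seed, "segments"))
  cf <- config$central_fraction
  labels <- sample(c(segs, "central"), n, replace = TRUE,
                   prob = c((1 - cf) * config$mixing_proportions, cf))

  # -- latent factors and items -------------------------------------------
  set.seed(stage_seed(config$seed, "latent"))
  centroids <- config$factor_centroids
  grand <- drop(config$mixing_proportions %*% centroids)
  mu <- rbind(centroids, central = grand)[labels, , drop = FALSE]
  nf <- ncol(centroids)
  F <- mu + matrix(stats::rnorm(n * nf, sd = config$noise_sd), n, nf)
  colnames(F) <- colnames(centroids)
  latent <- F[, spec$factor, drop = FALSE] *
    rep(spec$loading, each = n) +
    matrix(stats::rnorm(n * nrow(spec), sd = config$noise_sd), n, nrow(spec))
  colnames(latent) <- spec$item

  resp <- discretize_likert(latent, config$likert_levels)
  rownames(resp) <- ids

  # -- response-style flags (mutually exclusive) ---------------------------
  set.seed(stage_seed(config$seed, "styles"))
  style <- sample(c("none", "acq", "straight"), n, replace = TRUE,
                  prob = c(1 - config$acquiescence_fraction -
                             config$straightliner_fraction,
                           config$acquiescence_fraction,
                           config$straightliner_fraction))

  # -- sample source -------------------------------------------------------
  set.seed(stage_seed(config$seed, "source"))
  src <- sample(c("core", "booster", "telephone"), n, replace = TRUE,
                prob = c(1 - config$booster_fraction -
                           config$telephone_fraction,
                         config$booster_fraction,
                         config$telephone_fraction))

  truth <- data.frame(respondent_id = ids, true_segment = labels,
                      acquiescent = style == "acq",
                      straightliner = style == "straight",
                      sample_source = src, stringsAsFactors = FALSE)

  demo <- if (!is.null(config$demographic_profiles))
    draw_demographics(labels, config$demographic_profiles,
                      stage_seed(config$seed, "demographics"))

  X <- response_matrix(resp, config$blocks, demographics = demo,
                       sample_source = src,
                       likert_levels = config$likert_levels)
  X <- inject_acquiescence(X, truth, config$acquiescence_blocks,
                           config$acquiescence_shift)
  secondary <- setdiff(screened_blocks(config$blocks),
                       config$acquiescence_blocks)
  if (length(secondary))
    X <- inject_acquiescence(X, truth, secondary,
                             config$acquiescence_secondary_shift)
  X <- inject_straightliners(X, truth)
  X <- attach_outcomes(X, truth, config$outcome_rates,
                       seed = stage_seed(config$seed, "outcomes"))
  list(responses = X, truth = truth)
}

# equal-width bins over mean +/- 3 sd per item, clipped to 1..levels;
# a zero-variance item maps to the middle of the scale
discretize_likert <- function(latent, levels) {
  n <- nrow(latent)
  out <- matrix(NA_integer_, n, ncol(latent),
                dimnames = dimnames(latent))
  mid <- as.integer(ceiling((levels + 1) / 2))
  for (j in seq_len(ncol(latent))) {
    x <- latent[, j]
    m <- mean(x)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      out[, j] <- mid
      next
    }
    width <- 6 * s / levels
    b <- floor((x - (m - 3 * s)) / width) + 1
    out[, j] <- as.integer(pmin(pmax(b, 1), levels))
  }
  out
}

draw_demographics <- function(labels, prof, seed) {
  set.seed(seed)
  n <- length(labels)
  segs <- names(prof$age_mean)
  pop <- function(v) sum(default_mixing_proportions() * v[segs])
  age_mu <- ifelse(labels == "central", pop(prof$age_mean),
                   prof$age_mean[labels])
  age_sd <- ifelse(labels == "central", mean(prof$age_sd),
                   prof$age_sd[match(labels, segs)])
  age <- round(pmin(pmax(stats::rnorm(n, age_mu, age_sd), 18), 90))
  fem <- ifelse(labels == "central", pop(prof$female_prop),
                prof$female_prop[labels])
  gender <- ifelse(stats::runif(n) < fem, "female", "male")
  draw_cat <- function(pmat) {
    lv <- colnames(pmat)
    central_p <- drop(default_mixing_proportions() %*% pmat[segs, ])
    out <- character(n)
    for (i in seq_len(n)) {
      p <- if (labels[i] == "central") central_p else pmat[labels[i], ]
      out[i] <- sample(lv, 1, prob = p)
    }
    out
  }
  ethnicity <- draw_cat(prof$ethnicity)
  grade <- draw_cat(prof$social_grade)
  edu_mu <- ifelse(labels == "central", pop(prof$education_mean),
                   prof$education_mean[labels])
  education <- as.integer(pmin(pmax(round(stats::rnorm(n, edu_mu, 1)), 1), 5))
  inc_mu <- ifelse(labels == "central", pop(prof$income_mean),
                   prof$income_mean[labels])
  income <- as.integer(pmin(pmax(round(stats::rnorm(n, inc_mu, 1.3)), 1), 7))
  data.frame(age = age, gender = gender, ethnicity = ethnicity,
             social_grade = grade, education = education, income = income,
             stringsAsFactors = FALSE)
}

#' Inject acquiescent response style
#'
#' Shifts the designated-block responses of flagged (acquiescent)
#' respondents toward the agreement pole of the scale: integer shift added
#' to the Likert code, clipped at the scale maximum. Other respondents and
#' other blocks are untouched; truth labels are not altered.
#'
#' @param X a [response_matrix].
#' @param truth truth table with `acquiescent` flags (see
#'   [generate_population()]).
#' @param blocks block ids to shift; must exist in `X`'s block map.
#' @param shift nonnegative shift in scale points.
#' @return the modified `response_matrix`.
#' @export
inject_acquiescence <- function(X, truth, blocks, shift) {
  stopifnot(inherits(X, "response_matrix"), shift >= 0)
  if (shift == 0 || !any(truth$acquiescent)) return(X)
  items <- block_items(X$blocks, blocks)
  rows <- match(truth$respondent_id[truth$acquiescent], respondent_ids(X))
  rows <- rows[!is.na(rows)]
  if (!length(rows)) return(X)
  sub <- X$responses[rows, items, drop = FALSE]
  sub <- pmin(sub + as.integer(round(shift)), X$likert_levels)
  X$responses[rows, items] <- sub
  X
}

#' Inject straight-lining response style
#'
#' Replaces each flagged respondent's answers across all non-exempt blocks
#' with a single constant value (the respondent's answer to the first
#' non-exempt item, i.e. they anchor on their first response). Exempt
#' blocks are untouched; truth labels are not altered.
#'
#' @param X a [response_matrix].
#' @param truth truth table with `straightliner` flags.
#' @return the modified `response_matrix`.
#' @export
inject_straightliners <- function(X, truth) {
  stopifnot(inherits(X, "response_matrix"))
  if (!any(truth$straightliner)) return(X)
  items <- block_items(X$blocks, screened_blocks(X$blocks))
  rows <- match(truth$respondent_id[truth$straightliner], respondent_ids(X))
  rows <- rows[!is.na(rows)]
  for (i in rows)
    X$responses[i, items] <- X$responses[i, items[1]]
  X
}

#' Attach binary outcome indicators
#'
#' Draws each outcome column independently per respondent from the
#' respondent's true segment's outcome probabilities.
#'
#' @param X a [response_matrix].
#' @param truth truth table (provides `true_segment` per respondent).
#' @param outcome_rates segment x outcome probability matrix with a row per
#'   segment label occurring in `truth` (including `central` if present).
#' @param seed RNG seed for the outcome draws.
#' @return `X` with outcome columns attached.
#' @export
attach_outcomes <- function(X, truth, outcome_rates, seed = 1L) {
  stopifnot(inherits(X, "response_matrix"))
  if (any(outcome_rates < 0 | outcome_rates > 1))
    stop("outcome probabilities must lie in [0, 1]")
  missing_rows <- setdiff(unique(truth$true_segment), rownames(outcome_rates))
  if (length(missing_rows))
    stop("outcome_rates lacks rows for: ",
         paste(missing_rows, collapse = ", "))
  set.seed(seed)
  idx <- match(respondent_ids(X), truth$respondent_id)
  p <- outcome_rates[truth$true_segment[idx], , drop = FALSE]
  draws <- matrix(stats::runif(length(p)), nrow(p), ncol(p))
  out <- as.data.frame((draws < p) * 1L)
  names(out) <- colnames(outcome_rates)
  X$outcomes <- out
  rownames(X$outcomes) <- respondent_ids(X)
  X
}
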