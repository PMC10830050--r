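# Default synthetic questionnaire design: 10 latent attitude factors measured
# by 118 Likert items organised in 12 thematic blocks, plus 7 latent segments
# with distinct factor centroids. Centroid magnitudes are illustrative (no
# published per-segment factor means exist); their patterns follow the
# qualitative segment descriptions. Item counts per factor match the published
# factor sizes (22/35/14/12/4/6/5/6/3/5).

default_factor_names <- function() {
  c("manageability", "effectiveness", "concern", "wellbeing", "selfcare",
    "sociability", "selfreliance", "world_anxiety", "guidance_trust",
    "health_anxiety")
}

default_segment_names <- function() {
  c("trusting_compliers", "concerned_cooperators", "fearful_overwhelmed",
    "informed_responsible", "nonchalant", "unconcerned_uncooperative",
    "skeptical_resisters")
}

# Segment shares patterned on published rounded percentages
# (14,14,13,13,15,21,15), normalised to a simplex.
default_mixing_proportions <- function() {
  p <- c(14, 14, 13, 13, 15, 21, 15)
  p / sum(p)
}

# segment x factor centroids in standardized factor units
default_factor_centroids <- function() {
  m <- rbind(
    trusting_compliers        = c(-1.0,  1.2,  0.8,  0.6,  0.5, -0.3,  0.0,  0.4,  1.4,  0.6),
    concerned_cooperators     = c(-0.6,  0.8,  1.0, -0.2,  0.1,  0.0, -0.4,  0.8,  0.3,  0.9),
    fearful_overwhelmed       = c(-0.8,  0.2,  1.4, -1.2, -0.6, -0.5, -0.8,  1.2, -0.8,  1.5),
    informed_responsible      = c(-0.2,  0.6,  0.0,  0.8,  0.9,  0.2,  1.2,  0.2,  0.6, -0.2),
    nonchalant                = c( 0.3,  0.1, -0.4,  0.6, -0.6,  0.7, -0.5, -0.3,  0.3, -0.5),
    unconcerned_uncooperative = c( 0.9, -0.6, -1.0,  0.3, -0.3,  1.2,  0.3, -0.6, -0.4, -1.0),
    skeptical_resisters       = c( 1.4, -1.2, -0.8, -0.4,  0.3,  0.6,  1.0, -0.3, -1.5, -0.6)
  )
  colnames(m) <- default_factor_names()
  m
}

# Item -> (factor, signed loading, block) map. Loadings cycle through a fixed
# magnitude schedule; a minority of items in each attitude battery are
# reverse-keyed (negative loading), as in real mixed-keyed scales.
default_item_spec <- function() {
  mk <- function(factor, n, prefix, blocks, signs, mags) {
    data.frame(
      item = sprintf("%s_%02d", prefix, seq_len(n)),
      factor = factor,
      loading = rep_len(mags, n) * rep_len(signs, n),
      block = blocks,
      stringsAsFactors = FALSE
    )
  }
  spec <- rbind(
    # manageability of covid risks: 22 items, two blocks, ~1/3 reverse-keyed
    mk("manageability", 22, "man",
       rep(c("risk_a", "risk_b"), each = 11),
       c(1, 1, -1, 1, 1, -1, 1, -1, 1, 1, -1),
       c(0.75, 0.65, 0.80, 0.60, 0.70, 0.85, 0.55, 0.75, 0.65, 0.70, 0.60)),
    # effectiveness of protective behaviours: 35 items, three blocks
    mk("effectiveness", 35, "eff",
       c(rep("efficacy_a", 12), rep("efficacy_b", 12), rep("efficacy_c", 11)),
       c(1, 1, 1, -1, 1, 1, 1, 1, -1, 1),
       c(0.80, 0.75, 0.85, 0.70, 0.80, 0.65, 0.75, 0.85, 0.70, 0.80)),
    # concern about covid risks: 14 items, the two acquiescence-prone blocks
    mk("concern", 14, "con",
       rep(c("concern_a", "concern_b"), each = 7),
       c(1, 1, 1, -1, 1, 1, 1),
       c(0.85, 0.75, 0.80, 0.70, 0.85, 0.65, 0.80)),
    # personal well-being: 12 items, satisfaction block (filter-exempt)
    mk("wellbeing", 12, "wb", "life_satisfaction",
       c(1, 1, -1, 1, 1, 1),
       c(0.70, 0.60, 0.75, 0.65, 0.55, 0.70)),
    # self-care: 4 items, behaviour-frequency block (filter-exempt)
    mk("selfcare", 4, "care", "health_habits",
       c(1, 1, 1, -1), c(0.85, 0.80, 0.80, 0.85)),
    # sociability / sensation-seeking: 6 items
    mk("sociability", 6, "soc", "outlook",
       c(1, 1, -1, 1, 1, 1), c(0.75, 0.70, 0.70, 0.80, 0.65, 0.75)),
    # covid self-reliance: 5 items
    mk("selfreliance", 5, "rely", "outlook",
       c(1, -1, 1, 1, 1), c(0.70, 0.75, 0.65, 0.75, 0.70)),
    # anxiety about the world: 6 items
    mk("world_anxiety", 6, "world", "anxieties",
       c(1, 1, 1, -1, 1, 1), c(0.75, 0.70, 0.80, 0.70, 0.65, 0.75)),
    # comprehension / trust in official guidance: 3 items
    mk("guidance_trust", 3, "guide", "guidance",
       c(1, 1, -1), c(0.80, 0.75, 0.70)),
    # personal health anxiety: 5 items
    mk("health_anxiety", 5, "hlth", "anxieties",
       c(1, 1, -1, 1, 1), c(0.80, 0.75, 0.75, 0.70, 0.80)),
    # information-use filler items (weakly related to guidance trust, not
    # part of any shipped factor model)
    mk("guidance_trust", 6, "info", "guidance",
       c(1, 1, 1, -1, 1, 1), rep(0.45, 6))
  )
  rownames(spec) <- NULL
  spec
}

#' Default questionnaire block specification
#'
#' Twelve thematic blocks over the default 118-item design: the two
#' satisfaction/behaviour-frequency blocks (`life_satisfaction`,
#' `health_habits`) are exempt from variability screening (a constant
#' response there can be genuine), and the two concern blocks are
#' designated for respondent-level (ipsative) standardization, these being
#' the acquiescence-prone agree/disagree batteries in the default design.
#'
#' @return a [block_spec].
#' @export
default_block_spec <- function() {
  spec <- default_item_spec()
  block_spec(
    stats::setNames(spec$block, spec$item),
    filter_exempt = c("life_satisfaction", "health_habits"),
    respondent_std = c("concern_a", "concern_b")
  )
}

# per-segment demographic generators, patterned on the published demographic
# profile (mean ages, gender split, ethnicity, social grade); education and
# income gradients are illustrative
default_demographic_profiles <- function() {
  segs <- default_segment_names()
  prof <- list(
    age_mean    = c(58, 54, 48, 56, 43, 36, 48),
    age_sd      = rep(13, 7),
    female_prop = c(0.44, 0.51, 0.64, 0.40, 0.55, 0.51, 0.53),
    ethnicity   = rbind(
      c(0.90, 0.06, 0.02, 0.01, 0.01),
      c(0.88, 0.07, 0.03, 0.01, 0.01),
      c(0.88, 0.07, 0.02, 0.02, 0.01),
      c(0.91, 0.05, 0.02, 0.01, 0.01),
      c(0.81, 0.12, 0.04, 0.02, 0.01),
      c(0.81, 0.09, 0.05, 0.03, 0.02),
      c(0.92, 0.03, 0.03, 0.01, 0.01)
    ),
    social_grade = rbind(
      c(0.33, 0.49, 0.18),
      c(0.22, 0.54, 0.24),
      c(0.17, 0.47, 0.36),
      c(0.28, 0.52, 0.20),
      c(0.23, 0.54, 0.23),
      c(0.20, 0.55, 0.25),
      c(0.17, 0.52, 0.31)
    ),
    education_mean = c(3.4, 3.0, 2.6, 3.5, 3.0, 2.8, 2.7),
    income_mean    = c(4.2, 3.6, 2.9, 4.3, 3.6, 3.2, 3.1)
  )
  names(prof$age_mean) <- names(prof$female_prop) <- segs
  names(prof$education_mean) <- names(prof$income_mean) <- segs
  rownames(prof$ethnicity) <- rownames(prof$social_grade) <- segs
  colnames(prof$ethnicity) <- c("white", "asian", "black", "mixed", "other")
  colnames(prof$social_grade) <- c("AB", "C1C2", "DE")
  prof$ethnicity <- prof$ethnicity / rowSums(prof$ethnicity)
  prof$social_grade <- prof$social_grade / rowSums(prof$social_grade)
  prof
}

#' Default segment-by-outcome probability matrix
#'
#' Vaccination-status and past-two-week protective-behaviour endorsement
#' rates per segment. The three vaccination rows and the mask / handwash /
#' distancing rows follow the published segment-by-outcome percentages; the
#' crowd-avoidance and ventilation rows are illustrative, graded like the
#' other behaviours.
#'
#' @return segment x outcome probability matrix (rows include the neutral
#'   `central` group at population-average rates).
#' @export
default_outcome_rates <- function() {
  m <- rbind(
    out_vax_full     = c(0.88, 0.80, 0.72, 0.83, 0.59, 0.39, 0.46),
    out_vax_partial  = c(0.09, 0.13, 0.16, 0.11, 0.21, 0.22, 0.19),
    out_vax_refuse   = c(0.004, 0.01, 0.03, 0.02, 0.02, 0.08, 0.24),
    out_mask         = c(0.96, 0.92, 0.88, 0.92, 0.76, 0.53, 0.69),
    out_handwash     = c(0.90, 0.87, 0.81, 0.80, 0.62, 0.46, 0.50),
    out_distance     = c(0.86, 0.77, 0.73, 0.62, 0.55, 0.35, 0.28),
    out_avoid_crowds = c(0.78, 0.72, 0.70, 0.58, 0.48, 0.32, 0.30),
    out_open_window  = c(0.70, 0.66, 0.64, 0.55, 0.45, 0.35, 0.33)
  )
  colnames(m) <- default_segment_names()
  out <- t(m)
  central <- drop(default_mixing_proportions() %*% out)
  rbind(out, central = central)
}

#' Names of the five protective-behaviour outcome columns
#'
#' The components of the summative protective-behaviour score: masking,
#' social distancing, avoiding crowded indoor spaces, handwashing for at
#' least 20 seconds, and opening a window for ventilation.
#' @return character vector of column names.
#' @export
protective_behaviour_items <- function() {
  c("out_mask", "out_distance", "out_avoid_crowds", "out_handwash",
    "out_open_window")
}
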