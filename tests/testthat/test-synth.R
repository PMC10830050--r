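test_that("synth_config validates its inputs", {
  expect_error(mini_config(n = 100, mixing_proportions = c(0.6, 0.5)),
               "simplex")
  expect_error(synth_config(n_respondents = 10, n_segments = 2,
                            mixing_proportions = c(0.5, 0.5),
                            factor_centroids = rbind(a = c(zz = 1),
                                                     b = c(zz = -1)),
                            item_spec = mini_item_spec(),
                            blocks = mini_blocks(),
                            demographic_profiles = NULL),
               "unknown factor")
  expect_error(mini_config(n = 100, likert_levels = 1), "likert_levels")
  expect_error(mini_config(n = 100, acquiescence_fraction = 1.2),
               "fractions")
  bad_rates <- rbind(seg_a = c(out_yes = 1.4), seg_b = c(out_yes = 0.2))
  expect_error(mini_config(n = 100, outcome_rates = bad_rates), "\\[0, 1\\]")
})

test_that("an empty population yields an empty matrix and empty truth", {
  gen <- generate_population(mini_config(n = 0))
  expect_equal(n_respondents(gen$responses), 0)
  expect_equal(ncol(gen$responses$responses), nrow(mini_item_spec()))
  expect_equal(nrow(gen$truth), 0)
})

test_that("zero noise makes same-segment respondents identical", {
  gen <- generate_population(mini_config(n = 120, noise_sd = 0))
  for (s in unique(gen$truth$true_segment)) {
    rows <- gen$responses$responses[gen$truth$true_segment == s, ,
                                    drop = FALSE]
    expect_true(all(apply(rows, 2, function(col) length(unique(col)) == 1)))
  }
  # and the two segments differ somewhere
  expect_gt(length(unique(gen$truth$true_segment)), 1)
  seg_rows <- split(seq_len(nrow(gen$truth)), gen$truth$true_segment)
  v1 <- gen$responses$responses[seg_rows[[1]][1], ]
  v2 <- gen$responses$responses[seg_rows[[2]][1], ]
  expect_false(all(v1 == v2))
})

test_that("realized segment counts follow the mixing proportions", {
  # binomial oracle: each realized count within 4*sqrt(n*pi*(1-pi)) of n*pi
  p <- c(14, 14, 13, 13, 15, 21, 15) / 105
  cfg <- synth_config(n_respondents = 10000, central_fraction = 0,
                      straightliner_fraction = 0,
                      acquiescence_fraction = 0,
                      demographic_profiles = NULL, seed = 99)
  gen <- generate_population(cfg)
  counts <- table(factor(gen$truth$true_segment,
                         levels = rownames(cfg$factor_centroids)))
  expect_true(all(abs(counts - 10000 * p) <=
                    4 * sqrt(10000 * p * (1 - p))))
})

test_that("generation is deterministic given the config seed", {
  g1 <- generate_population(mini_config(n = 150, seed = 5,
                                        straightliner_fraction = 0.1))
  g2 <- generate_population(mini_config(n = 150, seed = 5,
                                        straightliner_fraction = 0.1))
  expect_identical(g1$responses$responses, g2$responses$responses)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_population(mini_config(n = 150, seed = 6,
                                        straightliner_fraction = 0.1))
  expect_false(identical(g1$responses$responses, g3$responses$responses))
})

test_that("acquiescence injection shifts designated blocks and nothing else", {
  gen <- generate_population(mini_config(n = 200, seed = 2))
  X <- gen$responses
  truth <- gen$truth
  truth$acquiescent <- seq_len(nrow(truth)) <= 50
  # shift 0 is the identity
  expect_identical(inject_acquiescence(X, truth, "blk1", 0)$responses,
                   X$responses)
  # saturation: shift >= likert_levels pins flagged rows at the scale max
  Xs <- inject_acquiescence(X, truth, "blk1", 5)
  flagged_rows <- which(truth$acquiescent)
  blk1 <- block_items(X$blocks, "blk1")
  expect_true(all(Xs$responses[flagged_rows, blk1] == 5))
  expect_identical(Xs$responses[-flagged_rows, ], X$responses[-flagged_rows, ])
  expect_identical(Xs$responses[, setdiff(colnames(X$responses), blk1)],
                   X$responses[, setdiff(colnames(X$responses), blk1)])
  # shift 1: flagged rows' designated-block mean exceeds unflagged rows'
  X1 <- inject_acquiescence(X, truth, "blk1", 1)
  expect_gt(mean(X1$responses[flagged_rows, blk1]),
            mean(X1$responses[-flagged_rows, blk1]))
  expect_error(inject_acquiescence(X, truth, "nope", 1), "unknown block")
})

test_that("straightliner injection gives constant non-exempt rows", {
  cfg <- mini_config(n = 5000, seed = 3, straightliner_fraction = 0.05)
  gen <- generate_population(cfg)
  X <- gen$responses
  items <- block_items(X$blocks, screened_blocks(X$blocks))
  flagged <- gen$truth$straightliner
  expect_true(all(apply(X$responses[flagged, items], 1,
                        function(r) stats::var(r) == 0)))
  # count within 4 binomial sd of n * fraction
  expect_lt(abs(sum(flagged) - 250), 4 * sqrt(5000 * 0.05 * 0.95))
  # fraction 0 leaves the matrix untouched
  g0 <- generate_population(mini_config(n = 100, seed = 3))
  expect_identical(inject_straightliners(g0$responses, g0$truth)$responses,
                   g0$responses$responses)
})

test_that("truth labels are invariant under response-style injection", {
  cfg <- mini_config(n = 300, seed = 4, straightliner_fraction = 0.1,
                     acquiescence_fraction = 0.2)
  gen <- generate_population(cfg)
  clean <- generate_population(mini_config(n = 300, seed = 4))
  expect_identical(gen$truth$true_segment, clean$truth$true_segment)
})

test_that("outcomes follow the true segment's rates", {
  rates0 <- rbind(seg_a = c(out_yes = 0), seg_b = c(out_yes = 1))
  gen <- generate_population(mini_config(n = 300, seed = 6,
                                         outcome_rates = rates0))
  ya <- gen$responses$outcomes$out_yes[gen$truth$true_segment == "seg_a"]
  yb <- gen$responses$outcomes$out_yes[gen$truth$true_segment == "seg_b"]
  expect_true(all(ya == 0))
  expect_true(all(yb == 1))
  # refusal-style rate 0.24: observed share within 3*sqrt(p(1-p)/n) of 0.24
  rates <- rbind(seg_a = c(out_refuse = 0.24), seg_b = c(out_refuse = 0.02))
  cfg <- mini_config(n = 2000, seed = 8, outcome_rates = rates)
  gen <- generate_population(cfg)
  in_a <- gen$truth$true_segment == "seg_a"
  n_a <- sum(in_a)
  share <- mean(gen$responses$outcomes$out_refuse[in_a])
  expect_lt(abs(share - 0.24), 3 * sqrt(0.24 * 0.76 / n_a))
  expect_error(attach_outcomes(gen$responses, gen$truth,
                               rbind(seg_a = 1.5, seg_b = 0.1)),
               "\\[0, 1\\]")
})

test_that("segment shares converge to the mixing proportions at large n", {
  cfg <- mini_config(n = 50000, seed = 10,
                     mixing_proportions = c(0.3, 0.7))
  gen <- generate_population(cfg)
  share <- mean(gen$truth$true_segment == "seg_a")
  expect_lt(abs(share - 0.3), 0.01)
})

test_that("responses round-trip through CSV", {
  gen <- generate_population(mini_config(n = 40, seed = 12))
  path <- tempfile(fileext = ".csv")
  write_responses(gen$responses, path)
  back <- read_responses(path, gen$responses$blocks)
  expect_identical(back$responses, gen$responses$responses)
  expect_equal(back$outcomes, gen$responses$outcomes)
  expect_identical(back$sample_source, gen$responses$sample_source)
  # duplicate ids are rejected
  df <- utils::read.csv(path, check.names = FALSE)
  df$respondent_id[2] <- df$respondent_id[1]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_responses(path, gen$responses$blocks), "duplicate")
})

test_that("missing cells read back as NA, not zero", {
  gen <- generate_population(mini_config(n = 10, seed = 13))
  X <- gen$responses
  X$responses[1, 1] <- NA
  path <- tempfile(fileext = ".csv")
  write_responses(X, path)
  back <- read_responses(path, X$blocks)
  expect_true(is.na(back$responses[1, 1]))
  expect_identical(back$responses[-1, ], X$responses[-1, ])
})
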