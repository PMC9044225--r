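test_that("default configuration encodes the documented cue structure", {
  cfg <- default_config_nubeslike()
  expect_equal(cfg$p_negated, 0.255)
  expect_equal(cfg$p_uncertain, 0.075)
  expect_equal(cfg$p_continuous, 0.95)
  expect_equal(sum(cfg$negation_cues$freq), 1)
  expect_equal(sum(cfg$uncertainty_cues$freq), 1)
  # five most frequent negation surfaces carry 87% of the mass;
  # the uncertainty inventory is far flatter (< 48%)
  expect_equal(sum(sort(cfg$negation_cues$freq, decreasing = TRUE)[1:5]),
               0.87, tolerance = 1e-9)
  expect_lt(sum(sort(cfg$uncertainty_cues$freq, decreasing = TRUE)[1:5]),
            0.48)
  # class mix: 85/6/9 negation, 2/98 uncertainty
  mix <- tapply(cfg$negation_cues$freq, cfg$negation_cues$class, sum)
  expect_equal(as.numeric(mix[c("syntactic", "lexical", "morphological")]),
               c(0.85, 0.06, 0.09), tolerance = 1e-9)
  umix <- tapply(cfg$uncertainty_cues$freq, cfg$uncertainty_cues$class, sum)
  expect_equal(as.numeric(umix["lexical"]), 0.98, tolerance = 1e-9)
  # misconfiguration is rejected
  expect_error(generator_config(
    p_negated = 0.2, p_uncertain = 0.1,
    negation_cues = cfg$negation_cues,
    uncertainty_cues = cfg$uncertainty_cues,
    p_continuous = 0.9, length_quantiles = c(9, 14, 23),
    filler_vocabulary = c("x", "no")), "overlap")
})

test_that("generation is a pure function of (config, n, seed)", {
  cfg <- default_config_nubeslike()
  a <- generate_corpus(cfg, 40, seed = 7)
  b <- generate_corpus(cfg, 40, seed = 7)
  expect_identical(a, b)
  c_ <- generate_corpus(cfg, 40, seed = 8)
  expect_false(identical(a, c_))
  expect_error(generate_corpus(cfg, 0), ">= 1")
})

test_that("degenerate parameters are honored exactly", {
  cfg <- default_config_nubeslike()
  cfg$p_continuous <- 1
  corpus <- generate_corpus(cfg, 250, seed = 3)
  n_disc <- sum(vapply(corpus, function(s)
    sum(vapply(s$scopes, function(sc) !sc$continuous, NA)), 0L))
  expect_identical(n_disc, 0L)
})

test_that("generated annotations satisfy every structural invariant", {
  corpus <- generate_corpus(default_config_nubeslike(), 200, seed = 15)
  for (s in corpus) {
    # construction went through the validating constructor; re-check the
    # visible contracts explicitly
    for (a in c(s$cues, s$scopes)) {
      expect_true(all(a$fragments$char_start < a$fragments$char_end))
      expect_true(all(a$fragments$char_end <= nchar(s$text)))
    }
    for (cu in s$cues) {
      expect_identical(
        cu$surface,
        paste(substring(s$text, cu$fragments$char_start + 1,
                        cu$fragments$char_end), collapse = " "))
    }
    cue_ids <- vapply(s$cues, `[[`, "", "id")
    for (sc in s$scopes) {
      expect_true(sc$cue_id %in% cue_ids)
      expect_identical(sc$continuous, nrow(sc$fragments) == 1L)
    }
  }
  # morphological cues carry the negation in the cue token itself:
  # they emit no scope record
  cls <- unlist(lapply(corpus, function(s)
    vapply(s$cues, `[[`, "", "cue_class")))
  expect_true("morphological" %in% cls)
  scoped_cues <- unlist(lapply(corpus, function(s)
    vapply(s$scopes, `[[`, "", "cue_id")))
  for (s in corpus)
    for (cu in s$cues)
      if (cu$cue_class == "morphological")
        expect_false(cu$id %in% vapply(s$scopes, `[[`, "", "cue_id"))
})

test_that("scope sides follow the configured direction distribution", {
  cfg <- default_config_nubeslike()
  corpus <- generate_corpus(cfg, 2000, seed = 31)
  # among continuous scopes, tally whether the scope lies right or left of
  # its cue, and compare to the renormalized configured mix
  sides <- c(right = 0L, left = 0L)
  for (s in corpus) {
    cue_by_id <- stats::setNames(s$cues, vapply(s$cues, `[[`, "", "id"))
    for (sc in s$scopes) {
      if (!sc$continuous) next
      cu <- cue_by_id[[sc$cue_id]]
      side <- if (sc$fragments$char_start[1] >= max(cu$fragments$char_end))
        "right" else "left"
      sides[side] <- sides[side] + 1L
    }
  }
  right_share <- function(inv) {
    inv <- inv[inv$class != "morphological", ]
    w <- inv$freq / sum(inv$freq)
    sum(w * inv$dir_right / (inv$dir_right + inv$dir_left))
  }
  wk <- c(cfg$p_negated, cfg$p_uncertain)
  wk <- wk / sum(wk)
  expected_right <- wk[1] * right_share(cfg$negation_cues) +
    wk[2] * right_share(cfg$uncertainty_cues)
  expect_lt(abs(sides[["right"]] / sum(sides) - expected_right), 0.05)
})
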