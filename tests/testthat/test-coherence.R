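test_that("prototype is the leave-one-out mean of the other responses", {
  sp <- toy_space()
  rs <- list(response("p1", "q", c("a", "a")),
             response("p2", "q", c("b", "b")),
             response("p3", "q", c("c", "c")))
  proto <- prototype_vector(rs, exclude = "p3", sp)
  # (u + v)/2 for u = a-vector, v = b-vector
  expect_equal(proto$values, c(0.5, 0.5, 0))
  expect_equal(proto$n_responses_averaged, 2L)
  expect_identical(proto$excluded, "p3")
})

test_that("the excluded response contributes nothing to its own prototype", {
  sp <- toy_space()
  base <- list(response("p1", "q", c("a", "d")),
               response("p2", "q", c("b", "c")))
  # same pool but with p2's words polluted by p1's tokens: prototypes differ,
  # proving the leave-one-out pool is sensitive to *other* responses...
  polluted <- list(base[[1]], response("p2", "q", c("b", "c", "a", "a")))
  p_clean <- suppressWarnings(prototype_vector(base, exclude = "p1", sp))
  p_poll <- suppressWarnings(prototype_vector(polluted, exclude = "p1", sp))
  expect_false(isTRUE(all.equal(p_clean$values, p_poll$values)))
  # ...while any change confined to the excluded response itself is inert
  changed <- list(response("p1", "q", c("e", "e", "e")), base[[2]])
  expect_equal(suppressWarnings(
    prototype_vector(changed, exclude = "p1", sp))$values,
    p_clean$values)
})

test_that("identical remaining responses give their common vector; degenerate pools handled", {
  sp <- toy_space()
  rs <- list(response("p1", "q", "d"),
             response("p2", "q", c("a", "b")),
             response("p3", "q", c("b", "a")))
  proto <- prototype_vector(rs, exclude = "p1", sp)
  expect_equal(proto$values, c(0.5, 0.5, 0))
  expect_warning(prototype_vector(rs[1:2], exclude = "p2", sp), "single")
  expect_error(prototype_vector(rs[1:2], exclude = "p1", sp) |>
                 suppressWarnings(), NA)
  expect_error(prototype_vector(list(rs[[1]]), exclude = "p1", sp),
               "no eligible")
  mixed <- c(rs[1:2], list(response("p3", "other", "a")))
  expect_error(prototype_vector(mixed, exclude = "p1", sp), "same prompt")
})

test_that("coherence scale endpoints: identical window scores 100, orthogonal window 0", {
  sp <- toy_space()
  proto <- structure(list(prompt_id = "q", values = c(1, 0, 0),
                          n_responses_averaged = 2L, excluded = "px"),
                     class = "prototype_vector")
  same <- response("px", "q", rep(c("a", "e"), 3))  # both collinear with proto
  s1 <- global_coherence_series(same, proto, sp, window = 4)
  expect_equal(s1$score[4:6], rep(100, 3))
  orth <- response("px", "q", rep("b", 6))
  s2 <- global_coherence_series(orth, proto, sp, window = 4)
  expect_equal(s2$score[4:6], rep(0, 3))
  expect_true(all(is.na(s1$score[1:3])))
})

test_that("incremental window scoring equals brute-force recomputation everywhere", {
  tts <- two_topic_space(seed = 11, k = 4)
  resp <- generate_responses(tts$spec, 1, drift_spec(p0 = 0.9, delta = 0.08),
                             n_participants = 4, seed = 12)
  proto <- prototype_vector(resp, exclude = "p01", tts$space)
  for (w in c(5L, 20L)) {
    got <- global_coherence_series(resp[[1]], proto, tts$space, window = w)
    expect_equal(got$score, brute_global(resp[[1]], proto, tts$space, w),
                 tolerance = 1e-10)
    loc <- local_coherence_series(resp[[1]], tts$space, window = w)
    expect_equal(loc$score, brute_local(resp[[1]], tts$space, w),
                 tolerance = 1e-10)
  }
})

test_that("coherence values live on [0, 100] with raw cosines exposed", {
  tts <- two_topic_space(seed = 21, k = 4)
  resp <- generate_responses(tts$spec, 1, drift_spec(), n_participants = 3,
                             seed = 22)
  proto <- prototype_vector(resp, exclude = "p02", tts$space)
  s <- global_coherence_series(resp[[2]], proto, tts$space)
  ok <- !is.na(s$score)
  expect_true(all(s$score[ok] >= 0 & s$score[ok] <= 100))
  expect_true(all(s$raw_cosine[ok] >= -1 & s$raw_cosine[ok] <= 1))
  expect_equal(s$score[ok], 100 * pmax(0, s$raw_cosine[ok]))
})

test_that("local coherence: repetition scores 100, an abrupt topic switch 0", {
  sp <- toy_space()
  rep_resp <- response("p", "q", rep("a", 12))
  s <- local_coherence_series(rep_resp, sp, window = 3)
  expect_true(all(is.na(s$score[1:5])))
  expect_equal(s$score[6:12], rep(100, 7))
  # words 1-3 on one orthogonal axis, 4-6 on another
  switch_resp <- response("p", "q", c("a", "a", "a", "b", "b", "b"))
  s2 <- local_coherence_series(switch_resp, sp, window = 3)
  expect_equal(s2$score[6], 0)
})

test_that("block coherence averages word values with the first-block substitution rule", {
  # constant series -> every block equals the constant
  resp <- response("p", "q", rep("a", 30), period_length = 15)
  series <- structure(list(score = rep(55, 30)), class = "coherence_series")
  bc <- block_coherence(series, resp, block_length = 5)
  expect_equal(bc$value, rep(55, 3))

  # hand-assigned 3-block toy: block 1 undefined, block 2 = {10, 20},
  # block 3 = {30} -> (15, 15, 30)
  resp2 <- response("p", "q", c("w1", "w2", "w3", "w4", "w5"),
                    onsets = c(1, 6, 8, 11, 14), period_length = 15)
  series2 <- structure(list(score = c(NA, 10, 20, 30, NA)),
                       class = "coherence_series")
  bc2 <- block_coherence(series2, resp2, block_length = 5)
  expect_equal(bc2$value, c(15, 15, 30))
  expect_true(bc2$filled[1])
  expect_equal(bc2$n_words, c(1, 2, 2))

  # block 1 undefined, block 2 defined at 40 -> block 1 gets 40
  series3 <- structure(list(score = c(NA, 40, 40, 30, NA)),
                       class = "coherence_series")
  expect_equal(block_coherence(series3, resp2, 5)$value[1], 40)
})

test_that("empty middle blocks are filled from the nearest later defined block", {
  resp <- response("p", "q", c("w1", "w2", "w3"), onsets = c(1, 2, 16),
                   period_length = 20)
  series <- structure(list(score = c(20, 20, 60)),
                      class = "coherence_series")
  expect_message(bc <- block_coherence(series, resp, 5), "block 2")
  # block 2 and 3 empty -> take block 4's 60; block 1 then takes block 2
  expect_equal(bc$value, c(60, 60, 60, 60))
  expect_error(block_coherence(series,
                               response("p", "q", c("w1"), onsets = 0,
                                        period_length = 4), 5),
               "fewer than 2 blocks")
})

test_that("participant mean coherence pools blocks with equal weight", {
  b1 <- data.frame(value = c(40, 40))
  b2 <- data.frame(value = c(60, 60))
  expect_equal(participant_mean_coherence(list(b1)), 40)
  expect_equal(participant_mean_coherence(list(b1, b2)), 50)
  # unequal block counts match the brute-force pooled mean
  b3 <- data.frame(value = c(10, 20, 30, 40, 50))
  expect_equal(participant_mean_coherence(list(b1, b3)),
               mean(c(40, 40, 10, 20, 30, 40, 50)))
})

test_that("block coherence declines with block index on drifting responses", {
  tts <- two_topic_space(seed = 31, k = 6)
  spec6 <- topic_model_spec(n_topics = 6)
  corp <- generate_corpus(spec6, n_docs = 36, seed = 31)
  sp <- build_space(corp, k = 8)
  resp <- generate_responses(spec6, 1, drift_spec(), n_participants = 5,
                             seed = 32)
  tab <- suppressMessages(score_responses(resp, sp, local = FALSE))
  rho <- cor(tab$block, tab$global_coherence, method = "spearman")
  expect_lt(rho, 0)
})
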