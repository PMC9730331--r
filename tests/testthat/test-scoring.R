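test_that("score assignment follows the size rule and its boundaries", {
  rule <- score_rule()
  mk <- function(d, v = 0.1) list(max_diameter_cm = d, volume_cc = v)
  # the printed 4/5 cutoff: 1.6 cm scores 5; exactly 1.5 cm scores 5
  expect_equal(assign_score(mk(1.6), rule)$score, 5L)
  expect_equal(assign_score(mk(1.5), rule)$score, 5L)
  expect_equal(assign_score(mk(1.49), rule)$score, 4L)
  # lower boundaries, right-closed
  expect_equal(assign_score(mk(0.56), rule)$score, 2L)
  expect_equal(assign_score(mk(0.57), rule)$score, 3L)
  expect_equal(assign_score(mk(0.82), rule)$score, 4L)
  # clinical significance: volume above 0.5 cc flags even a small lesion
  r <- assign_score(mk(0.3, v = 0.6), rule)
  expect_equal(r$score, 2L)
  expect_true(r$clinically_significant)
  expect_false(assign_score(mk(0.3, v = 0.4), rule)$clinically_significant)
  # score >= 4 is clinically significant regardless of volume
  expect_true(assign_score(mk(1.0, v = 0.1), rule)$clinically_significant)

  expect_error(assign_score(mk(-1), rule), "positive")
  expect_error(score_rule(t23 = 0.9, t34 = 0.8), "cut-points")
})

test_that("score is monotone in diameter; significance monotone in volume", {
  rule <- score_rule()
  d <- sort(runif(50, 0.1, 2))
  s <- vapply(d, function(x)
    assign_score(list(max_diameter_cm = x, volume_cc = 0.2), rule)$score,
    integer(1))
  expect_true(all(diff(s) >= 0))
  v <- sort(runif(50, 0.01, 1))
  cs <- vapply(v, function(x)
    assign_score(list(max_diameter_cm = 0.3, volume_cc = x),
                 rule)$clinically_significant, logical(1))
  expect_true(all(diff(cs) >= 0))
})

test_that("volume override promotes only score-3 lesions when enabled", {
  rule_on <- score_rule(volume_override = TRUE)
  m3 <- list(max_diameter_cm = 0.7, volume_cc = 0.6)
  expect_equal(assign_score(m3, score_rule())$score, 3L)
  expect_equal(assign_score(m3, rule_on)$score, 4L)
  m2 <- list(max_diameter_cm = 0.4, volume_cc = 0.6)
  expect_equal(assign_score(m2, rule_on)$score, 2L)
})

test_that("cohort scoring summarizes per observed score only", {
  tab <- data.frame(diameter_cm = c(0.3, 0.4, 0.5, 1.7),
                    volume_cc = c(0.1, 0.1, 0.2, 1.2))
  st <- score_cohort(tab)
  expect_equal(st$scores$score, c(2L, 2L, 2L, 5L))
  expect_setequal(st$summary$score, c(2L, 5L))   # scores 3, 4 absent
  r2 <- st$summary[st$summary$score == 2, ]
  expect_equal(r2$n, 3)
  expect_equal(r2$diameter_mean, 0.4)
  # single-class cohort: one summary row
  st2 <- score_cohort(data.frame(diameter_cm = c(0.2, 0.3, 0.4),
                                 volume_cc = c(0.1, 0.1, 0.1)))
  expect_equal(nrow(st2$summary), 1L)
  expect_error(score_cohort(list()), "at least one")
})

test_that("a cohort drawn from the class distributions scores consistently", {
  tab <- generate_feature_table(c("2" = 200, "5" = 200), seed = 12L)
  st <- score_cohort(tab)
  # lesions drawn from the score-5 size distribution land in the high
  # scores, those from score 2 in the low scores
  s5 <- st$scores$score[tab$score == "5"]
  s2 <- st$scores$score[tab$score == "2"]
  expect_gt(mean(s5 >= 4), 0.95)
  expect_gt(mean(s2 <= 3), 0.95)
  # the full score-5 draw (no selection) matches its generating mean
  expect_lt(abs(mean(tab$diameter_cm[tab$score == "5"]) - 1.45),
            3 * 0.15 / sqrt(200))
})
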