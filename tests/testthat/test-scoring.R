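test_that("trunk score bands and twist adjustment", {
  expect_equal(trunk_score(0), 1L)
  expect_equal(trunk_score(-10.2), 2L)    # mild extension
  expect_equal(trunk_score(15), 2L)
  expect_equal(trunk_score(45), 3L)
  expect_equal(trunk_score(-30), 3L)      # deep extension
  expect_equal(trunk_score(70), 4L)
  expect_equal(trunk_score(70, twisted = TRUE), 5L)
  expect_equal(trunk_score(70 + 20, twisted = TRUE), 5L)  # capped
  expect_error(trunk_score(NA), "missing")
})

test_that("neck, legs, arm and wrist scores follow the worksheet bands", {
  expect_equal(neck_score(10), 1L)
  expect_equal(neck_score(25), 2L)
  expect_equal(neck_score(-5), 2L)        # extension
  expect_equal(neck_score(25, TRUE), 3L)

  expect_equal(legs_score(0, 0, "bilateral"), 1L)
  expect_equal(legs_score(0, 45, "unilateral"), 3L)   # base 2 + flexion 1
  expect_equal(legs_score(5, 110, "kneeling"), 4L)    # base 2 + 2, capped
  expect_equal(legs_score(70, 75, "bilateral"), 3L)   # deep bilateral crouch
  expect_equal(legs_score(NA, 40, "unilateral"), 3L)

  expect_equal(upper_arm_score(10), 1L)
  expect_equal(upper_arm_score(30), 2L)
  expect_equal(upper_arm_score(-30), 2L)
  expect_equal(upper_arm_score(60), 3L)
  expect_equal(upper_arm_score(120), 4L)
  expect_equal(upper_arm_score(120, shoulder_raised = TRUE), 5L)
  expect_equal(upper_arm_score(10, gravity = TRUE), 1L)  # floors at 1
  expect_equal(upper_arm_score(30, gravity = TRUE), 1L)
  expect_equal(upper_arm_score(30, TRUE, TRUE), 2L)      # +1 then -1
  expect_true(is.na(upper_arm_score(NA)))

  expect_equal(lower_arm_score(80), 1L)
  expect_equal(lower_arm_score(10), 2L)
  expect_equal(lower_arm_score(140), 2L)

  expect_equal(wrist_score(7), 1L)
  expect_equal(wrist_score(20), 2L)
  expect_equal(wrist_score(20, TRUE), 3L)
  expect_equal(wrist_score(0, TRUE), 2L)
})

test_that("table lookups match their printed corners and reject bad input", {
  expect_equal(table_a(1, 1, 1), 1L)
  expect_equal(table_a(3, 5, 4), 9L)
  expect_equal(table_b(1, 1, 1), 1L)
  expect_equal(table_b(6, 2, 3), 9L)
  expect_equal(table_c(1, 1), 1L)
  expect_equal(table_c(12, 12), 12L)
  expect_equal(table_c(13, 14), 12L)   # clamps above 12
  expect_error(table_a(0, 1, 1), "neck")
  expect_error(table_a(1, 6, 1), "trunk")
  expect_error(table_b(7, 1, 1), "upper_arm")
})

test_that("tables are monotone in every argument", {
  for (n in 1:3) for (t in 1:5) for (l in 1:4) {
    v <- table_a(n, t, l)
    if (n < 3) expect_gte(table_a(n + 1, t, l), v)
    if (t < 5) expect_gte(table_a(n, t + 1, l), v)
    if (l < 4) expect_gte(table_a(n, t, l + 1), v)
  }
  for (u in 1:6) for (lo in 1:2) for (w in 1:3) {
    v <- table_b(u, lo, w)
    if (u < 6) expect_gte(table_b(u + 1, lo, w), v)
    if (lo < 2) expect_gte(table_b(u, lo + 1, w), v)
    if (w < 3) expect_gte(table_b(u, lo, w + 1), v)
  }
  for (a in 1:12) for (b in 1:12) {
    v <- table_c(a, b)
    if (a < 12) expect_gte(table_c(a + 1, b), v)
    if (b < 12) expect_gte(table_c(a, b + 1), v)
  }
})

test_that("modifier additions and the grand score behave additively", {
  expect_equal(score_a(1, 0), 1L)
  expect_equal(score_a(3, 2), 5L)
  expect_equal(score_a(9, 3), 12L)
  expect_equal(score_b(9, 3), 12L)
  expect_error(score_a(1, 4), "load")
  expect_equal(grand_score(1, 0), 1L)
  expect_equal(grand_score(12, 3), 15L)
  expect_equal(grand_score(5, 1), 6L)
})

test_that("risk level mapping covers the five published bands", {
  expect_equal(risk_level(1)$level, 1L)
  expect_identical(risk_level(1)$description, "Negligible risk")
  expect_equal(risk_level(2)$level, 2L)
  expect_equal(risk_level(5)$level, 3L)
  expect_identical(risk_level(5)$description,
                   "Medium risk. Further investigate change soon")
  expect_equal(risk_level(8)$level, 4L)
  expect_equal(risk_level(11)$level, 5L)
  expect_identical(risk_level(15)$description,
                   "Very high risk. Implement change")
  expect_error(risk_level(0), "out of range")
  expect_error(risk_level(16), "out of range")
})

test_that("end-to-end assessment of the upright posture scores 1", {
  sk <- build_skeleton(posture_specs()[["upright_standing"]])
  res <- reba_assess(sk, task_context(0, 0, 0))
  expect_equal(res$grand_score, 1L)
  expect_equal(res$risk_level, 1L)
  expect_equal(unlist(res$part_scores),
               c(neck = 1, trunk = 1, legs = 1, upper_arm = 1,
                 lower_arm = 2, wrist = 1))
  worse <- reba_assess(sk, task_context(3, 3, 3))
  expect_gt(worse$grand_score, res$grand_score)
})

test_that("a one-armed skeleton is scored from the visible side", {
  sk <- build_skeleton(posture_specs()[["standing_reach_forward"]])
  pres <- sk$present
  pres[c("left_shoulder", "left_elbow", "left_wrist")] <- FALSE
  one_arm <- skeleton(sk$coords[pres, , drop = FALSE])
  res <- reba_assess(one_arm, task_context())
  full <- reba_assess(sk, task_context())
  expect_equal(res$side_scores$upper_arm$left, NA_integer_)
  expect_equal(res$part_scores$upper_arm,
               full$side_scores$upper_arm$right)
  # and a skeleton with no arms at all names the missing part
  pres[c("right_shoulder", "right_elbow", "right_wrist")] <- FALSE
  no_arms <- skeleton(sk$coords[pres, , drop = FALSE])
  expect_error(reba_assess(no_arms, task_context()), "upper_arm")
})
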