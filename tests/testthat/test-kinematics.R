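test_that("absolute limb angle uses the full-quadrant arctangent", {
  expect_equal(absolute_limb_angle(c(0, 0), c(1, 1)), 45)
  expect_equal(absolute_limb_angle(c(0, 0), c(1, 0)), 0)
  # vertical limb: single-argument arctangent is undefined, the
  # two-argument extension must give 90
  expect_equal(absolute_limb_angle(c(0, 0), c(0, 1)), 90)
  expect_equal(absolute_limb_angle(c(2, 3), c(1, 3)), 180)
  expect_error(absolute_limb_angle(c(1, 1), c(1, 1)), "degenerate")
})

test_that("vertical reference rotation maps vertical to zero with region sign", {
  expect_equal(to_vertical_reference(90, TRUE), 0)
  expect_equal(to_vertical_reference(90, FALSE), 0)
  expect_equal(to_vertical_reference(0, FALSE), -90)
  expect_equal(abs(to_vertical_reference(0, FALSE)), 90)
  # round trip on the principal branch for limbs above the neck
  for (d in seq(-85, 85, by = 17)) {
    expect_equal(to_vertical_reference(90 - d, TRUE), d)
  }
})

test_that("relative limb angle is the normalised-dot-product arc cosine", {
  expect_equal(relative_limb_angle(c(0, 0), c(0, 1), c(0, 2)), 0)
  expect_equal(relative_limb_angle(c(0, 0), c(0, 1), c(1, 1)), 90)
  expect_equal(
    relative_limb_angle(c(0, 0), c(1, 0),
                        c(1 + cos(20 * pi / 180), sin(20 * pi / 180))),
    20, tolerance = 1e-9)
  expect_error(relative_limb_angle(c(0, 0), c(0, 0), c(1, 1)), "degenerate")
})

test_that("bilateral reduction takes the worse side with one-sided fallback", {
  expect_equal(bilateral_reduce(2, 3), 3)
  expect_equal(bilateral_reduce(4, NA), 4)
  expect_equal(bilateral_reduce(NA, 2), 2)
  for (k in 1:6) expect_equal(bilateral_reduce(k, k), k)  # idempotent
  # commutative and monotone
  for (a in 1:4) for (b in 1:4) {
    expect_equal(bilateral_reduce(a, b), bilateral_reduce(b, a))
    expect_gte(bilateral_reduce(a + 1, b), bilateral_reduce(a, b))
  }
  expect_error(bilateral_reduce(NA, NA, part = "wrist"), "wrist")
})

test_that("rigid rotation shifts absolute angles and preserves relative ones", {
  set.seed(42)
  specs <- posture_specs()
  rot <- function(p, phi) {
    r <- phi * pi / 180
    c(cos(r) * p[1] - sin(r) * p[2], sin(r) * p[1] + cos(r) * p[2])
  }
  for (phi in c(-77, 13, 131)) {
    for (nm in c("stoop_lift", "kneel_work")) {
      sk <- build_skeleton(specs[[nm]])
      a0 <- compute_angles(sk)
      co <- sk$coords
      co2 <- t(apply(co, 1, rot, phi = phi))
      colnames(co2) <- c("x", "y")
      sk2 <- skeleton(co2)
      # absolute angle of every limb shifts by exactly phi
      for (pair in list(c("mid_hip", "neck"), c("left_shoulder", "left_elbow"),
                        c("right_hip", "right_knee"))) {
        d <- absolute_limb_angle(joint_xy(sk2, pair[1]), joint_xy(sk2, pair[2])) -
          absolute_limb_angle(joint_xy(sk, pair[1]), joint_xy(sk, pair[2]))
        expect_equal(((d - phi + 180) %% 360) - 180, 0, tolerance = 1e-9)
      }
      # relative (hinge) angles are rotation invariant
      a1 <- compute_angles(sk2)
      for (part in c("leg_left", "leg_right", "lower_arm_left",
                     "lower_arm_right")) {
        expect_equal(a1[[part]], a0[[part]], tolerance = 1e-9)
      }
    }
  }
})

test_that("uniform scaling leaves every limb angle unchanged", {
  specs <- posture_specs()
  for (nm in names(specs)) {
    sk <- build_skeleton(specs[[nm]])
    a0 <- compute_angles(sk)
    for (s in c(0.25, 3.7)) {
      sk2 <- skeleton(sk$coords * s)
      a1 <- compute_angles(sk2)
      expect_equal(as.numeric(a1), as.numeric(a0), tolerance = 1e-9)
    }
  }
})

test_that("forward kinematics and angle recovery are mutually inverse", {
  specs <- posture_specs()
  expect_length(specs, 12)
  for (spec in specs) {
    sk <- build_skeleton(spec)
    ang <- compute_angles(sk)
    expect_equal(as.numeric(ang[names(spec$angles)]),
                 as.numeric(spec$angles), tolerance = 1e-6,
                 label = spec$name)
  }
})

test_that("absent joints propagate as undefined angles", {
  sk <- build_skeleton(posture_specs()[["upright_standing"]])
  pres <- sk$present
  pres[c("left_elbow", "right_elbow")] <- FALSE
  sk2 <- skeleton(sk$coords[pres, , drop = FALSE])
  ang <- compute_angles(sk2)
  expect_true(is.na(ang[["lower_arm_left"]]))
  expect_true(is.na(ang[["lower_arm_right"]]))
  expect_true(is.na(ang[["upper_arm_left"]]))
  expect_false(is.na(ang[["trunk"]]))
})

test_that("facing direction is inferred from the face and defaults left", {
  specs <- posture_specs()
  sk_r <- build_skeleton(specs[["stoop_lift"]])       # faces right
  sk_l <- build_skeleton(specs[["overhead_reach"]])   # faces left
  expect_equal(attr(compute_angles(sk_r), "facing"), 1)
  expect_equal(attr(compute_angles(sk_l), "facing"), -1)
  # strip the whole face: default is image-left
  pres <- sk_r$present
  pres[c("nose", "left_eye", "right_eye", "left_ear", "right_ear")] <- FALSE
  sk_blind <- skeleton(sk_r$coords[pres, , drop = FALSE])
  expect_equal(attr(compute_angles(sk_blind), "facing"), -1)
})
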