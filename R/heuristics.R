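# Automatic posture-judgment heuristics.
#
# A single 2D view cannot measure twist directly, so twist is inferred from
# exposure: how much of the chest (shoulder span) or face (ear span)
# transverse width is visible relative to what the skeleton's own scale
# predicts for a frontal view. A profile or twisted segment exposes a
# narrow span. Leg support, gravity-assisted arm, shoulder elevation and
# wrist twist follow simple angle/exposure rules with all thresholds held
# in reba_config().

#' Exposure ratio of a body region
#'
#' Ratio of the observed transverse width of a region to the width expected
#' for a frontal view, clipped to \[0, 1\]. The expected chest width is the
#' shoulder span predicted from skeleton scale (trunk length times an
#' anthropometric ratio); the face analogue uses ear span against the
#' neck-to-nose distance.
#'
#' @param region_width_observed Observed transverse width, pixels.
#' @param region_width_expected Expected frontal width, pixels; must be
#'   positive.
#' @return Fraction in \[0, 1\].
#' @export
exposure_ratio <- function(region_width_observed, region_width_expected) {
  if (!is.finite(region_width_expected) || region_width_expected <= 0) {
    stop("degenerate skeleton: expected region width must be positive",
         call. = FALSE)
  }
  max(0, min(1, region_width_observed / region_width_expected))
}

#' Chest and face exposure ratios of a skeleton
#'
#' @param sk A \code{\link{skeleton}}.
#' @param config A \code{\link{reba_config}} supplying the anthropometric
#'   width ratios.
#' @return Named list with \code{chest} and \code{face} fractions; either is
#'   \code{NA} when the joints needed are absent.
#' @export
skeleton_exposures <- function(sk, config = reba_config()) {
  chest <- NA_real_
  face <- NA_real_
  if (joint_present(sk, "left_shoulder") &&
      joint_present(sk, "right_shoulder") &&
      joint_present(sk, "neck") && joint_present(sk, "mid_hip")) {
    trunk_len <- sqrt(sum((joint_xy(sk, "neck") - joint_xy(sk, "mid_hip"))^2))
    observed <- abs(joint_xy(sk, "left_shoulder")["x"] -
                      joint_xy(sk, "right_shoulder")["x"])
    chest <- exposure_ratio(observed, config$chest_width_ratio * trunk_len)
  }
  if (joint_present(sk, "left_ear") && joint_present(sk, "right_ear") &&
      joint_present(sk, "neck") && joint_present(sk, "nose")) {
    head_len <- sqrt(sum((joint_xy(sk, "nose") - joint_xy(sk, "neck"))^2))
    observed <- abs(joint_xy(sk, "left_ear")["x"] -
                      joint_xy(sk, "right_ear")["x"])
    face <- exposure_ratio(observed, config$face_width_ratio * head_len)
  }
  list(chest = unname(chest), face = unname(face))
}

#' Detect trunk and neck twist from exposure ratios
#'
#' A segment is flagged as twisted when its exposure ratio reaches the
#' threshold, i.e. the comparison is inclusive: a ratio exactly at the
#' threshold counts as twisted. An \code{NA} ratio leaves the flag unset.
#'
#' @param chest_ratio,face_ratio Fractions in \[0, 1\] (or \code{NA}).
#' @param threshold Twist threshold, default 0.30.
#' @return Named logical list \code{trunk_twisted}, \code{neck_twisted}.
#' @export
#' @examples
#' detect_twist(chest_ratio = 0.30, face_ratio = 1)  # trunk twisted
detect_twist <- function(chest_ratio, face_ratio, threshold = 0.30) {
  list(
    trunk_twisted = isTRUE(chest_ratio <= threshold),
    neck_twisted = isTRUE(face_ratio <= threshold)
  )
}

#' Classify leg support
#'
#' Bilateral support when the two knee-flexion angles differ by less than
#' the threshold (default 30 degrees). When the difference reaches the
#' threshold the stance is single-leg support, or kneeling when the
#' more-flexed knee exceeds the kneel threshold (default 90 degrees,
#' strict). With only one leg visible the stance is taken as single-leg
#' support.
#'
#' @param leg_left_angle,leg_right_angle Knee flexion angles in degrees
#'   (\code{NA} when undefined).
#' @param leg_delta_threshold Angle-difference threshold, degrees.
#' @param kneel_threshold Kneeling knee-flexion threshold, degrees.
#' @return One of \code{"bilateral"}, \code{"unilateral"},
#'   \code{"kneeling"}.
#' @export
#' @examples
#' classify_leg_support(10, 50)   # "unilateral"
#' classify_leg_support(5, 110)   # "kneeling"
classify_leg_support <- function(leg_left_angle, leg_right_angle,
                                 leg_delta_threshold = 30,
                                 kneel_threshold = 90) {
  if (is.na(leg_left_angle) && is.na(leg_right_angle)) {
    stop("missing data: neither leg angle is defined", call. = FALSE)
  }
  if (is.na(leg_left_angle) || is.na(leg_right_angle)) return("unilateral")
  delta <- abs(leg_left_angle - leg_right_angle)
  if (delta < leg_delta_threshold) return("bilateral")
  flexed <- max(leg_left_angle, leg_right_angle)
  if (flexed > kneel_threshold) "kneeling" else "unilateral"
}

#' Gravity-assisted upper-arm position
#'
#' When the trunk is strongly flexed while the upper arm hangs near
#' vertical, the arm is supported by gravity and REBA credits the upper-arm
#' score with -1.
#'
#' @param trunk_angle,upper_arm_angle Signed angles in degrees.
#' @param trunk_min Minimum absolute trunk flexion, default 45.
#' @param arm_max Maximum absolute upper-arm angle, default 20.
#' @return Logical.
#' @export
#' @examples
#' gravity_assisted(60, 5)   # TRUE
#' gravity_assisted(60, 60)  # FALSE
gravity_assisted <- function(trunk_angle, upper_arm_angle,
                             trunk_min = 45, arm_max = 20) {
  if (is.na(trunk_angle) || is.na(upper_arm_angle)) return(FALSE)
  abs(trunk_angle) >= trunk_min && abs(upper_arm_angle) <= arm_max
}

#' Shoulder elevation (shrug) detection
#'
#' Measures the angle at the neck between the two neck-to-shoulder lines.
#' With relaxed shoulders the three joints are nearly collinear (180
#' degrees); raised shoulders fold the lines upward. The flag fires when
#' the deviation from a straight line exceeds the threshold. A missing
#' joint degrades to \code{FALSE} with a warning attribute.
#'
#' @param neck_point,l_shoulder,r_shoulder \code{c(x, y)} pairs, or
#'   \code{NULL} when absent.
#' @param threshold Deviation threshold in degrees, default 25.
#' @return Logical with attribute \code{warning} when degraded.
#' @export
shoulder_raised <- function(neck_point, l_shoulder, r_shoulder,
                            threshold = 25) {
  if (is.null(neck_point) || is.null(l_shoulder) || is.null(r_shoulder)) {
    return(structure(FALSE,
                     warning = "shoulder joint missing; flag defaulted"))
  }
  between <- relative_limb_angle(l_shoulder, neck_point, r_shoulder)
  # relative_limb_angle() measures the turn of the path l -> neck -> r:
  # collinear shoulders give 0 turn, i.e. a straight 180-degree line
  deviation <- between
  deviation > threshold
}

#' Wrist twist from hand exposure
#'
#' With no hand keypoints in the skeleton model, wrist/forearm twist is
#' inferred from how much of the hand is exposed: a mostly occluded hand
#' (exposure at or below the threshold) indicates a twisted wrist. The
#' exposure is supplied externally (e.g. from a hand detector) and
#' defaults to 1 (fully exposed, no twist).
#'
#' @param hand_exposure Fraction in \[0, 1\].
#' @param threshold Twist threshold, default 0.30 (inclusive).
#' @return Logical.
#' @export
wrist_flip <- function(hand_exposure = 1, threshold = 0.30) {
  stop_unless(is_fraction(hand_exposure), "hand_exposure must be in [0, 1]")
  hand_exposure <= threshold
}

#' All heuristic flags for a skeleton
#'
#' Runs every automatic judgment rule and returns the flag set consumed by
#' the scoring chain. Flags default to their non-penalising values when the
#' joints driving them are absent.
#'
#' @param sk A \code{\link{skeleton}}.
#' @param angles Optional precomputed \code{\link{compute_angles}} result.
#' @param config A \code{\link{reba_config}}.
#' @param hand_exposure External hand-exposure fraction, default 1.
#' @return Named list: \code{trunk_twisted}, \code{neck_twisted},
#'   \code{leg_support}, \code{upper_arm_gravity_assisted} (per side),
#'   \code{shoulder_raised}, \code{wrist_twisted}.
#' @export
heuristic_flags <- function(sk, angles = NULL, config = reba_config(),
                            hand_exposure = 1) {
  if (is.null(angles)) angles <- compute_angles(sk, config)
  expo <- skeleton_exposures(sk, config)
  tw <- detect_twist(expo$chest, expo$face, config$twist_threshold)
  support <- if (is.na(angles["leg_left"]) && is.na(angles["leg_right"])) {
    "bilateral"
  } else {
    classify_leg_support(angles[["leg_left"]], angles[["leg_right"]],
                         config$leg_delta_threshold, config$kneel_threshold)
  }
  grav <- vapply(c(left = "upper_arm_left", right = "upper_arm_right"),
                 function(nm) gravity_assisted(angles[["trunk"]],
                                               angles[[nm]],
                                               config$gravity_trunk_min,
                                               config$gravity_arm_max),
                 logical(1))
  shr <- shoulder_raised(
    if (joint_present(sk, "neck")) joint_xy(sk, "neck") else NULL,
    if (joint_present(sk, "left_shoulder")) joint_xy(sk, "left_shoulder")
    else NULL,
    if (joint_present(sk, "right_shoulder")) joint_xy(sk, "right_shoulder")
    else NULL,
    config$shoulder_threshold)
  list(
    trunk_twisted = tw$trunk_twisted,
    neck_twisted = tw$neck_twisted,
    leg_support = support,
    upper_arm_gravity_assisted = as.list(grav),
    shoulder_raised = as.logical(shr),
    wrist_twisted = wrist_flip(hand_exposure, config$wrist_flip_threshold),
    chest_exposure = expo$chest,
    face_exposure = expo$face
  )
}
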