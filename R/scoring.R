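# The REBA scoring chain.
#
# Angle-to-score binning follows the canonical worksheet bands; the
# automatic heuristic flags supply the twist, support, shoulder and
# gravity adjustments that an observer would normally judge by eye.
# Adjustment order for the upper arm: +1 shoulder raised first, then the
# -1 gravity credit, floored at 1.

#' Trunk score from trunk flexion angle
#'
#' Bands: exactly upright (0 degrees) scores 1; up to 20 degrees of flexion
#' or extension scores 2; 20-60 degrees of flexion, or more than 20 degrees
#' of extension, scores 3; over 60 degrees of flexion scores 4. Twisting
#' (or side flexion) adds 1; the score caps at 5.
#'
#' @param angle Signed trunk angle in degrees (flexion positive).
#' @param twisted Logical trunk-twist flag.
#' @return Integer 1-5.
#' @export
trunk_score <- function(angle, twisted = FALSE) {
  if (is.na(angle)) stop("missing data: trunk angle undefined", call. = FALSE)
  base <- if (angle == 0) 1L
  else if (abs(angle) <= 20) 2L
  else if (angle > 20 && angle <= 60) 3L
  else if (angle < -20) 3L
  else 4L
  min(base + as.integer(isTRUE(twisted)), 5L)
}

#' Neck score from neck flexion angle
#'
#' Flexion of 0-20 degrees scores 1; more than 20 degrees of flexion, or
#' any extension, scores 2. Twisting adds 1; the score caps at 3.
#'
#' @param angle Signed neck angle in degrees (flexion positive).
#' @param twisted Logical neck-twist flag.
#' @return Integer 1-3.
#' @export
neck_score <- function(angle, twisted = FALSE) {
  if (is.na(angle)) stop("missing data: neck angle undefined", call. = FALSE)
  base <- if (angle >= 0 && angle <= 20) 1L else 2L
  min(base + as.integer(isTRUE(twisted)), 3L)
}

knee_adder <- function(flexion) {
  if (is.na(flexion)) return(NA_integer_)
  if (flexion > 60) 2L else if (flexion >= 30) 1L else 0L
}

#' Legs score from knee flexion and support classification
#'
#' Bilateral support scores a base of 1; single-leg support or kneeling
#' scores 2. Knee flexion adds 1 at 30-60 degrees and 2 beyond 60 degrees,
#' per side, and the worse side is kept. Caps at 4.
#'
#' @param leg_left_angle,leg_right_angle Knee flexion angles in degrees
#'   (\code{NA} for an unseen leg; at least one must be defined).
#' @param support \code{"bilateral"}, \code{"unilateral"} or
#'   \code{"kneeling"}; computed from the angles when \code{NULL}.
#' @return Integer 1-4.
#' @export
legs_score <- function(leg_left_angle, leg_right_angle, support = NULL) {
  if (is.null(support)) {
    support <- classify_leg_support(leg_left_angle, leg_right_angle)
  }
  base <- if (support == "bilateral") 1L else 2L
  sides <- c(knee_adder(leg_left_angle), knee_adder(leg_right_angle))
  adder <- bilateral_reduce(sides[1], sides[2], part = "legs")
  min(base + adder, 4L)
}

#' Upper-arm score from shoulder flexion angle
#'
#' Bands: within 20 degrees of hanging vertical scores 1; 20-45 degrees of
#' flexion or over 20 degrees of extension scores 2; 45-90 degrees scores
#' 3; over 90 degrees scores 4. A raised shoulder adds 1 and a
#' gravity-assisted position subtracts 1 (applied after the addition,
#' floored at 1). Caps at 6.
#'
#' @param angle Signed upper-arm angle in degrees.
#' @param shoulder_raised Logical shrug flag.
#' @param gravity Logical gravity-assisted flag.
#' @return Integer 1-6, or \code{NA} when \code{angle} is \code{NA}.
#' @export
upper_arm_score <- function(angle, shoulder_raised = FALSE,
                            gravity = FALSE) {
  if (is.na(angle)) return(NA_integer_)
  base <- if (abs(angle) <= 20) 1L
  else if (angle > 20 && angle <= 45) 2L
  else if (angle < -20) 2L
  else if (angle <= 90) 3L
  else 4L
  s <- base + as.integer(isTRUE(shoulder_raised))
  s <- s - as.integer(isTRUE(gravity))
  min(max(s, 1L), 6L)
}

#' Lower-arm score from elbow flexion angle
#'
#' Elbow flexion of 60-100 degrees (measured from the straight arm) scores
#' 1; anything else - a straighter or more folded elbow - scores 2.
#'
#' @param angle Elbow flexion in \[0, 180\] degrees.
#' @return Integer 1-2, or \code{NA} when \code{angle} is \code{NA}.
#' @export
lower_arm_score <- function(angle) {
  if (is.na(angle)) return(NA_integer_)
  if (angle >= 60 && angle <= 100) 1L else 2L
}

#' Wrist score from wrist flexion angle
#'
#' Within 15 degrees of neutral scores 1, beyond scores 2; wrist twist
#' (from the hand-exposure heuristic) adds 1. Caps at 3.
#'
#' @param angle Signed wrist angle in degrees.
#' @param flipped Logical wrist-twist flag.
#' @return Integer 1-3, or \code{NA} when \code{angle} is \code{NA}.
#' @export
wrist_score <- function(angle, flipped = FALSE) {
  if (is.na(angle)) return(NA_integer_)
  base <- if (abs(angle) <= 15) 1L else 2L
  min(base + as.integer(isTRUE(flipped)), 3L)
}

#' Score A: Table A plus the load modifier
#'
#' @param table_a_value Table A result, 1-9.
#' @param load Force/load score, 0-3.
#' @return Integer 1-12.
#' @export
score_a <- function(table_a_value, load) {
  stop_unless(is_count_0_3(load), "load must be an integer in 0..3")
  as.integer(table_a_value + load)
}

#' Score B: Table B plus the coupling modifier
#'
#' @param table_b_value Table B result, 1-9.
#' @param coupling Coupling score, 0-3.
#' @return Integer 1-12.
#' @export
score_b <- function(table_b_value, coupling) {
  stop_unless(is_count_0_3(coupling), "coupling must be an integer in 0..3")
  as.integer(table_b_value + coupling)
}

#' Grand REBA score: score C plus the activity modifier
#'
#' @param score_c Table C result, 1-12.
#' @param activity Activity/frequency score, 0-3.
#' @return Integer in \[1, 15\].
#' @export
grand_score <- function(score_c, activity) {
  stop_unless(is_count_0_3(activity), "activity must be an integer in 0..3")
  min(max(as.integer(score_c + activity), 1L), 15L)
}

RISK_TABLE <- data.frame(
  level = 1:5,
  description = c(
    "Negligible risk",
    "Low risk. Change may be needed",
    "Medium risk. Further investigate change soon",
    "High risk. Investigate and implement change",
    "Very high risk. Implement change"
  ),
  stringsAsFactors = FALSE
)

#' Risk level and description for a grand score
#'
#' Grand score 1 is level 1 (negligible); 2-3 level 2 (low); 4-7 level 3
#' (medium); 8-10 level 4 (high); 11 and above level 5 (very high).
#'
#' @param grand Grand REBA score in \[1, 15\].
#' @return List with integer \code{level} and character
#'   \code{description}.
#' @export
#' @examples
#' risk_level(5)   # level 3, medium risk
risk_level <- function(grand) {
  if (!is.numeric(grand) || length(grand) != 1L || is.na(grand) ||
      grand != as.integer(grand) || grand < 1 || grand > 15) {
    stop("grand score out of range 1..15: ", grand, call. = FALSE)
  }
  level <- if (grand <= 1) 1L
  else if (grand <= 3) 2L
  else if (grand <= 7) 3L
  else if (grand <= 10) 4L
  else 5L
  list(level = level, description = RISK_TABLE$description[level])
}

#' Assess a posture: the full REBA pipeline
#'
#' Runs the complete chain on a skeleton: limb angles, heuristic flags,
#' per-part scores with bilateral max reduction on paired parts, Tables A
#' and B with the load and coupling modifiers, Table C, the activity
#' modifier and the risk level. Every intermediate is kept in the result.
#'
#' @param sk A \code{\link{skeleton}}.
#' @param context A \code{\link{task_context}}.
#' @param config A \code{\link{reba_config}}.
#' @param hand_exposure External hand-exposure fraction for the wrist-twist
#'   heuristic, default 1 (no twist).
#' @return An object of class \code{"reba_result"}; see
#'   \code{\link{write_report}} for its serialised shape.
#' @export
#' @examples
#' sk <- build_skeleton(posture_specs()[["upright_standing"]])
#' res <- reba_assess(sk, task_context(0, 0, 0))
#' res$grand_score
reba_assess <- function(sk, context = task_context(),
                        config = reba_config(), hand_exposure = 1) {
  stopifnot(inherits(sk, "skeleton"), inherits(context, "task_context"))
  angles <- compute_angles(sk, config)
  # snap to nanodegree precision so floating-point wobble at an exact band
  # boundary (e.g. a synthetic 20-degree neck recovered as 20 + 1e-14)
  # cannot flip a score bin
  angles <- round(angles, 9)
  flags <- heuristic_flags(sk, angles, config, hand_exposure)

  p_neck <- neck_score(angles[["neck"]], flags$neck_twisted)
  p_trunk <- trunk_score(angles[["trunk"]], flags$trunk_twisted)
  if (is.na(angles[["leg_left"]]) && is.na(angles[["leg_right"]])) {
    stop("missing data: neither side of 'legs' is defined", call. = FALSE)
  }
  p_legs <- legs_score(angles[["leg_left"]], angles[["leg_right"]],
                       flags$leg_support)

  ua <- c(
    left = upper_arm_score(angles[["upper_arm_left"]], flags$shoulder_raised,
                           flags$upper_arm_gravity_assisted$left),
    right = upper_arm_score(angles[["upper_arm_right"]],
                            flags$shoulder_raised,
                            flags$upper_arm_gravity_assisted$right)
  )
  la <- c(left = lower_arm_score(angles[["lower_arm_left"]]),
          right = lower_arm_score(angles[["lower_arm_right"]]))
  wr <- c(left = wrist_score(angles[["wrist_left"]], flags$wrist_twisted),
          right = wrist_score(angles[["wrist_right"]], flags$wrist_twisted))
  p_ua <- bilateral_reduce(ua["left"], ua["right"], part = "upper_arm")
  p_la <- bilateral_reduce(la["left"], la["right"], part = "lower_arm")
  p_wr <- bilateral_reduce(wr["left"], wr["right"], part = "wrist")

  ta <- table_a(p_neck, p_trunk, p_legs)
  tb <- table_b(p_ua, p_la, p_wr)
  sa <- score_a(ta, context$load)
  sb <- score_b(tb, context$coupling)
  sc <- table_c(sa, sb)
  grand <- grand_score(sc, context$activity)
  risk <- risk_level(grand)

  plain_angles <- stats::setNames(as.numeric(angles), names(angles))
  flags$facing <- attr(angles, "facing")
  res <- list(
    part_scores = list(neck = p_neck, trunk = p_trunk, legs = p_legs,
                       upper_arm = as.integer(p_ua),
                       lower_arm = as.integer(p_la),
                       wrist = as.integer(p_wr)),
    side_scores = list(upper_arm = as.list(ua), lower_arm = as.list(la),
                       wrist = as.list(wr)),
    table_a_value = ta, table_b_value = tb,
    score_a = sa, score_b = sb, score_c = sc,
    grand_score = grand,
    risk_level = risk$level,
    risk_description = risk$description,
    angles = plain_angles,
    flags = flags,
    context = context
  )
  class(res) <- "reba_result"
  res
}

#' @export
print.reba_result <- function(x, ...) {
  cat(sprintf("REBA assessment: grand score %d, risk level %d\n  %s\n",
              x$grand_score, x$risk_level, x$risk_description))
  invisible(x)
}

#' @export
summary.reba_result <- function(object, ...) {
  x <- object
  cat("REBA assessment\n")
  cat("  Part scores:  ",
      paste(sprintf("%s=%d", names(x$part_scores),
                    unlist(x$part_scores)), collapse = "  "), "\n")
  cat(sprintf("  Table A = %d, + load %d    -> score A = %d\n",
              x$table_a_value, x$context$load, x$score_a))
  cat(sprintf("  Table B = %d, + coupling %d -> score B = %d\n",
              x$table_b_value, x$context$coupling, x$score_b))
  cat(sprintf("  Table C = %d, + activity %d -> grand score = %d\n",
              x$score_c, x$context$activity, x$grand_score))
  cat(sprintf("  Risk level %d: %s\n", x$risk_level, x$risk_description))
  flg <- x$flags
  on <- c(if (isTRUE(flg$trunk_twisted)) "trunk twisted",
          if (isTRUE(flg$neck_twisted)) "neck twisted",
          if (!identical(flg$leg_support, "bilateral")) flg$leg_support,
          if (isTRUE(flg$upper_arm_gravity_assisted$left) ||
                isTRUE(flg$upper_arm_gravity_assisted$right))
            "gravity-assisted arm",
          if (isTRUE(flg$shoulder_raised)) "shoulder raised",
          if (isTRUE(flg$wrist_twisted)) "wrist twisted")
  cat("  Heuristics:   ",
      if (length(on)) paste(on, collapse = ", ") else "none active", "\n")
  invisible(x)
}
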