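# Limb-angle kinematics.
#
# A limb is the vector between two joint points. Its absolute angle is the
# full-quadrant arctangent of (dy, dx); the single-argument arctangent form
# is undefined for vertical limbs, which are the common case (an upright
# trunk), so the two-argument extension is used throughout and agrees with
# the single-argument form on its principal branch. REBA references angles
# to the vertical, so absolute angles are rotated into a signed deviation
# from the vertical axis, with flexion toward the body's facing direction
# taken as positive. Hinge joints (elbow, knee) use the relative angle
# between adjacent limbs, the arc-cosine of the normalised dot product.

RAD2DEG <- 180 / pi

# signed counter-clockwise angle (degrees, (-180, 180]) from vector a to b
ang_ccw <- function(a, b) {
  d <- unname(atan2(a[1] * b[2] - a[2] * b[1],
                    a[1] * b[1] + a[2] * b[2])) * RAD2DEG
  if (d <= -180) d + 360 else d
}

rotate2 <- function(v, deg) {
  r <- deg / RAD2DEG
  c(cos(r) * v[1] - sin(r) * v[2], sin(r) * v[1] + cos(r) * v[2])
}

wrap180 <- function(d) {
  d <- (d + 180) %% 360 - 180
  ifelse(d == -180, 180, d)
}

#' Absolute limb angle
#'
#' Direction angle (degrees) of the limb from \code{p_proximal} to
#' \code{p_distal}, measured from the positive x axis with the
#' full-quadrant arctangent of \code{(dy, dx)}, in (-180, 180].
#'
#' @param p_proximal,p_distal Numeric \code{c(x, y)} coordinate pairs in the
#'   y-up frame.
#' @return Angle in degrees.
#' @export
#' @examples
#' absolute_limb_angle(c(0, 0), c(1, 1))  # 45
#' absolute_limb_angle(c(0, 0), c(0, 1))  # 90 (vertical limb)
absolute_limb_angle <- function(p_proximal, p_distal) {
  d <- p_distal - p_proximal
  if (all(d == 0)) {
    stop("degenerate limb: proximal and distal points coincide",
         call. = FALSE)
  }
  unname(atan2(d[2], d[1])) * RAD2DEG
}

#' Rotate an absolute limb angle to the vertical reference
#'
#' REBA measures postural angles against the vertical, so the x-referenced
#' absolute angle is rotated: a limb aligned with the vertical maps to 0.
#' The sign convention follows the body region: for limbs above the neck
#' the signed deviation is returned as-is, for limbs below the neck its
#' sign is inverted.
#'
#' @param theta Absolute limb angle in degrees.
#' @param above_neck Logical; is the limb above the neck?
#' @return Signed deviation from vertical, degrees in (-180, 180].
#' @export
#' @examples
#' to_vertical_reference(90, TRUE)    # 0: vertical limb
#' to_vertical_reference(0, FALSE)    # -90: horizontal limb below the neck
to_vertical_reference <- function(theta, above_neck = TRUE) {
  d <- wrap180(90 - theta)
  if (above_neck) d else -d
}

#' Relative angle between adjacent limbs
#'
#' Angle (degrees, in \[0, 180\]) between the limb \code{p_mid -> p_next}
#' and the preceding limb \code{p_prev -> p_mid}: the arc-cosine of the
#' normalised dot product of the two limb vectors. Collinear continuation
#' gives 0 (a straight joint); a fully folded joint gives 180.
#'
#' @param p_prev,p_mid,p_next Numeric \code{c(x, y)} coordinate pairs.
#' @return Angle in degrees.
#' @export
#' @examples
#' relative_limb_angle(c(0, 0), c(0, 1), c(0, 2))  # 0, straight
#' relative_limb_angle(c(0, 0), c(0, 1), c(1, 1))  # 90
relative_limb_angle <- function(p_prev, p_mid, p_next) {
  u <- p_mid - p_prev
  v <- p_next - p_mid
  if (all(u == 0) || all(v == 0)) {
    stop("degenerate limb: adjacent joint points coincide", call. = FALSE)
  }
  cs <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(max(-1, min(1, cs))) * RAD2DEG
}

#' Bilateral maximum reduction
#'
#' REBA scores paired parts (wrist, upper arm, lower arm, leg) with the
#' worse of the two sides; when only one side was recognised, that side is
#' used alone. \code{NA} marks an undefined side.
#'
#' @param left_score,right_score Integer part scores or \code{NA}.
#' @param part Part name used in the error message.
#' @return The maximum of the defined sides.
#' @export
#' @examples
#' bilateral_reduce(2, 3)   # 3
#' bilateral_reduce(4, NA)  # 4
bilateral_reduce <- function(left_score, right_score, part = "part") {
  if (is.na(left_score) && is.na(right_score)) {
    stop("missing data: neither side of '", part, "' is defined",
         call. = FALSE)
  }
  max(left_score, right_score, na.rm = TRUE)
}

# facing direction: +1 if facing image-right (+x), -1 if image-left.
# The nose is anterior and the ears posterior, so nose minus ear-midpoint is
# the most reliable cue; nose-vs-neck and eye-midpoint-vs-neck are
# fallbacks. Defaults to image-left when the face gives no cue.
infer_facing <- function(sk, tol = 1e-9) {
  if (joint_present(sk, "nose")) {
    nose <- joint_xy(sk, "nose")
    if (joint_present(sk, "left_ear") && joint_present(sk, "right_ear")) {
      em <- (joint_xy(sk, "left_ear") + joint_xy(sk, "right_ear")) / 2
      dx <- nose["x"] - em["x"]
      if (abs(dx) > tol) return(unname(sign(dx)))
    }
    if (joint_present(sk, "neck")) {
      dx <- nose["x"] - joint_xy(sk, "neck")["x"]
      if (abs(dx) > tol) return(unname(sign(dx)))
    }
  }
  if (joint_present(sk, "left_eye") && joint_present(sk, "right_eye") &&
      joint_present(sk, "neck")) {
    em <- (joint_xy(sk, "left_eye") + joint_xy(sk, "right_eye")) / 2
    dx <- em["x"] - joint_xy(sk, "neck")["x"]
    if (abs(dx) > tol) return(unname(sign(dx)))
  }
  -1
}

# signed deviation from vertical with flexion-toward-facing positive.
# up = TRUE for limbs whose rest direction points up (trunk), FALSE for
# limbs hanging down at rest (upper arm, upper leg).
vertical_deviation <- function(v, facing, up = TRUE) {
  ref <- if (up) c(0, 1) else c(0, -1)
  s <- if (up) -facing else facing
  s * ang_ccw(ref, v)
}

ANGLE_NAMES <- c("neck", "trunk", "leg_left", "leg_right",
                 "upper_arm_left", "upper_arm_right",
                 "lower_arm_left", "lower_arm_right",
                 "wrist_left", "wrist_right")

#' Compute the ten REBA limb angles from a skeleton
#'
#' Populates the ten body-part angles used by REBA: trunk and neck as
#' signed vertical-referenced angles (flexion toward the facing direction
#' positive; the neck is measured against the trunk line by default), knee
#' and elbow as relative angles in \[0, 180\] (0 = straight), upper arms as
#' signed deviation of the shoulder-to-elbow segment from hanging vertical.
#' The 18/19-joint model has no hand keypoints, so wrist flexion defaults to
#' 0 with a low-confidence marker; wrist twist is handled by the exposure
#' heuristic instead. Angles whose joints are absent are \code{NA}.
#'
#' @param sk A \code{\link{skeleton}}.
#' @param config A \code{\link{reba_config}}.
#' @return A named numeric vector of class \code{"limb_angles"} with
#'   elements \code{neck, trunk, leg_left, leg_right, upper_arm_left,
#'   upper_arm_right, lower_arm_left, lower_arm_right, wrist_left,
#'   wrist_right} (degrees), with attributes \code{facing} (+1/-1) and
#'   \code{wrist_low_confidence}.
#' @export
compute_angles <- function(sk, config = reba_config()) {
  stopifnot(inherits(sk, "skeleton"))
  facing <- infer_facing(sk)
  ang <- stats::setNames(rep(NA_real_, length(ANGLE_NAMES)), ANGLE_NAMES)

  trunk_vec <- NULL
  if (joint_present(sk, "mid_hip") && joint_present(sk, "neck")) {
    trunk_vec <- joint_xy(sk, "neck") - joint_xy(sk, "mid_hip")
    ang["trunk"] <- vertical_deviation(trunk_vec, facing, up = TRUE)
  }

  head_distal <- if (config$neck_distal == "nose") {
    if (joint_present(sk, "nose")) joint_xy(sk, "nose") else NULL
  } else {
    if (joint_present(sk, "left_ear") && joint_present(sk, "right_ear")) {
      (joint_xy(sk, "left_ear") + joint_xy(sk, "right_ear")) / 2
    } else NULL
  }
  if (!is.null(head_distal) && joint_present(sk, "neck")) {
    head_vec <- head_distal - joint_xy(sk, "neck")
    if (config$neck_reference == "trunk" && !is.null(trunk_vec)) {
      ang["neck"] <- -facing * ang_ccw(trunk_vec, head_vec)
    } else {
      ang["neck"] <- vertical_deviation(head_vec, facing, up = TRUE)
    }
  }

  for (side in c("left", "right")) {
    sh <- paste0(side, "_shoulder"); el <- paste0(side, "_elbow")
    wr <- paste0(side, "_wrist")
    hp <- paste0(side, "_hip"); kn <- paste0(side, "_knee")
    an <- paste0(side, "_ankle")
    if (joint_present(sk, sh) && joint_present(sk, el)) {
      ang[paste0("upper_arm_", side)] <-
        vertical_deviation(joint_xy(sk, el) - joint_xy(sk, sh), facing,
                           up = FALSE)
      if (joint_present(sk, wr)) {
        ang[paste0("lower_arm_", side)] <-
          relative_limb_angle(joint_xy(sk, sh), joint_xy(sk, el),
                              joint_xy(sk, wr))
      }
    }
    if (joint_present(sk, hp) && joint_present(sk, kn) &&
        joint_present(sk, an)) {
      ang[paste0("leg_", side)] <-
        relative_limb_angle(joint_xy(sk, hp), joint_xy(sk, kn),
                            joint_xy(sk, an))
    }
    # no hand keypoints: wrist flexion defaults to 0 when the wrist exists
    if (joint_present(sk, wr)) ang[paste0("wrist_", side)] <- 0
  }

  structure(ang, facing = facing, wrist_low_confidence = TRUE,
            class = "limb_angles")
}

#' @export
print.limb_angles <- function(x, ...) {
  cat("REBA limb angles (degrees):\n")
  v <- unclass(x)
  attributes(v) <- list(names = names(v))
  print(round(v, 2))
  cat(sprintf("facing: image-%s; wrist angles are low-confidence proxies\n",
              if (attr(x, "facing") > 0) "right" else "left"))
  invisible(x)
}

#' Limb definition table
#'
#' The proximal/distal joint pairs defining each REBA body-part angle, and
#' whether the angle is vertical-referenced (signed) or relative (hinge).
#'
#' @return A data frame with columns \code{part}, \code{proximal},
#'   \code{mid}, \code{distal}, \code{kind}.
#' @export
limb_definitions <- function() {
  data.frame(
    part = c("trunk", "neck", "upper_arm_left", "upper_arm_right",
             "lower_arm_left", "lower_arm_right", "leg_left", "leg_right",
             "wrist_left", "wrist_right"),
    proximal = c("mid_hip", "neck", "left_shoulder", "right_shoulder",
                 "left_shoulder", "right_shoulder", "left_hip", "right_hip",
                 "left_elbow", "right_elbow"),
    mid = c(NA, NA, NA, NA, "left_elbow", "right_elbow", "left_knee",
            "right_knee", NA, NA),
    distal = c("neck", "nose", "left_elbow", "right_elbow", "left_wrist",
               "right_wrist", "left_knee", "right_knee", "left_wrist",
               "right_wrist"),
    kind = c("vertical", "trunk-relative", "vertical", "vertical",
             "relative", "relative", "relative", "relative",
             "hand-proxy", "hand-proxy"),
    stringsAsFactors = FALSE
  )
}
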