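#' Canonical joint names of the 19-point skeleton model
#'
#' The skeleton model is the 18-keypoint COCO body layout of
#' convolutional-pose-machine estimators, plus a \code{mid_hip} joint
#' synthesised as the midpoint of the two hips when the source does not
#' provide one. The ordering below is the package's canonical ordering; the
#' first 18 names follow the COCO keypoint order.
#'
#' @format A character vector of length 19.
#' @export
REBA_JOINTS <- c(
  "nose", "neck",
  "right_shoulder", "right_elbow", "right_wrist",
  "left_shoulder", "left_elbow", "left_wrist",
  "right_hip", "right_knee", "right_ankle",
  "left_hip", "left_knee", "left_ankle",
  "right_eye", "left_eye", "right_ear", "left_ear",
  "mid_hip"
)

# BODY_25 source ordering (feet keypoints 20-25 are dropped)
BODY25_TO_CANONICAL <- c(
  "nose", "neck",
  "right_shoulder", "right_elbow", "right_wrist",
  "left_shoulder", "left_elbow", "left_wrist",
  "mid_hip",
  "right_hip", "right_knee", "right_ankle",
  "left_hip", "left_knee", "left_ankle",
  "right_eye", "left_eye", "right_ear", "left_ear"
)

#' Construct a skeleton from joint coordinates
#'
#' A skeleton holds the 19 canonical joints as rows of a coordinate matrix in
#' a y-up mathematical frame, together with per-joint confidences and
#' presence flags. Joints marked absent must never be read by the
#' kinematics; their coordinates are stored as \code{NA}.
#'
#' @param xy Numeric matrix with one row per canonical joint (rownames from
#'   \code{\link{REBA_JOINTS}}, any order; missing joints allowed) and columns
#'   \code{x}, \code{y}, in the y-up frame.
#' @param confidence Named numeric vector of per-joint confidences in
#'   \[0, 1\]; defaults to 1 for every supplied joint.
#' @param present Named logical vector; defaults to \code{TRUE} for supplied
#'   joints with finite coordinates.
#' @param source_image_size Optional \code{c(width, height)} in pixels of the
#'   source image, recorded when coordinates were converted from image
#'   (y-down) convention.
#'
#' @return An object of class \code{"skeleton"}.
#' @export
skeleton <- function(xy, confidence = NULL, present = NULL,
                     source_image_size = NULL) {
  stop_unless(is.matrix(xy) && ncol(xy) == 2 && !is.null(rownames(xy)),
              "xy must be a matrix with columns x, y and joint rownames")
  bad <- setdiff(rownames(xy), REBA_JOINTS)
  if (length(bad)) {
    stop("unknown joint name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  coords <- matrix(NA_real_, nrow = length(REBA_JOINTS), ncol = 2,
                   dimnames = list(REBA_JOINTS, c("x", "y")))
  coords[rownames(xy), ] <- xy
  conf <- stats::setNames(rep(0, length(REBA_JOINTS)), REBA_JOINTS)
  conf[rownames(xy)] <- 1
  if (!is.null(confidence)) conf[names(confidence)] <- confidence
  pres <- stats::setNames(rep(FALSE, length(REBA_JOINTS)), REBA_JOINTS)
  pres[rownames(xy)] <- apply(is.finite(xy), 1, all)
  if (!is.null(present)) pres[names(present)] <- present
  pres <- pres & apply(is.finite(coords), 1, all)
  coords[!pres, ] <- NA_real_
  conf[!pres] <- 0
  # synthesise mid_hip from the two hips when absent
  if (!pres["mid_hip"] && pres["left_hip"] && pres["right_hip"]) {
    coords["mid_hip", ] <- (coords["left_hip", ] + coords["right_hip", ]) / 2
    conf["mid_hip"] <- min(conf["left_hip"], conf["right_hip"])
    pres["mid_hip"] <- TRUE
  }
  if (!any(pres)) stop("skeleton rejected: no joint present", call. = FALSE)
  structure(list(coords = coords, confidence = conf, present = pres,
                 source_image_size = source_image_size),
            class = "skeleton")
}

#' Query a skeleton
#'
#' \code{joint_present} tests presence; \code{joint_xy} returns the
#' coordinate pair of a present joint and errors on an absent one, so the
#' kinematics can never silently read an undefined location.
#'
#' @param sk A \code{skeleton}.
#' @param name Canonical joint name.
#' @return \code{joint_present}: logical. \code{joint_xy}: numeric
#'   \code{c(x, y)}.
#' @export
joint_present <- function(sk, name) {
  stopifnot(inherits(sk, "skeleton"))
  unname(sk$present[name])
}

#' @rdname joint_present
#' @export
joint_xy <- function(sk, name) {
  stopifnot(inherits(sk, "skeleton"))
  if (!isTRUE(unname(sk$present[name]))) {
    stop("joint '", name, "' is not present", call. = FALSE)
  }
  sk$coords[name, ]
}

#' @export
print.skeleton <- function(x, ...) {
  n <- sum(x$present)
  cat(sprintf("<skeleton> %d/%d joints present\n", n, length(REBA_JOINTS)))
  if (n < length(REBA_JOINTS)) {
    cat("  absent:", paste(names(which(!x$present)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Plot a skeleton as a stick figure
#'
#' Draws the present joints and the limb segments connecting them, in the
#' internal y-up frame. Useful for eyeballing synthetic postures.
#'
#' @param x A \code{skeleton}.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.skeleton <- function(x, ...) {
  segs <- list(
    c("mid_hip", "neck"), c("neck", "nose"),
    c("neck", "left_shoulder"), c("neck", "right_shoulder"),
    c("left_shoulder", "left_elbow"), c("left_elbow", "left_wrist"),
    c("right_shoulder", "right_elbow"), c("right_elbow", "right_wrist"),
    c("mid_hip", "left_hip"), c("mid_hip", "right_hip"),
    c("left_hip", "left_knee"), c("left_knee", "left_ankle"),
    c("right_hip", "right_knee"), c("right_knee", "right_ankle")
  )
  pts <- x$coords[x$present, , drop = FALSE]
  plot(pts[, "x"], pts[, "y"], asp = 1, pch = 19,
       xlab = "x", ylab = "y", ...)
  for (s in segs) {
    if (joint_present(x, s[1]) && joint_present(x, s[2])) {
      a <- joint_xy(x, s[1]); b <- joint_xy(x, s[2])
      graphics::segments(a["x"], a["y"], b["x"], b["y"])
    }
  }
  invisible(x)
}

#' Task context for REBA modifiers
#'
#' The force/load, coupling and activity (frequency) inputs that the REBA
#' worksheet adds on top of the posture scores. These are observational
#' inputs, each an integer from 0 (best case) to 3 (worst case).
#'
#' @param load Force/load score, 0-3.
#' @param coupling Grip/handle quality score, 0-3.
#' @param activity Task frequency/demand score, 0-3.
#' @param description Free-text task description.
#' @return An object of class \code{"task_context"}.
#' @export
#' @examples
#' task_context(load = 1, coupling = 0, activity = 1, "lift 5 kg carton")
task_context <- function(load = 0L, coupling = 0L, activity = 0L,
                         description = "") {
  for (nm in c("load", "coupling", "activity")) {
    stop_unless(is_count_0_3(get(nm)),
                sprintf("%s must be an integer in 0..3", nm))
  }
  structure(list(load = as.integer(load), coupling = as.integer(coupling),
                 activity = as.integer(activity),
                 description = as.character(description)),
            class = "task_context")
}

#' @export
print.task_context <- function(x, ...) {
  cat(sprintf("<task_context> load=%d coupling=%d activity=%d%s\n",
              x$load, x$coupling, x$activity,
              if (nzchar(x$description)) paste0(" (", x$description, ")")
              else ""))
  invisible(x)
}
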