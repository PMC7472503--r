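# Readers and writers for skeleton keypoints and assessment reports.
#
# All on-disk formats use image coordinates (origin top-left, y increasing
# downward), which is what pose estimators emit. Internally the package
# works in a y-up mathematical frame, since the vertical-reference rotation
# of the kinematics is stated geometrically; the conversion y_math = -y_image
# is applied on read and inverted on write, and is exact.

image_to_math <- function(xy) {
  xy[, "y"] <- -xy[, "y"]
  xy
}

#' Read a pose-estimator JSON file
#'
#' Parses OpenPose-style JSON (\code{people[[i]]$pose_keypoints_2d} as a flat
#' vector of \code{x, y, confidence} triples) into a \code{\link{skeleton}}.
#' Both the 18-keypoint COCO layout and the 25-keypoint body layout are
#' recognised by their length; with the COCO layout the \code{mid_hip} joint
#' is synthesised as the hip midpoint. A keypoint with confidence below
#' \code{confidence_threshold}, or at the (0, 0) sentinel with zero
#' confidence, is marked absent.
#'
#' @param path Path to the JSON file.
#' @param person_index 1-based index into the \code{people} array.
#' @param confidence_threshold Detection threshold in \[0, 1\].
#' @return A \code{\link{skeleton}} (coordinates converted to the internal
#'   y-up frame).
#' @export
read_openpose_json <- function(path, person_index = 1L,
                               confidence_threshold = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("malformed JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  people <- doc$people
  if (is.null(people) || person_index < 1L || person_index > length(people)) {
    stop("person_index ", person_index, " out of range: file has ",
         length(people), " person record(s)", call. = FALSE)
  }
  kp <- unlist(people[[person_index]]$pose_keypoints_2d, use.names = FALSE)
  if (is.null(kp) || length(kp) %% 3 != 0) {
    stop("pose_keypoints_2d is not a flat list of [x, y, c] triples",
         call. = FALSE)
  }
  n <- length(kp) / 3
  if (n == 18) {
    src_names <- REBA_JOINTS[seq_len(18)]
  } else if (n == 25) {
    src_names <- BODY25_TO_CANONICAL
    kp <- kp[seq_len(19 * 3)]
  } else {
    stop("expected 18 (COCO) or 25 (BODY_25) keypoints, found ", n,
         call. = FALSE)
  }
  m <- matrix(kp, ncol = 3, byrow = TRUE,
              dimnames = list(src_names, c("x", "y", "c")))
  present <- m[, "c"] >= confidence_threshold &
    !(m[, "x"] == 0 & m[, "y"] == 0 & m[, "c"] == 0)
  skeleton(image_to_math(m[, c("x", "y"), drop = FALSE]),
           confidence = m[, "c"],
           present = present)
}

csv_joint_columns <- function() {
  c(paste0(rep(REBA_JOINTS, each = 2), c("_x", "_y")))
}

#' Read skeletons from a CSV of named joint columns
#'
#' The CSV must have one row per frame/photo and columns
#' \code{<joint>_x}, \code{<joint>_y} (and optionally \code{<joint>_c} for
#' confidence) for each of the 19 canonical joint names, in image
#' coordinates. Empty cells mark absent joints.
#'
#' @param path Path to the CSV file.
#' @param confidence_threshold Detection threshold applied to \code{_c}
#'   columns when present.
#' @return A list of \code{\link{skeleton}} objects, one per row.
#' @export
read_skeleton_csv <- function(path, confidence_threshold = 0.1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- csv_joint_columns()
  known <- c(needed, paste0(REBA_JOINTS, "_c"))
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    stop("unknown column name(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(needed, names(df))
  # mid_hip columns may be omitted; it is synthesised from the hips
  missing <- setdiff(missing, c("mid_hip_x", "mid_hip_y"))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    have <- intersect(REBA_JOINTS,
                      unique(sub("_[xyc]$", "", names(df))))
    xy <- matrix(NA_real_, nrow = length(have), ncol = 2,
                 dimnames = list(have, c("x", "y")))
    conf <- stats::setNames(rep(1, length(have)), have)
    for (j in have) {
      xy[j, ] <- c(as.numeric(df[[paste0(j, "_x")]][i]),
                   as.numeric(df[[paste0(j, "_y")]][i]))
      cc <- paste0(j, "_c")
      if (cc %in% names(df)) conf[j] <- as.numeric(df[[cc]][i])
    }
    present <- apply(is.finite(xy), 1, all) & conf >= confidence_threshold
    xy[!present, ] <- NA_real_
    skeleton(image_to_math(xy), confidence = conf, present = present)
  })
}

#' Write skeletons to CSV
#'
#' Inverse of \code{\link{read_skeleton_csv}}: one row per skeleton, image
#' coordinates, empty cells for absent joints.
#'
#' @param skeletons A \code{skeleton} or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_skeleton_csv <- function(skeletons, path) {
  if (inherits(skeletons, "skeleton")) skeletons <- list(skeletons)
  cols <- c(rbind(paste0(REBA_JOINTS, "_x"), paste0(REBA_JOINTS, "_y"),
                  paste0(REBA_JOINTS, "_c")))
  rows <- lapply(skeletons, function(sk) {
    v <- stats::setNames(rep(NA_real_, length(cols)), cols)
    for (j in REBA_JOINTS) {
      if (joint_present(sk, j)) {
        p <- joint_xy(sk, j)
        v[paste0(j, "_x")] <- p["x"]
        v[paste0(j, "_y")] <- -p["y"]   # back to image convention
        v[paste0(j, "_c")] <- sk$confidence[j]
      }
    }
    as.data.frame(as.list(v), check.names = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

REPORT_SCHEMA_VERSION <- "1.0"

#' Write a machine-readable assessment report
#'
#' Serialises a full assessment (part scores, score A/B/C, grand score, risk
#' level and description, the ten limb angles, heuristic flags, task
#' context) to JSON with stable field names. The
#' \code{high_risk_background} flag mirrors the red/green report rule: red
#' when the risk level is 3 or more.
#'
#' @param result A \code{reba_result} from \code{\link{reba_assess}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{read_report}}
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "reba_result"))
  doc <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    part_scores = result$part_scores,
    score_a = result$score_a,
    score_b = result$score_b,
    score_c = result$score_c,
    grand_score = result$grand_score,
    risk_level = result$risk_level,
    risk_description = result$risk_description,
    high_risk_background = result$risk_level >= 3,
    angles = as.list(result$angles),
    flags = result$flags,
    context = unclass(result$context)
  )
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write report to '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", na = "null"), con)
  invisible(path)
}

#' Read an assessment report back into a result object
#'
#' @param path Path to a report written by \code{\link{write_report}}.
#' @return A \code{reba_result}.
#' @export
read_report <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  angles <- doc$angles
  angles <- stats::setNames(
    lapply(angles, function(a) if (is.null(a)) NA_real_ else as.numeric(a)),
    names(angles))
  res <- list(
    part_scores = lapply(doc$part_scores, as.integer),
    score_a = as.integer(doc$score_a),
    score_b = as.integer(doc$score_b),
    score_c = as.integer(doc$score_c),
    grand_score = as.integer(doc$grand_score),
    risk_level = as.integer(doc$risk_level),
    risk_description = doc$risk_description,
    angles = unlist(angles),
    flags = doc$flags,
    context = do.call(task_context, doc$context)
  )
  class(res) <- "reba_result"
  res
}
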