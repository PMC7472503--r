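#' Pipeline configuration
#'
#' Collects every tunable threshold of the scoring pipeline in a single
#' object. All angle thresholds are in degrees, exposure thresholds are
#' fractions in \[0, 1\].
#'
#' @param confidence_threshold Keypoints with estimator confidence below this
#'   value are treated as absent. Default 0.1.
#' @param twist_threshold Exposure ratio at or below which the trunk (chest
#'   exposure) or neck (face exposure) is flagged as twisted. Default 0.30;
#'   the comparison is inclusive, so a ratio exactly at the threshold counts
#'   as twisted.
#' @param leg_delta_threshold Difference between the two knee-flexion angles
#'   (degrees) at or beyond which support is no longer bilateral. Default 30.
#' @param kneel_threshold Knee flexion (degrees) of the more-flexed leg above
#'   which a non-bilateral stance is classified as kneeling rather than
#'   single-leg support. Default 90; the comparison is strict.
#' @param gravity_trunk_min Minimum absolute trunk flexion (degrees) for the
#'   gravity-assisted upper-arm credit. Default 45.
#' @param gravity_arm_max Maximum absolute upper-arm angle (degrees) for the
#'   gravity-assisted credit. Default 20.
#' @param shoulder_threshold Deviation (degrees) of the shoulder-neck-shoulder
#'   angle from a straight line beyond which the shoulders count as raised.
#'   Default 25.
#' @param wrist_flip_threshold Hand-exposure fraction at or below which the
#'   wrist counts as twisted. Default 0.30.
#' @param chest_width_ratio Expected shoulder-to-shoulder transverse distance
#'   as a fraction of trunk length (mid-hip to neck), used to normalise chest
#'   exposure. Default 0.75.
#' @param face_width_ratio Expected ear-to-ear transverse distance as a
#'   fraction of the neck-to-nose distance, used to normalise face exposure.
#'   Default 0.8.
#' @param neck_reference Either \code{"trunk"} (neck flexion measured against
#'   the trunk line, standard REBA practice, the default) or
#'   \code{"vertical"} (measured against the global vertical).
#' @param neck_distal Joint used as the distal end of the neck segment:
#'   \code{"nose"} (default) or \code{"ear_mid"}.
#' @param icc_model Default intraclass-correlation model:
#'   \code{"two_way_random_absolute"} (default) or
#'   \code{"two_way_mixed_consistency"}.
#' @param seed Integer seed recorded for reproducibility of stochastic steps.
#'
#' @return An object of class \code{"reba_config"}: a named list of the
#'   validated settings.
#' @export
#' @examples
#' cfg <- reba_config(twist_threshold = 0.25)
#' cfg$twist_threshold
reba_config <- function(confidence_threshold = 0.1,
                        twist_threshold = 0.30,
                        leg_delta_threshold = 30,
                        kneel_threshold = 90,
                        gravity_trunk_min = 45,
                        gravity_arm_max = 20,
                        shoulder_threshold = 25,
                        wrist_flip_threshold = 0.30,
                        chest_width_ratio = 0.75,
                        face_width_ratio = 0.8,
                        neck_reference = c("trunk", "vertical"),
                        neck_distal = c("nose", "ear_mid"),
                        icc_model = c("two_way_random_absolute",
                                      "two_way_mixed_consistency"),
                        seed = 1L) {
  neck_reference <- match.arg(neck_reference)
  neck_distal <- match.arg(neck_distal)
  icc_model <- match.arg(icc_model)
  stop_unless(is_fraction(confidence_threshold),
              "confidence_threshold must be in [0, 1]")
  stop_unless(is_fraction(twist_threshold), "twist_threshold must be in [0, 1]")
  stop_unless(is_fraction(wrist_flip_threshold),
              "wrist_flip_threshold must be in [0, 1]")
  for (nm in c("leg_delta_threshold", "kneel_threshold", "gravity_trunk_min",
               "gravity_arm_max", "shoulder_threshold")) {
    v <- get(nm)
    stop_unless(is.numeric(v) && length(v) == 1L && is.finite(v) && v >= 0 &&
                  v <= 180, sprintf("%s must be a single angle in [0, 180]", nm))
  }
  stop_unless(is.numeric(chest_width_ratio) && chest_width_ratio > 0,
              "chest_width_ratio must be positive")
  stop_unless(is.numeric(face_width_ratio) && face_width_ratio > 0,
              "face_width_ratio must be positive")
  cfg <- list(
    confidence_threshold = confidence_threshold,
    twist_threshold = twist_threshold,
    leg_delta_threshold = leg_delta_threshold,
    kneel_threshold = kneel_threshold,
    gravity_trunk_min = gravity_trunk_min,
    gravity_arm_max = gravity_arm_max,
    shoulder_threshold = shoulder_threshold,
    wrist_flip_threshold = wrist_flip_threshold,
    chest_width_ratio = chest_width_ratio,
    face_width_ratio = face_width_ratio,
    neck_reference = neck_reference,
    neck_distal = neck_distal,
    icc_model = icc_model,
    seed = as.integer(seed)
  )
  class(cfg) <- "reba_config"
  cfg
}

#' @export
print.reba_config <- function(x, ...) {
  cat("REBA pipeline configuration\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a configuration as JSON
#'
#' @param path File path.
#' @return \code{read_config} returns a \code{reba_config};
#'   \code{write_config} returns \code{path} invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(reba_config, raw)
}

#' @rdname read_config
#' @param config A \code{reba_config} object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "reba_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# internal helpers shared across modules -------------------------------------

stop_unless <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_count_0_3 <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) &&
    x >= 0 && x <= 3
}
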