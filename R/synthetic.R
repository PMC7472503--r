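# Forward-kinematic generator of synthetic 2D working postures.
#
# Each posture profile declares the ten REBA body-part angles (plus a few
# auxiliary quantities with no effect on those angles: hip flexion, facing
# direction, twist/shrug flags realised geometrically). build_skeleton()
# chains limb vectors from the mid-hip root so that compute_angles() is its
# exact inverse; perturb() adds seeded Gaussian landmark noise and random
# dropout to emulate pose-estimator error; run_benchmark() re-creates the
# posture-repeat experiment layout and emits paired truth/recovered tables
# for the agreement battery.

DEFAULT_LIMB_LENGTHS <- c(
  trunk = 120, head = 30, upper_arm = 55, forearm = 45,
  upper_leg = 75, lower_leg = 70, hip_halfwidth = 18
)

ANATOMICAL_RANGES <- list(
  trunk = c(-30, 90), neck = c(-60, 60),
  leg_left = c(0, 150), leg_right = c(0, 150),
  upper_arm_left = c(-60, 150), upper_arm_right = c(-60, 150),
  lower_arm_left = c(0, 150), lower_arm_right = c(0, 150),
  wrist_left = c(-30, 30), wrist_right = c(-30, 30)
)

#' Construct a posture specification
#'
#' @param name Posture name.
#' @param angles Named numeric vector/list of the ten target angles
#'   (degrees): \code{neck, trunk, leg_left, leg_right, upper_arm_left,
#'   upper_arm_right, lower_arm_left, lower_arm_right, wrist_left,
#'   wrist_right}.
#' @param facing \code{"left"} or \code{"right"} (image direction the
#'   worker faces).
#' @param leg_support Declared support class; must be consistent with the
#'   leg angles under the default thresholds.
#' @param twist_trunk,twist_neck Logical; realised geometrically by
#'   shrinking the shoulder/ear transverse spread below the exposure
#'   threshold.
#' @param shoulders_raised Logical shrug flag, realised by folding the
#'   neck-shoulder lines upward.
#' @param hip_flexion Named list \code{left}/\code{right} of upper-leg
#'   deviations from vertical (degrees); auxiliary, does not enter the ten
#'   target angles.
#' @param occlude Character vector of joints the benchmark drops (e.g. a
#'   carried carton hiding a wrist).
#' @return An object of class \code{"posture_spec"}.
#' @export
posture_spec <- function(name, angles, facing = c("left", "right"),
                         leg_support = c("bilateral", "unilateral",
                                         "kneeling"),
                         twist_trunk = FALSE, twist_neck = FALSE,
                         shoulders_raised = FALSE,
                         hip_flexion = list(left = 0, right = 0),
                         occlude = character()) {
  facing <- match.arg(facing)
  leg_support <- match.arg(leg_support)
  angles <- unlist(angles)
  missing <- setdiff(ANGLE_NAMES, names(angles))
  stop_unless(length(missing) == 0,
              paste("posture spec lacks angle(s):",
                    paste(missing, collapse = ", ")))
  angles <- angles[ANGLE_NAMES]
  for (nm in names(ANATOMICAL_RANGES)) {
    rng <- ANATOMICAL_RANGES[[nm]]
    if (angles[nm] < rng[1] || angles[nm] > rng[2]) {
      stop(sprintf("posture '%s': angle %s = %g outside anatomical range [%g, %g]",
                   name, nm, angles[nm], rng[1], rng[2]), call. = FALSE)
    }
  }
  implied <- classify_leg_support(angles[["leg_left"]],
                                  angles[["leg_right"]])
  if (implied != leg_support) {
    stop(sprintf("posture '%s': declared leg support '%s' inconsistent with leg angles (imply '%s')",
                 name, leg_support, implied), call. = FALSE)
  }
  bad <- setdiff(occlude, REBA_JOINTS)
  stop_unless(length(bad) == 0,
              paste("unknown joint(s) in occlude:", paste(bad, collapse = ", ")))
  structure(list(name = name, angles = angles, facing = facing,
                 leg_support = leg_support, twist_trunk = twist_trunk,
                 twist_neck = twist_neck,
                 shoulders_raised = shoulders_raised,
                 hip_flexion = hip_flexion, occlude = occlude),
            class = "posture_spec")
}

#' The twelve shipped working-posture profiles
#'
#' Parameterised reconstructions of twelve common workplace postures
#' (upright standing, forward reach, stooped lifting, overhead reach,
#' kneeling, single-leg support, trunk/neck twist, deep stoop, carrying
#' with occlusion, shrugged carry, crouch) in the style of ergonomic
#' assessment worksheets. They ship as editable JSON data
#' (\code{inst/extdata/postures.json}), not code: the profiles are
#' representative, not measured replicas.
#'
#' @param path Optional path to an alternative posture JSON file.
#' @return Named list of \code{\link{posture_spec}} objects.
#' @export
posture_specs <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "postures.json", package = "quickreba")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(seq_len(nrow(doc$postures)), function(i) {
    p <- doc$postures[i, ]
    posture_spec(
      name = p$name,
      angles = unlist(p$angles),
      facing = p$facing,
      leg_support = p$leg_support,
      twist_trunk = p$twist_trunk,
      twist_neck = p$twist_neck,
      shoulders_raised = p$shoulders_raised,
      hip_flexion = as.list(unlist(p$hip_flexion)),
      occlude = if (length(unlist(p$occlude))) unlist(p$occlude)
      else character()
    )
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Build a skeleton from a posture specification
#'
#' Forward kinematics: places the 19 joints by chaining limb vectors at the
#' specified angles from the mid-hip root. \code{\link{compute_angles}} on
#' the result returns the spec's ten target angles exactly (to floating
#' precision); twist and shrug flags are realised through the transverse
#' shoulder/ear spread and shoulder height so that the posture heuristics
#' recover them too.
#'
#' @param spec A \code{\link{posture_spec}}.
#' @param limb_lengths Named numeric vector of segment lengths in pixels
#'   (see \code{quickreba:::DEFAULT_LIMB_LENGTHS}).
#' @param root Mid-hip position, \code{c(x, y)} in the y-up frame.
#' @param config A \code{\link{reba_config}} (supplies the anthropometric
#'   width ratios used for the exposure geometry).
#' @return A \code{\link{skeleton}} with all 19 joints present.
#' @export
build_skeleton <- function(spec, limb_lengths = DEFAULT_LIMB_LENGTHS,
                           root = c(0, 0), config = reba_config()) {
  stopifnot(inherits(spec, "posture_spec"))
  L <- DEFAULT_LIMB_LENGTHS
  L[names(limb_lengths)] <- limb_lengths
  stop_unless(all(L > 0), "limb lengths must be positive")
  a <- spec$angles
  f <- if (spec$facing == "right") 1 else -1
  deg <- function(d) d * pi / 180
  J <- list()
  J$mid_hip <- c(root[1], root[2])

  u_t <- c(f * sin(deg(a[["trunk"]])), cos(deg(a[["trunk"]])))
  J$neck <- J$mid_hip + L[["trunk"]] * u_t

  d_head <- rotate2(u_t, -f * a[["neck"]])
  J$nose <- J$neck + L[["head"]] * d_head

  # face geometry: ears sit behind the nose (encoding the facing
  # direction), with a transverse spread that shrinks under neck twist
  ear_mid <- J$nose + c(-f * 0.5 * L[["head"]], 0.1 * L[["head"]])
  face_spread <- config$face_width_ratio * L[["head"]] *
    (if (spec$twist_neck) 0.2 else 1)
  J$left_ear <- ear_mid + c(face_spread / 2, 0)
  J$right_ear <- ear_mid - c(face_spread / 2, 0)
  J$left_eye <- J$nose + c(0.15 * L[["head"]], 0.25 * L[["head"]])
  J$right_eye <- J$nose + c(-0.15 * L[["head"]], 0.25 * L[["head"]])

  # shoulders: transverse spread shrinks under trunk twist; raised
  # shoulders fold the neck-shoulder lines upward
  spread <- config$chest_width_ratio * L[["trunk"]] *
    (if (spec$twist_trunk) 0.2 else 1)
  dy <- if (spec$shoulders_raised) 0.6 * spread / 2 else -0.1 * spread / 2
  J$left_shoulder <- J$neck + c(spread / 2, dy)
  J$right_shoulder <- J$neck + c(-spread / 2, dy)

  J$left_hip <- J$mid_hip + c(L[["hip_halfwidth"]], 0)
  J$right_hip <- J$mid_hip - c(L[["hip_halfwidth"]], 0)

  for (side in c("left", "right")) {
    ua <- a[[paste0("upper_arm_", side)]]
    la <- a[[paste0("lower_arm_", side)]]
    d_ua <- c(f * sin(deg(ua)), -cos(deg(ua)))
    J[[paste0(side, "_elbow")]] <-
      J[[paste0(side, "_shoulder")]] + L[["upper_arm"]] * d_ua
    d_fa <- rotate2(d_ua, f * la)
    J[[paste0(side, "_wrist")]] <-
      J[[paste0(side, "_elbow")]] + L[["forearm"]] * d_fa

    hf <- spec$hip_flexion[[side]]
    kf <- a[[paste0("leg_", side)]]
    d_ul <- c(f * sin(deg(hf)), -cos(deg(hf)))
    J[[paste0(side, "_knee")]] <-
      J[[paste0(side, "_hip")]] + L[["upper_leg"]] * d_ul
    d_ll <- rotate2(d_ul, -f * kf)
    J[[paste0(side, "_ankle")]] <-
      J[[paste0(side, "_knee")]] + L[["lower_leg"]] * d_ll
  }

  xy <- do.call(rbind, J[REBA_JOINTS])
  colnames(xy) <- c("x", "y")
  skeleton(xy)
}

#' Landmark noise model
#'
#' Isotropic Gaussian displacement per landmark plus independent dropout,
#' emulating pose-estimator error. Fully determined by the seed.
#'
#' @param sigma Standard deviation of the per-landmark displacement,
#'   pixels.
#' @param dropout_probability Probability that a present joint is dropped.
#' @param seed Integer RNG seed.
#' @return An object of class \code{"noise_model"}.
#' @export
noise_model <- function(sigma = 0, dropout_probability = 0, seed = 1L) {
  stop_unless(is.numeric(sigma) && sigma >= 0, "sigma must be >= 0")
  stop_unless(is.numeric(dropout_probability) && dropout_probability >= 0 &&
                dropout_probability < 1, "dropout must be in [0, 1)")
  structure(list(sigma = sigma,
                 dropout_probability = dropout_probability,
                 seed = as.integer(seed)),
            class = "noise_model")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Perturb a skeleton with landmark noise
#'
#' Adds a seeded Gaussian displacement to every present joint and drops
#' joints independently with the model's dropout probability. Identical
#' inputs and seed give identical output.
#'
#' @param sk A \code{\link{skeleton}}.
#' @param noise A \code{\link{noise_model}}.
#' @return A perturbed \code{\link{skeleton}}.
#' @export
perturb <- function(sk, noise = noise_model()) {
  stopifnot(inherits(sk, "skeleton"), inherits(noise, "noise_model"))
  with_seed(noise$seed, {
    coords <- sk$coords
    pres <- sk$present
    idx <- which(pres)
    if (noise$sigma > 0) {
      coords[idx, ] <- coords[idx, ] +
        matrix(stats::rnorm(2 * length(idx), 0, noise$sigma),
               ncol = 2)
    }
    if (noise$dropout_probability > 0) {
      drop <- stats::runif(length(idx)) < noise$dropout_probability
      pres[idx[drop]] <- FALSE
    }
    coords[!pres, ] <- NA_real_
    skeleton(coords[pres, , drop = FALSE],
             confidence = sk$confidence[pres],
             present = stats::setNames(rep(TRUE, sum(pres)),
                                       names(which(pres))))
  })
}

occlude_joints <- function(sk, joints) {
  if (!length(joints)) return(sk)
  pres <- sk$present
  pres[joints] <- FALSE
  skeleton(sk$coords[pres, , drop = FALSE],
           confidence = sk$confidence[pres],
           present = stats::setNames(rep(TRUE, sum(pres)),
                                     names(which(pres))))
}

#' Run the synthetic posture benchmark
#'
#' Re-creates the posture-by-repeat experiment layout: for every posture
#' and repeat, the profile skeleton is perturbed with landmark noise (and
#' any profile-declared occlusion applied), then assessed end to end. The
#' truth columns come from the unperturbed skeleton through the same
#' pipeline, so at zero noise truth and recovery coincide exactly.
#'
#' @param specs List of \code{\link{posture_spec}}; default the 12 shipped
#'   profiles.
#' @param repeats Number of repeats per posture.
#' @param noise A \code{\link{noise_model}}; per-replicate seeds are
#'   derived deterministically from its seed.
#' @param context A \code{\link{task_context}} applied to every
#'   assessment.
#' @param config A \code{\link{reba_config}}.
#' @return An object of class \code{"reba_benchmark"}: a list with
#'   \code{angles} (long data frame: posture, repeat, part, truth,
#'   measured), \code{scores} (per assessment: truth and measured grand
#'   score, score A/B, risk level) and the inputs.
#' @export
run_benchmark <- function(specs = posture_specs(), repeats = 4L,
                          noise = noise_model(), context = task_context(),
                          config = reba_config()) {
  stop_unless(repeats >= 1, "repeats must be >= 1")
  angle_rows <- list()
  score_rows <- list()
  for (si in seq_along(specs)) {
    spec <- specs[[si]]
    truth_sk <- build_skeleton(spec, config = config)
    truth_sk <- occlude_joints(truth_sk, spec$occlude)
    truth_ang <- compute_angles(truth_sk, config)
    truth_res <- reba_assess(truth_sk, context, config)
    for (r in seq_len(repeats)) {
      seed_r <- noise$seed + 1009L * si + r
      nm <- noise_model(noise$sigma, noise$dropout_probability, seed_r)
      sk <- perturb(build_skeleton(spec, config = config), nm)
      sk <- occlude_joints(sk, spec$occlude)
      ang <- compute_angles(sk, config)
      res <- tryCatch(reba_assess(sk, context, config),
                      error = function(e) NULL)
      angle_rows[[length(angle_rows) + 1L]] <- data.frame(
        posture = spec$name, rep = r, part = ANGLE_NAMES,
        truth = as.numeric(truth_ang[ANGLE_NAMES]),
        measured = as.numeric(ang[ANGLE_NAMES]),
        stringsAsFactors = FALSE)
      score_rows[[length(score_rows) + 1L]] <- data.frame(
        posture = spec$name, rep = r,
        grand_truth = truth_res$grand_score,
        grand = if (is.null(res)) NA_integer_ else res$grand_score,
        score_a_truth = truth_res$score_a,
        score_a = if (is.null(res)) NA_integer_ else res$score_a,
        score_b_truth = truth_res$score_b,
        score_b = if (is.null(res)) NA_integer_ else res$score_b,
        level_truth = truth_res$risk_level,
        level = if (is.null(res)) NA_integer_ else res$risk_level,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(angles = do.call(rbind, angle_rows),
                 scores = do.call(rbind, score_rows),
                 repeats = repeats, noise = noise, context = context),
            class = "reba_benchmark")
}

#' @export
print.reba_benchmark <- function(x, ...) {
  cat(sprintf(
    "<reba_benchmark> %d postures x %d repeats (sigma = %g px, dropout = %g)\n",
    length(unique(x$angles$posture)), x$repeats, x$noise$sigma,
    x$noise$dropout_probability))
  invisible(x)
}

#' Agreement summary of a benchmark run
#'
#' Reshapes the benchmark's paired angle and score tables and feeds them to
#' \code{\link{agreement_report}}.
#'
#' @param bench A \code{\link{run_benchmark}} result.
#' @param what \code{"angles"} or \code{"scores"}.
#' @param ... Passed to \code{\link{agreement_report}}.
#' @return An \code{agreement_report}.
#' @export
benchmark_agreement <- function(bench, what = c("angles", "scores"), ...) {
  what <- match.arg(what)
  stopifnot(inherits(bench, "reba_benchmark"))
  if (what == "angles") {
    long <- bench$angles
    ref <- stats::reshape(long[, c("posture", "rep", "part", "truth")],
                          idvar = c("posture", "rep"), timevar = "part",
                          direction = "wide")
    tst <- stats::reshape(long[, c("posture", "rep", "part", "measured")],
                          idvar = c("posture", "rep"), timevar = "part",
                          direction = "wide")
    names(ref) <- sub("^truth\\.", "", names(ref))
    names(tst) <- sub("^measured\\.", "", names(tst))
    agreement_report(ref[ANGLE_NAMES], tst[ANGLE_NAMES], ...)
  } else {
    sc <- bench$scores
    agreement_report(
      data.frame(grand = sc$grand_truth, score_a = sc$score_a_truth,
                 score_b = sc$score_b_truth, level = sc$level_truth),
      data.frame(grand = sc$grand, score_a = sc$score_a,
                 score_b = sc$score_b, level = sc$level), ...)
  }
}
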