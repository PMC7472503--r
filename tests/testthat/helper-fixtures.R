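# Fixture builders: small pose-estimator files written at test time.

# OpenPose-style JSON with one person; joints is a named list of
# c(x, y, confidence) in image coordinates, COCO-18 order, defaults from a
# plausible frontal standing figure.
coco18_order <- REBA_JOINTS[1:18]

standing_keypoints <- function() {
  sk <- build_skeleton(posture_specs()[["upright_standing"]])
  kp <- list()
  for (j in coco18_order) {
    p <- joint_xy(sk, j)
    kp[[j]] <- c(p[["x"]], -p[["y"]], 0.9)   # back to image y-down
  }
  kp
}

write_openpose_json <- function(path, keypoints = standing_keypoints(),
                                n_people = 1) {
  flat <- unlist(keypoints, use.names = FALSE)
  people <- rep(list(list(pose_keypoints_2d = as.list(flat))), n_people)
  jsonlite::write_json(list(version = 1.3, people = people), path,
                       auto_unbox = TRUE, digits = NA)
  path
}
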