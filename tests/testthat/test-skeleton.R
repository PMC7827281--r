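test_that("joint model has exactly the 25 named joints", {
  j <- kinect_joints()
  expect_length(j, 25)
  expect_false(anyDuplicated(j) > 0)
  expect_true(all(c("SPINE_MID", "SPINE_BASE", "SPINE_SHOULDER",
                    "SHOULDER_LEFT", "SHOULDER_RIGHT",
                    "HAND_LEFT", "HAND_RIGHT") %in% j))
})

test_that("segment returns displacement and Euclidean length", {
  pose <- standing_pose(test_body)
  pose["ELBOW_RIGHT", ] <- c(0, 0, 2)
  pose["WRIST_RIGHT", ] <- c(0.3, 0.4, 2)
  fs <- pose_stream(pose)
  # coincident joints: zero vector, zero length
  pose2 <- pose
  pose2["WRIST_RIGHT", ] <- pose2["ELBOW_RIGHT", ]
  s0 <- segment(pose_stream(pose2), "ELBOW_RIGHT", "WRIST_RIGHT")
  expect_equal(unlist(s0[, c("dx", "dy", "dz", "length")]),
               c(dx = 0, dy = 0, dz = 0, length = 0))
  # 3-4-5 triangle
  expect_equal(segment(fs, "ELBOW_RIGHT", "WRIST_RIGHT")$length, 0.5)
  expect_error(segment(fs, "ELBOW_RIGHT", "ELBOW_RIGHT"),
               class = "exertrack_input_error")
  expect_error(segment(fs, "ELBOW_RIGHT", "FUNNY_BONE"),
               class = "exertrack_input_error")
})

test_that("segment length matches an element-wise norm oracle", {
  set.seed(11)
  for (i in 1:20) {
    pose <- standing_pose(test_body)
    pose[, ] <- pose + matrix(rnorm(75, sd = 0.3), 25, 3)
    a <- sample(kinect_joints(), 1)
    b <- sample(setdiff(kinect_joints(), a), 1)
    got <- segment(pose_stream(pose), a, b)$length
    oracle <- sqrt(sum((pose[b, ] - pose[a, ])^2))
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("joint_angle reproduces canonical poses", {
  pose <- standing_pose(test_body)
  # upright: hip, knee, ankle collinear
  expect_equal(joint_angle(pose_stream(pose), "HIP_RIGHT", "KNEE_RIGHT",
                           "ANKLE_RIGHT"), 180)
  # thigh horizontal, shank vertical: full squat depth
  pose90 <- pose
  pose90["KNEE_RIGHT", ] <- c(-0.1, 0.45, 2)
  pose90["ANKLE_RIGHT", ] <- c(-0.1, 0.05, 2)        # straight down
  pose90["HIP_RIGHT", ] <- c(-0.1, 0.45, 2.4)        # horizontal
  expect_equal(joint_angle(pose_stream(pose90), "HIP_RIGHT", "KNEE_RIGHT",
                           "ANKLE_RIGHT"), 90)
  # 45 degrees by construction
  pose45 <- pose
  pose45["KNEE_RIGHT", ] <- c(0, 0, 2)
  pose45["HIP_RIGHT", ] <- c(1, 0, 2)
  pose45["ANKLE_RIGHT", ] <- c(1, 1, 2)
  expect_equal(joint_angle(pose_stream(pose45), "HIP_RIGHT", "KNEE_RIGHT",
                           "ANKLE_RIGHT"), 45)
  # degenerate: vertex coincides with an endpoint
  posez <- pose
  posez["ANKLE_RIGHT", ] <- posez["KNEE_RIGHT", ]
  expect_error(joint_angle(pose_stream(posez), "HIP_RIGHT", "KNEE_RIGHT",
                           "ANKLE_RIGHT"),
               class = "exertrack_degenerate_pose_error")
})

test_that("joint_angle is symmetric and rigid-motion invariant", {
  set.seed(21)
  for (i in 1:10) {
    pose <- standing_pose(test_body)
    pose[, ] <- pose + matrix(rnorm(75, sd = 0.2), 25, 3)
    fs <- pose_stream(pose)
    a1 <- joint_angle(fs, "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT")
    expect_equal(joint_angle(fs, "ANKLE_LEFT", "KNEE_LEFT", "HIP_LEFT"), a1)
    moved <- transform_stream(fs, random_rotation(), rnorm(3))
    expect_equal(joint_angle(moved, "HIP_LEFT", "KNEE_LEFT", "ANKLE_LEFT"),
                 a1, tolerance = 1e-9)
  }
})

test_that("segment length is translation invariant and scales linearly", {
  set.seed(31)
  pose <- standing_pose(test_body)
  fs <- pose_stream(pose)
  len <- segment(fs, "SHOULDER_LEFT", "ELBOW_LEFT")$length
  shifted <- transform_stream(fs, diag(3), rnorm(3))
  expect_equal(segment(shifted, "SHOULDER_LEFT", "ELBOW_LEFT")$length, len)
  scaled <- fs
  scaled$x <- 2.5 * scaled$x
  scaled$y <- 2.5 * scaled$y
  scaled$z <- 2.5 * scaled$z
  scaled <- frame_stream(scaled)
  expect_equal(segment(scaled, "SHOULDER_LEFT", "ELBOW_LEFT")$length,
               2.5 * len)
})

test_that("torso_tilt measures the spine's angle to the vertical", {
  pose <- standing_pose(test_body)
  expect_equal(torso_tilt(pose_stream(pose)), 0)
  pose45 <- pose
  pose45["SPINE_SHOULDER", ] <- pose45["SPINE_BASE", ] + c(0.5, 0.5, 0)
  expect_equal(torso_tilt(pose_stream(pose45)), 45)
  # dot-product oracle on random spine vectors
  set.seed(41)
  for (i in 1:20) {
    v <- rnorm(3)
    posev <- pose
    posev["SPINE_SHOULDER", ] <- posev["SPINE_BASE", ] + v
    oracle <- acos(v[2] / sqrt(sum(v^2))) * 180 / pi
    expect_equal(torso_tilt(pose_stream(posev)), oracle, tolerance = 1e-9)
  }
  posez <- pose
  posez["SPINE_SHOULDER", ] <- posez["SPINE_BASE", ]
  expect_error(torso_tilt(pose_stream(posez)),
               class = "exertrack_degenerate_pose_error")
})

test_that("tilting an upright pose by theta yields torso_tilt theta", {
  pose <- standing_pose(test_body)
  for (theta in c(0.5, 5, 20, 45, 77.3, 90)) {
    a <- theta * pi / 180
    rot <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    tilted <- transform_stream(pose_stream(pose), rot)
    expect_equal(torso_tilt(tilted), theta, tolerance = 1e-9)
  }
})

test_that("frames are flagged when any joint depth leaves the working range", {
  pose <- standing_pose(test_body, distance = 2)
  expect_false(flag_out_of_range(pose_stream(pose))$out_of_range)
  near <- pose; near[, "z"] <- 0.39
  expect_true(flag_out_of_range(pose_stream(near))$out_of_range)
  far <- pose; far[, "z"] <- 4.51
  expect_true(flag_out_of_range(pose_stream(far))$out_of_range)
  edge <- pose; edge[, "z"] <- 4.5
  expect_false(flag_out_of_range(pose_stream(edge))$out_of_range)
  one <- pose; one["HAND_LEFT", "z"] <- 5
  expect_true(flag_out_of_range(pose_stream(one))$out_of_range)
})

test_that("frame_stream enforces its invariants", {
  pose <- standing_pose(test_body)
  df <- pose_to_frame(pose, 0)
  expect_error(frame_stream(df[-1, ]), class = "exertrack_format_error")
  df2 <- dplyr::bind_rows(pose_to_frame(pose, 0.1), pose_to_frame(pose, 0))
  expect_error(frame_stream(df2), class = "exertrack_format_error")
  expect_error(frame_stream(df, nominal_rate = 0),
               class = "exertrack_input_error")
})
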