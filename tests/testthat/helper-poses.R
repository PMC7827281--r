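# Fixtures built in code: poses, rotations, and a calibrated profile reused
# across tests.

test_body <- body_model(1.70)

# one-frame stream from a pose matrix
pose_stream <- function(pose, time = 0, rate = 30) {
  frame_stream(pose_to_frame(pose, time), nominal_rate = rate)
}

# stream of n identical frames
repeat_pose <- function(pose, n = 45, rate = 30) {
  frame_stream(
    dplyr::bind_rows(lapply(seq_len(n) - 1,
                            function(i) pose_to_frame(pose, i / rate))),
    nominal_rate = rate
  )
}

# random rotation matrix (uniform axis, uniform angle)
random_rotation <- function() {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

transform_stream <- function(stream, rot = diag(3), shift = c(0, 0, 0)) {
  m <- as.matrix(stream[, c("x", "y", "z")]) %*% t(rot)
  out <- stream
  out$x <- m[, 1] + shift[1]
  out$y <- m[, 2] + shift[2]
  out$z <- m[, 3] + shift[3]
  frame_stream(out, nominal_rate = nominal_rate(stream))
}

mirror_stream <- function(stream) {
  out <- stream
  out$x <- -out$x
  frame_stream(out, nominal_rate = nominal_rate(stream))
}

calibration_profile <- function(body = test_body, side = "right") {
  calibrate(simulate_static(body, duration_s = 1.5), side = side)
}

catalog_entry <- function(movement_, side_ = NULL) {
  cat <- default_catalog()
  rows <- cat[cat$movement == movement_, ]
  if (!is.null(side_)) rows <- rows[rows$side == side_, ]
  rows[1, ]
}
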