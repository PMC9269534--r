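# Shared fixtures, built in code. Sessions are cached per test run so the
# expensive simulations happen once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# a short noiseless static session
static_session <- function(duration = 1, rate = 60, mounts = default_mounts()) {
  simulate_session(protocol = NULL, t_cal = duration, rate = rate,
                   noise = noise_model("none"), mounts = mounts)
}

# the full standard protocol, noiseless, computed once
standard_noiseless <- function() {
  cached("standard_noiseless", simulate_session(noise = noise_model("none")))
}

# the full standard protocol under the default noise model, seeded
standard_noisy <- function(seed = 7) {
  cached(paste0("standard_noisy_", seed),
         simulate_session(noise = noise_model("default"), seed = seed))
}

random_rotation <- function() {
  v <- stats::rnorm(3)
  quat_to_matrix(quat_from_rotvec(v / sqrt(sum(v^2)) * stats::runif(1, 0, 179)))
}

angle_between <- function(R1, R2 = diag(3)) {
  sqrt(sum(quat_to_rotvec(matrix_to_quat(t(R2) %*% R1))^2))
}

quat_angle <- function(q1, q2 = quat(1, 0, 0, 0)) {
  sqrt(sum(quat_to_rotvec(quat_multiply(quat_conjugate(quat(q2)),
                                        quat(q1)))^2))
}

track_error_deg <- function(track, quat_truth) {
  vapply(seq_len(nrow(track)), function(i) {
    quat_angle(as.numeric(track[i, c("qw", "qx", "qy", "qz")]),
               quat_truth[i, ])
  }, numeric(1))
}
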