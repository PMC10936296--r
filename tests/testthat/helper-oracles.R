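# Independent oracles used across the tests.  Deliberately written from
# first principles (plain vector arithmetic, enumeration) so they do not
# share code paths with the package implementation.

norm2 <- function(v) sqrt(sum(v * v))

unit_oracle <- function(from, to) {
  d <- c(to[1] - from[1], to[2] - from[2])
  d / norm2(d)
}

# perpendicular distance from point q to the line through a with direction d
line_dist_oracle <- function(q, a, d) {
  r <- c(q[1] - a[1], q[2] - a[2])
  abs(r[1] * d[2] - r[2] * d[1]) / norm2(d)
}

# brute-force total torque of all device-on-trunk forces about p0:
# the shoulder anchor carries T toward the pulley; the pulley (rigid arm,
# part of the trunk body) carries the two strap-leg pulls T*u(p2->p1) and
# T*u(p2->p3).
brute_torque_oracle <- function(p0, p1, p2, p3, tension) {
  crossz <- function(r, f) r[1] * f[2] - r[2] * f[1]
  f_shoulder <- tension * unit_oracle(p1, p2)
  f_pulley <- tension * (unit_oracle(p2, p1) + unit_oracle(p2, p3))
  crossz(p1 - p0, f_shoulder) + crossz(p2 - p0, f_pulley)
}

# random valid geometry with all routing points well separated
rand_geom <- function() {
  repeat {
    pts <- matrix(stats::runif(8, -0.5, 0.5), 4, 2)
    if (min(stats::dist(pts)) > 0.02) break
  }
  exo_geometry(p0 = pts[1, ], p1 = pts[2, ], p2 = pts[3, ], p3 = pts[4, ])
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
# (valid for tie-free pooled samples)
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_stat <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_stat(a, b)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) u_stat(pooled[i], pooled[-i]))
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# small, fast study configuration for pipeline tests
tiny_config <- function(seed = 11, ...) {
  study_config(n_participants = 3, repetitions = 2, n_cocontractors = 1,
               lift_s = 1, hold_s = 1, lower_s = 1, mvic_s = 2, rest_s = 2,
               seed = seed, ...)
}
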