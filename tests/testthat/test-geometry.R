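# Static human-exosuit model: forces, torques, effective moment arm, K.

p1_ref <- c(0.38, 0.08)
p3_ref <- c(-0.15, 0.05)
geom_ref <- exo_geometry(p2 = c(0, 0.20))

test_that("unit_vector matches direct vector arithmetic and rejects zero length", {
  expect_equal(unit_vector(c(0, 0), c(0, 3)), c(0, 1))
  expect_error(unit_vector(c(0, 0), c(0, 0)), class = "exo_degenerate_error")
  u <- unit_vector(p1_ref, c(0, 0.20))
  expect_equal(u, unit_oracle(p1_ref, c(0, 0.20)), tolerance = 1e-15)
  expect_equal(u, c(-0.9536, 0.3011), tolerance = 1e-4)
  expect_equal(norm2(u), 1, tolerance = 1e-15)
})

test_that("device-to-body forces have the defined directions and magnitudes", {
  expect_equal(shoulder_force(geom_ref, 0), c(0, 0))
  fs <- shoulder_force(geom_ref, 100)
  expect_equal(fs, c(-95.36, 30.11), tolerance = 1e-3)
  expect_equal(norm2(fs), 100, tolerance = 1e-12)

  fw <- waist_force(geom_ref, 100)
  fw_oracle <- 100 * (unit_oracle(c(0, 0.20), p3_ref) - unit_oracle(p1_ref, c(0, 0.20)))
  expect_equal(fw, fw_oracle, tolerance = 1e-12)
  expect_equal(fw, c(24.65, -100.82), tolerance = 1e-2)
  expect_equal(norm2(fw), 103.79, tolerance = 1e-2)
  expect_equal(waist_force(geom_ref, 200), 2 * fw, tolerance = 1e-12)

  # straight strap: pulley on the interior of p1 -> p3 transmits no net load
  mid <- (p1_ref + p3_ref) / 2
  expect_equal(waist_force(exo_geometry(p2 = mid), 100), c(0, 0), tolerance = 1e-10)

  ft <- thigh_force(exo_geometry(p2 = c(0, 0.2), p4 = c(-0.45, 0.02)), 100)
  expect_equal(ft, 100 * unit_oracle(c(-0.45, 0.02), p3_ref), tolerance = 1e-12)
  expect_equal(ft, c(99.50, 9.95), tolerance = 1e-2)
  expect_equal(norm2(ft), 100, tolerance = 1e-12)
})

test_that("torque components sum to the brute-force device-on-trunk torque", {
  expect_equal(torque_components(geom_ref, 0), c(tau_t1 = 0, tau_ma = 0))
  tc <- torque_components(geom_ref, 100)
  expect_equal(sum(tc),
               brute_torque_oracle(c(0, 0), p1_ref, c(0, 0.20), p3_ref, 100),
               tolerance = 1e-12)
  expect_equal(sum(tc), 14.14, tolerance = 1e-2)
  expect_equal(assistive_torque(geom_ref, 100), sum(tc), tolerance = 1e-12)

  # straight-strap limit: no pulley torque, shoulder strap alone
  mid <- (p1_ref + p3_ref) / 2
  g_mid <- exo_geometry(p2 = mid)
  tc_mid <- torque_components(g_mid, 100)
  expect_equal(tc_mid[["tau_ma"]], 0, tolerance = 1e-9)
  d13 <- line_dist_oracle(c(0, 0), p1_ref, p3_ref - p1_ref)
  expect_equal(abs(tc_mid[["tau_t1"]]), 100 * d13, tolerance = 1e-9)
  expect_equal(abs(assistive_torque(g_mid, 100)), 100 * 0.0584, tolerance = 1e-3)
})

test_that("effective moment arm is the point-to-line distance, tension-free", {
  r <- effective_moment_arm(geom_ref)
  expect_equal(r, line_dist_oracle(c(0, 0), c(0, 0.20), p3_ref - c(0, 0.20)),
               tolerance = 1e-15)
  expect_equal(r, 0.1414, tolerance = 1e-3)
  expect_equal(abs(assistive_torque(geom_ref, 1)) / 1, r, tolerance = 1e-12)
  expect_equal(abs(assistive_torque(geom_ref, 1000)) / 1000, r, tolerance = 1e-12)
  # pulley on the strap line: recover the no-arm moment arm
  mid <- (p1_ref + p3_ref) / 2
  expect_equal(effective_moment_arm(exo_geometry(p2 = mid)), 0.0584,
               tolerance = 1e-3)
})

test_that("force ratio K spans its geometric bounds", {
  mid <- (p1_ref + p3_ref) / 2
  expect_equal(force_ratio_k(exo_geometry(p2 = mid)), 0, tolerance = 1e-10)
  folded <- exo_geometry(p2 = c(0, 0), p1 = c(0, 1), p3 = c(0, 2))
  expect_equal(force_ratio_k(folded), 2, tolerance = 1e-12)
  expect_equal(force_ratio_k(geom_ref), 1.0379, tolerance = 1e-4)
})

test_that("cancellation, oracle equivalence, bounds and symmetry hold on random geometries", {
  set.seed(4211)
  for (i in 1:500) {
    g <- rand_geom()
    tension <- stats::runif(1, 1, 500)
    tau <- assistive_torque(g, tension)
    # cancellation of the shoulder-strap internal torque
    expect_equal(tau, sum(torque_components(g, tension)),
                 tolerance = 1e-12 * max(1, abs(tau)))
    # |tau| = T * distance from p0 to the distal strap line
    d <- line_dist_oracle(g$p0, g$p2, g$p3 - g$p2)
    expect_equal(abs(tau), tension * d, tolerance = 1e-12 * max(1, abs(tau)))
    k <- force_ratio_k(g)
    expect_gte(k, 0); expect_lte(k, 2)
    # degree-1 homogeneity in tension
    expect_equal(assistive_torque(g, 2 * tension), 2 * tau, tolerance = 1e-12)
    expect_equal(waist_force(g, 2 * tension), 2 * waist_force(g, tension),
                 tolerance = 1e-12)
    # mirror about the cranial axis: tau flips sign, r_eff and K invariant
    m <- function(p) c(p[1], -p[2])
    gm <- exo_geometry(p0 = m(g$p0), p1 = m(g$p1), p2 = m(g$p2), p3 = m(g$p3))
    expect_equal(assistive_torque(gm, tension), -tau, tolerance = 1e-10)
    expect_equal(effective_moment_arm(gm), effective_moment_arm(g), tolerance = 1e-12)
    expect_equal(force_ratio_k(gm), k, tolerance = 1e-12)
  }
})

test_that("limit recovery: pulley approaching the strap line", {
  d13 <- line_dist_oracle(c(0, 0), p1_ref, p3_ref - p1_ref)
  for (t in c(0.25, 0.5, 0.75)) {
    on_line <- p1_ref + t * (p3_ref - p1_ref)
    for (eps in c(1e-3, 1e-5)) {
      g <- exo_geometry(p2 = on_line + c(0, eps))
      expect_lt(force_ratio_k(g), 0.05)
      # deviation from the no-arm moment arm shrinks linearly with eps
      expect_lt(abs(effective_moment_arm(g) - d13), 30 * eps)
    }
  }
})

test_that("geometry configs round-trip losslessly through yaml and json", {
  g <- exo_geometry(p2 = c(pi / 30, exp(-1) / 2))
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_geometry(g, path, stiffness = 700)
    back <- read_geometry(path)
    expect_identical(back$geometry$p2, g$p2)
    expect_identical(back$geometry$p1, g$p1)
    expect_equal(back$stiffness, 700)
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(p1 = c(0, 1)), bad)
  expect_error(read_geometry(bad), "missing fields")
})

test_that("degenerate and invalid inputs raise explicit errors", {
  expect_error(exo_geometry(p2 = p1_ref), class = "exo_degenerate_error")
  expect_error(exo_geometry(p2 = p3_ref), class = "exo_degenerate_error")
  expect_error(shoulder_force(geom_ref, -1), "non-negative")
  expect_error(strap_state(stiffness = -5, stretch = 0.1), "positive")
  expect_equal(strap_state(700, 0.1)$tension, 70)
})
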