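# Sagittal-plane static model of a routed-strap back-assist exosuit.
#
# Coordinate convention: x is cranial-positive, y is posterior-positive,
# origin at the L5-S1 joint (p0).  All lengths in metres, forces in newtons,
# torques in newton-metres.  2D torques are signed scalars (out-of-plane,
# counterclockwise positive); the reported effective moment arm uses |tau|.

#' Signed 2D cross product
#'
#' Out-of-plane component of the cross product of two sagittal-plane vectors,
#' `r.x * f.y - r.y * f.x`.  Counterclockwise positive with x cranial and
#' y posterior.
#'
#' @param r,f numeric length-2 vectors.
#' @return Scalar signed magnitude.
#' @export
cross2 <- function(r, f) r[1L] * f[2L] - r[2L] * f[1L]

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("exo_degenerate_error", "error", "condition")))
}

as_point2d <- function(p, name = deparse(substitute(p))) {
  p <- as.numeric(p)
  if (length(p) != 2L || !all(is.finite(p))) {
    stop(sprintf("'%s' must be a finite numeric (x, y) pair", name))
  }
  p
}

#' Unit vector between two points
#'
#' @param p_from,p_to numeric (x, y) points in metres.
#' @return Unit-norm numeric vector pointing from `p_from` to `p_to`.
#'   Coincident points raise a degenerate-geometry error rather than
#'   returning NaN.
#' @export
unit_vector <- function(p_from, p_to) {
  p_from <- as_point2d(p_from)
  p_to <- as_point2d(p_to)
  d <- p_to - p_from
  n <- sqrt(sum(d * d))
  if (n == 0) stop_degenerate("unit_vector: coincident points give a zero-length direction")
  d / n
}

#' Exosuit strap/anchor geometry in the sagittal plane
#'
#' Bundles the model's anchor points: `p0` the L5-S1 torque reference
#' (origin by default), `p1` the shoulder anchor, `p2` the moment-arm pulley,
#' `p3` the buttocks contact point where the strap leaves the body, and `p4`
#' the thigh anchor.  The strap junction between elastic and inelastic
#' segments is collapsed into `p3`: with frictionless routing and a single
#' tension, the distal strap acts along the straight segment `p2 -> p3`.
#'
#' Defaults for `p1` and `p3` are the reference male anthropometry used for
#' the model exploration; `p4` is a nominal mid-thigh anchor.
#'
#' @param p2 pulley location (x, y) in metres.
#' @param p1 shoulder anchor, default `c(0.38, 0.08)`.
#' @param p3 buttocks contact point, default `c(-0.15, 0.05)`.
#' @param p0 torque reference (L5-S1), default origin.
#' @param p4 thigh anchor, default `c(-0.45, 0.02)`.
#' @return An object of class `exo_geometry`.
#' @examples
#' g <- exo_geometry(p2 = c(0, 0.20))
#' effective_moment_arm(g)
#' force_ratio_k(g)
#' @export
exo_geometry <- function(p2, p1 = c(0.38, 0.08), p3 = c(-0.15, 0.05),
                         p0 = c(0, 0), p4 = c(-0.45, 0.02)) {
  g <- list(p0 = as_point2d(p0), p1 = as_point2d(p1), p2 = as_point2d(p2),
            p3 = as_point2d(p3), p4 = as_point2d(p4))
  if (identical(g$p1, g$p2)) stop_degenerate("exo_geometry: p1 and p2 coincide")
  if (identical(g$p2, g$p3)) stop_degenerate("exo_geometry: p2 and p3 coincide")
  structure(g, class = "exo_geometry")
}

#' @export
print.exo_geometry <- function(x, ...) {
  cat("<exo_geometry> (m, x cranial+, y posterior+)\n")
  for (nm in c("p0", "p1", "p2", "p3", "p4")) {
    cat(sprintf("  %s: (%.4f, %.4f)\n", nm, x[[nm]][1L], x[[nm]][2L]))
  }
  cat(sprintf("  r_eff = %.4f m, K = %.4f\n",
              effective_moment_arm(x), force_ratio_k(x)))
  invisible(x)
}

check_tension <- function(tension) {
  if (!is.numeric(tension) || length(tension) != 1L || !is.finite(tension) || tension < 0) {
    stop("'tension' must be a single finite non-negative value in newtons")
  }
  tension
}

#' Elastic strap state
#'
#' Frictionless routing implies a single tension throughout the elastic and
#' inelastic strap segments: `tension = stiffness * stretch`.
#'
#' @param stiffness strap stiffness in N/m (the emulator's strap is 700 N/m).
#' @param stretch strap elongation in metres (non-negative).
#' @return List of class `strap_state` with `stiffness`, `stretch`, `tension`.
#' @export
strap_state <- function(stiffness = 700, stretch = 0) {
  if (stiffness <= 0) stop("'stiffness' must be positive (N/m)")
  if (stretch < 0) stop("'stretch' must be non-negative (m)")
  structure(list(stiffness = stiffness, stretch = stretch,
                 tension = stiffness * stretch),
            class = "strap_state")
}

#' Device-to-body force at the shoulder
#'
#' The inelastic strap pulls the shoulder anchor toward the pulley with the
#' strap tension: `F_S = T * unit(p1 -> p2)`, so `|F_S| = T` exactly.
#'
#' @param geom an [exo_geometry()].
#' @param tension strap tension in newtons (non-negative).
#' @return Numeric (x, y) force vector in newtons.
#' @export
shoulder_force <- function(geom, tension) {
  check_tension(tension)
  tension * unit_vector(geom$p1, geom$p2)
}

#' Device-to-body force at the waist
#'
#' Net load the strap transmits through the frictionless pulley and rigid
#' moment arm into the waist: the two strap legs pull the pulley toward `p1`
#' and `p3`, giving `F_W = T * (unit(p2 -> p3) - unit(p1 -> p2))`.  Its
#' magnitude is `K * T` with `K = force_ratio_k(geom)`.
#'
#' @inheritParams shoulder_force
#' @return Numeric (x, y) force vector in newtons.  A pulley on the interior
#'   of segment `p1 -> p3` (straight strap) gives the zero vector.
#' @export
waist_force <- function(geom, tension) {
  check_tension(tension)
  tension * (unit_vector(geom$p2, geom$p3) - unit_vector(geom$p1, geom$p2))
}

#' Device-to-body force at the thigh
#'
#' The elastic strap pulls the thigh anchor toward the buttocks contact
#' point: `F_T = T * unit(p4 -> p3)`, magnitude `T`.
#'
#' @inheritParams shoulder_force
#' @return Numeric (x, y) force vector in newtons.
#' @export
thigh_force <- function(geom, tension) {
  check_tension(tension)
  tension * unit_vector(geom$p4, geom$p3)
}

#' Torque components about L5-S1
#'
#' The assistive torque splits into the moment of the shoulder force acting
#' at `p1` and the moment of the pulley load acting at `p2` through the rigid
#' arm; the thigh force acts on the leg segment and does not load the trunk.
#' The `p1 -> p2` strap segment connects two points of the same (trunk + arm)
#' body, so its contributions cancel in the sum — see [assistive_torque()].
#'
#' @inheritParams shoulder_force
#' @return Named numeric vector `c(tau_t1, tau_ma)` in newton-metres.
#' @export
torque_components <- function(geom, tension) {
  check_tension(tension)
  tau_t1 <- cross2(geom$p1 - geom$p0, shoulder_force(geom, tension))
  tau_ma <- cross2(geom$p2 - geom$p0, waist_force(geom, tension))
  c(tau_t1 = tau_t1, tau_ma = tau_ma)
}

#' Assistive torque about L5-S1
#'
#' Because the shoulder-to-pulley strap segment acts internally on the
#' trunk + arm body, the total device torque reduces to the moment of the
#' distal strap tension alone: `tau = T * cross2(p2 - p0, unit(p2 -> p3))`.
#' This equals `sum(torque_components(geom, tension))` identically.
#'
#' @inheritParams shoulder_force
#' @return Signed scalar torque in newton-metres.
#' @export
assistive_torque <- function(geom, tension) {
  check_tension(tension)
  tension * cross2(geom$p2 - geom$p0, unit_vector(geom$p2, geom$p3))
}

#' Effective moment arm of the exosuit
#'
#' Assistive torque per unit strap tension; geometrically the perpendicular
#' distance from `p0` to the distal strap's line of action (the line through
#' `p2` with direction `unit(p2 -> p3)`).  Tension-independent.
#'
#' @param geom an [exo_geometry()].
#' @return Effective moment arm in metres (non-negative).
#' @export
effective_moment_arm <- function(geom) {
  abs(cross2(geom$p2 - geom$p0, unit_vector(geom$p2, geom$p3)))
}

#' Waist-to-shoulder force ratio K
#'
#' `K = |unit(p2 -> p3) - unit(p1 -> p2)|`, the magnitude ratio
#' `|F_W| / |F_S|` for any positive tension.  Bounded in `[0, 2]`: 0 for a
#' straight strap (pulley on the interior of `p1 -> p3`), 2 for a strap
#' folded back on itself at the pulley.
#'
#' @param geom an [exo_geometry()].
#' @return Dimensionless ratio in `[0, 2]`.
#' @export
force_ratio_k <- function(geom) {
  d <- unit_vector(geom$p2, geom$p3) - unit_vector(geom$p1, geom$p2)
  sqrt(sum(d * d))
}

#' Full device-to-body force state for one geometry and tension
#'
#' @inheritParams shoulder_force
#' @return List of class `exo_force_state` with the three device-to-body
#'   force vectors, the torque components, total assistive torque, effective
#'   moment arm and force ratio K.
#' @export
exo_force_state <- function(geom, tension) {
  check_tension(tension)
  tc <- torque_components(geom, tension)
  structure(list(
    tension = tension,
    f_shoulder = shoulder_force(geom, tension),
    f_waist = waist_force(geom, tension),
    f_thigh = thigh_force(geom, tension),
    tau_t1 = tc[["tau_t1"]],
    tau_ma = tc[["tau_ma"]],
    tau_exo = assistive_torque(geom, tension),
    r_eff = effective_moment_arm(geom),
    k_ratio = force_ratio_k(geom)
  ), class = "exo_force_state")
}

#' @export
print.exo_force_state <- function(x, ...) {
  cat("<exo_force_state>\n")
  cat(sprintf("  tension    : %.2f N\n", x$tension))
  cat(sprintf("  |F_S|      : %.2f N  (%.2f, %.2f)\n",
              sqrt(sum(x$f_shoulder^2)), x$f_shoulder[1L], x$f_shoulder[2L]))
  cat(sprintf("  |F_W|      : %.2f N  (%.2f, %.2f)\n",
              sqrt(sum(x$f_waist^2)), x$f_waist[1L], x$f_waist[2L]))
  cat(sprintf("  |F_T|      : %.2f N  (%.2f, %.2f)\n",
              sqrt(sum(x$f_thigh^2)), x$f_thigh[1L], x$f_thigh[2L]))
  cat(sprintf("  tau_exo    : %.3f N.m (tau_t1 %.3f + tau_ma %.3f)\n",
              x$tau_exo, x$tau_t1, x$tau_ma))
  cat(sprintf("  r_eff      : %.4f m\n", x$r_eff))
  cat(sprintf("  K          : %.4f\n", x$k_ratio))
  invisible(x)
}

#' Read or write an exosuit geometry config
#'
#' Flat key-value config with points in metres and optional strap stiffness
#' in N/m.  Format is chosen by file extension: `.yaml`/`.yml` or `.json`.
#' Values round-trip losslessly to full double precision.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @param geom an [exo_geometry()].
#' @param stiffness optional strap stiffness in N/m stored alongside points.
#' @return `read_geometry()` returns a list with `geometry`
#'   (an `exo_geometry`) and `stiffness` (or `NULL`);
#'   `write_geometry()` returns `path` invisibly.
#' @export
write_geometry <- function(geom, path, stiffness = NULL) {
  stopifnot(inherits(geom, "exo_geometry"))
  rec <- list(p0 = geom$p0, p1 = geom$p1, p2 = geom$p2, p3 = geom$p3, p4 = geom$p4)
  if (!is.null(stiffness)) rec$stiffness_N_per_m <- stiffness
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(rec, path, precision = 17L)
  } else if (ext == "json") {
    writeLines(jsonlite::toJSON(rec, digits = I(17), auto_unbox = FALSE), path)
  } else {
    stop("unsupported geometry config extension: ", ext)
  }
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rec <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path)
  } else {
    stop("unsupported geometry config extension: ", ext)
  }
  need <- c("p0", "p1", "p2", "p3", "p4")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("geometry config missing fields: ", paste(miss, collapse = ", "))
  list(
    geometry = exo_geometry(p2 = rec$p2, p1 = rec$p1, p3 = rec$p3,
                            p0 = rec$p0, p4 = rec$p4),
    stiffness = rec$stiffness_N_per_m
  )
}
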