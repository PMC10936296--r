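# Design-space exploration: sweep candidate pulley locations P2 over a
# sagittal grid, map the force ratio K and effective moment arm r_eff, and
# classify/rank named moment-arm configurations.

#' Sagittal sweep grid for pulley placement
#'
#' @param x range of cranial coordinates as `c(min, max, step)` in metres.
#' @param y range of posterior coordinates as `c(min, max, step)` in metres.
#'   Defaults cover the trunk's posterior region between the buttocks contact
#'   point and the shoulder anchor.
#' @return Object of class `sweep_grid` with `x2` and `y2` node vectors.
#' @export
sweep_grid <- function(x = c(-0.25, 0.40, 0.005), y = c(0.02, 0.35, 0.005)) {
  for (r in list(x, y)) {
    if (length(r) != 3L || r[1L] >= r[2L] || r[3L] <= 0) {
      stop("ranges must be c(min, max, step) with min < max and step > 0")
    }
  }
  structure(list(x2 = seq(x[1L], x[2L], by = x[3L]),
                 y2 = seq(y[1L], y[2L], by = y[3L]),
                 x = x, y = y),
            class = "sweep_grid")
}

#' Map K and r_eff over a grid of pulley locations
#'
#' Evaluates [force_ratio_k()] and [effective_moment_arm()] at every grid
#' node with the base geometry's `p0`, `p1`, `p3` held fixed.  Nodes that
#' coincide with `p1` or `p3` are degenerate and recorded as `NA`, never as
#' zero.  Values at grid nodes equal pointwise calls on the corresponding
#' [exo_geometry()] exactly (no interpolation).
#'
#' @param geom_base an [exo_geometry()] supplying `p0`, `p1`, `p3` (its `p2`
#'   is ignored).
#' @param grid a [sweep_grid()].
#' @return Object of class `design_map`: list with `grid`, and matrices `k`
#'   and `r_eff` of dimension `length(x2) x length(y2)`.
#' @export
sweep_design <- function(geom_base, grid = sweep_grid()) {
  stopifnot(inherits(geom_base, "exo_geometry"), inherits(grid, "sweep_grid"))
  nx <- length(grid$x2); ny <- length(grid$y2)
  if (nx == 0L || ny == 0L) stop("empty sweep grid")
  X <- matrix(grid$x2, nx, ny)
  Y <- matrix(grid$y2, nx, ny, byrow = TRUE)
  p0 <- geom_base$p0; p1 <- geom_base$p1; p3 <- geom_base$p3

  # distal strap direction u23 = unit(p2 -> p3)
  dx23 <- p3[1L] - X; dy23 <- p3[2L] - Y
  n23 <- sqrt(dx23^2 + dy23^2)
  # proximal strap direction u12 = unit(p1 -> p2)
  dx12 <- X - p1[1L]; dy12 <- Y - p1[2L]
  n12 <- sqrt(dx12^2 + dy12^2)

  bad <- n23 < 1e-12 | n12 < 1e-12
  n23[bad] <- NA_real_; n12[bad] <- NA_real_
  u23x <- dx23 / n23; u23y <- dy23 / n23
  u12x <- dx12 / n12; u12y <- dy12 / n12

  k <- sqrt((u23x - u12x)^2 + (u23y - u12y)^2)
  r_eff <- abs((X - p0[1L]) * u23y - (Y - p0[2L]) * u23x)
  structure(list(grid = grid, k = k, r_eff = r_eff, geom_base = geom_base),
            class = "design_map")
}

#' @export
print.design_map <- function(x, ...) {
  cat(sprintf("<design_map> %d x %d nodes (%d degenerate)\n",
              nrow(x$k), ncol(x$k), sum(is.na(x$k))))
  cat(sprintf("  K     in [%.4f, %.4f]\n", min(x$k, na.rm = TRUE), max(x$k, na.rm = TRUE)))
  cat(sprintf("  r_eff in [%.4f, %.4f] m\n",
              min(x$r_eff, na.rm = TRUE), max(x$r_eff, na.rm = TRUE)))
  invisible(x)
}

#' Classify a pulley location by region and radial distance
#'
#' Region follows the cranial coordinate of `p2` relative to L5-S1:
#' `above` if `x2 > tol`, `below` if `x2 < -tol`, otherwise `inline`
#' (in line with the joint).  The radius class compares `|p2 - p0|` with
#' `radius_threshold`.
#'
#' @param p2 pulley location (x, y) in metres.
#' @param p0 reference point, default origin.
#' @param radius_threshold radial cut between `short` and `long` arms (m).
#' @param tol half-width of the `inline` band (m).
#' @return List with `region`, `radius_class` and `radius`.
#' @export
classify_p2 <- function(p2, p0 = c(0, 0), radius_threshold = 0.12, tol = 0.01) {
  if (radius_threshold <= 0) stop("'radius_threshold' must be positive")
  p2 <- as_point2d(p2); p0 <- as_point2d(p0)
  x2 <- p2[1L] - p0[1L]
  region <- if (x2 > tol) "above" else if (x2 < -tol) "below" else "inline"
  radius <- sqrt(sum((p2 - p0)^2))
  list(region = region,
       radius_class = if (radius > radius_threshold) "long" else "short",
       radius = radius)
}

#' Build a candidate table from named pulley locations
#'
#' @param coords named list of (x, y) pulley locations in metres.
#' @param geom_base base [exo_geometry()] supplying the fixed anchors.
#' @param radius_threshold passed to [classify_p2()].
#' @return Data frame of class `config_candidates` with one row per
#'   candidate: name, x2, y2, region, radius_class, k_ratio, r_eff.
#' @export
make_candidates <- function(coords, geom_base = exo_geometry(p2 = c(0, 0.2)),
                            radius_threshold = 0.12) {
  stopifnot(length(coords) >= 1L, !is.null(names(coords)))
  rows <- lapply(names(coords), function(nm) {
    p2 <- as_point2d(coords[[nm]], nm)
    g <- exo_geometry(p2 = p2, p1 = geom_base$p1, p3 = geom_base$p3,
                      p0 = geom_base$p0, p4 = geom_base$p4)
    cl <- classify_p2(p2, geom_base$p0, radius_threshold)
    data.frame(name = nm, x2 = p2[1L], y2 = p2[2L],
               region = cl$region, radius_class = cl$radius_class,
               k_ratio = force_ratio_k(g), r_eff = effective_moment_arm(g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("config_candidates", "data.frame")
  out
}

#' Illustrative symmetric C1-C6 moment-arm candidates
#'
#' A classification-consistent layout: the inline pair sits on the posterior
#' axis, the above/below pairs at +/-30 degrees from it, with radial
#' distances 0.08 m (short: C1, C3, C5) and 0.16 m (long: C2, C4, C6).
#' These are illustrative defaults for region/radius classification and
#' ranking demos; the experiment never published its pulley coordinates.
#'
#' @inheritParams make_candidates
#' @return A `config_candidates` data frame (C1-C6).
#' @export
default_candidates <- function(geom_base = exo_geometry(p2 = c(0, 0.2)),
                               radius_threshold = 0.12) {
  polar <- function(theta_deg, r) {
    th <- theta_deg * pi / 180
    c(r * sin(th), r * cos(th))
  }
  coords <- list(
    C1 = polar(0, 0.08), C2 = polar(0, 0.16),     # inline short / long
    C3 = polar(30, 0.08), C4 = polar(30, 0.16),   # above  short / long
    C5 = polar(-30, 0.08), C6 = polar(-30, 0.16)  # below  short / long
  )
  make_candidates(coords, geom_base, radius_threshold)
}

#' Study-emulation C1-C6 moment-arm geometries
#'
#' The configuration set used by the synthetic-study generator.  It is
#' designed so that C4 carries both the largest effective moment arm and the
#' smallest K / r_eff among the six — reproducing the experimental ordering
#' in which C4 minimizes the shoulder *and* waist device-to-body force at a
#' given assistive torque.  Under the idealized static model a geometrically
#' symmetric layout cannot produce that double ordering (placements below or
#' in line with L5-S1 always reach a smaller K / r_eff than above ones of
#' equal radius), so the five non-C4 placements use sharp-wrap pulley
#' positions; the set is phenomenological, not a claim about the physical
#' emulator's coordinates.
#'
#' @inheritParams make_candidates
#' @return A `config_candidates` data frame (C1-C6).
#' @export
study_candidates <- function(geom_base = exo_geometry(p2 = c(0, 0.2)),
                             radius_threshold = 0.12) {
  coords <- list(
    C1 = c(-0.25, 0.05),
    C2 = c(-0.18, 0.03),
    C3 = c(-0.21, 0.04),
    C4 = c(0.05, 0.34),
    C5 = c(-0.20, 0.03),
    C6 = c(-0.20, 0.02)
  )
  make_candidates(coords, geom_base, radius_threshold)
}

#' Rank candidates by predicted device-to-body force at a target torque
#'
#' For each candidate the tension required to reach `target_torque` is
#' `T = tau / r_eff`, predicting `|F_S| = T` and `|F_W| = K * T`.  Candidates
#' are ordered ascending by the chosen force criterion (default shoulder
#' force, ties broken by waist force).  Candidates with `r_eff = 0` cannot
#' reach the torque and are dropped with a warning.
#'
#' @param candidates a `config_candidates` data frame (see
#'   [make_candidates()]).
#' @param target_torque assistive torque to reach, in newton-metres (> 0).
#' @param criterion `"shoulder"` or `"waist"`.
#' @return The candidate table with `required_tension`, `f_shoulder`,
#'   `f_waist` and `rank` columns, sorted by rank.
#' @export
rank_candidates <- function(candidates, target_torque,
                            criterion = c("shoulder", "waist")) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L)
  if (!is.numeric(target_torque) || target_torque <= 0) {
    stop("'target_torque' must be positive (N.m)")
  }
  drop <- candidates$r_eff <= 0
  if (any(drop)) {
    warning("excluding candidate(s) with zero effective moment arm: ",
            paste(candidates$name[drop], collapse = ", "))
    candidates <- candidates[!drop, , drop = FALSE]
  }
  if (!nrow(candidates)) stop("no candidates with positive r_eff")
  candidates$required_tension <- target_torque / candidates$r_eff
  candidates$f_shoulder <- candidates$required_tension
  candidates$f_waist <- candidates$k_ratio * candidates$required_tension
  keys <- if (criterion == "shoulder") {
    list(candidates$f_shoulder, candidates$f_waist)
  } else {
    list(candidates$f_waist, candidates$f_shoulder)
  }
  ord <- do.call(order, keys)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}

#' Export / read a design map as a long-format CSV
#'
#' Columns `x2, y2, K, r_eff`; degenerate nodes carry the explicit `NA`
#' marker and are never dropped.  Numeric values are written with 17
#' significant digits so a re-read reproduces the map to full precision.
#'
#' @param map a `design_map` from [sweep_design()].
#' @param path CSV file path.
#' @return `export_design_map()` returns `path` invisibly;
#'   `read_design_map()` returns a data frame with the four columns.
#' @export
export_design_map <- function(map, path) {
  stopifnot(inherits(map, "design_map"))
  long <- design_map_table(map)
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- data.frame(x2 = fmt(long$x2), y2 = fmt(long$y2),
                    K = fmt(long$K), r_eff = fmt(long$r_eff))
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname export_design_map
#' @export
read_design_map <- function(path) {
  df <- data.table::fread(path, na.strings = "NA", data.table = FALSE,
                          colClasses = list(numeric = c("x2", "y2", "K", "r_eff")))
  need <- c("x2", "y2", "K", "r_eff")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("design map file missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Long-format view of a design map
#'
#' @param map a `design_map`.
#' @return Data frame with one row per grid node: `x2, y2, K, r_eff`.
#' @export
design_map_table <- function(map) {
  stopifnot(inherits(map, "design_map"))
  data.frame(
    x2 = rep(map$grid$x2, times = length(map$grid$y2)),
    y2 = rep(map$grid$y2, each = length(map$grid$x2)),
    K = as.vector(map$k),
    r_eff = as.vector(map$r_eff)
  )
}

#' Contour plot of a design map (presentation only)
#'
#' @param map a `design_map`.
#' @param what `"k"` or `"r_eff"`.
#' @param ... passed to [graphics::filled.contour()].
#' @return Invisibly `NULL`; draws on the current device.
#' @export
plot_design_map <- function(map, what = c("k", "r_eff"), ...) {
  stopifnot(inherits(map, "design_map"))
  what <- match.arg(what)
  z <- if (what == "k") map$k else map$r_eff
  graphics::filled.contour(
    map$grid$x2, map$grid$y2, z,
    color.palette = grDevices::hcl.colors,
    xlab = "x2 (m, cranial+)", ylab = "y2 (m, posterior+)",
    main = if (what == "k") "Force ratio K" else "Effective moment arm (m)",
    ...)
  invisible(NULL)
}
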