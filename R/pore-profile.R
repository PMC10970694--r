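# Pore-dimension profiling in the spirit of HOLE: at stations along a fixed
# axis, the radius of the largest sphere that fits the pore is found as the
# maximum over lateral centre positions of (distance to the nearest atom
# surface). Unlike HOLE's connected Monte-Carlo walk, each station is an
# independent deterministic 2D maximisation - adequate for near-straight
# paracellular pores whose axis is known, and reproducible.

#' Pore-axis specification
#'
#' The pore axis is supplied, not discovered; by convention paracellular
#' pores run along +x (the membrane normal being z).
#'
#' @param x_min,x_max axial extent to profile, Angstrom.
#' @param station_spacing station step, Angstrom (default 0.5).
#' @param search_radius lateral search bound around the axis, Angstrom
#'   (default 15).
#' @param grid_step lateral grid resolution for the coarse search, Angstrom
#'   (default 0.25).
#' @return Object of class `pore_axis_spec`.
#' @export
pore_axis_spec <- function(x_min, x_max, station_spacing = 0.5,
                           search_radius = 15, grid_step = 0.25) {
  stopifnot(x_min < x_max, station_spacing > 0, search_radius > 0,
            grid_step > 0)
  structure(list(x_min = x_min, x_max = x_max,
                 station_spacing = station_spacing,
                 search_radius = search_radius, grid_step = grid_step),
            class = "pore_axis_spec")
}

# radius(c) = min over atoms of (|c - atom| - r_vdw), vectorised over a
# block of candidate centres (m x 3)
.min_clearance <- function(centers, axyz, avdw) {
  m <- nrow(centers)
  d2 <- outer(rowSums(centers^2), rowSums(axyz^2), "+") -
    2 * tcrossprod(centers, axyz)
  d <- sqrt(pmax(d2, 0))
  d <- d - rep(avdw, each = m)
  do.call(pmin, lapply(seq_len(ncol(d)), function(j) d[, j]))
}

#' Maximal inscribed sphere radius at one axial station
#'
#' Searches candidate centres in the plane through `station` perpendicular
#' to the x axis (lateral offset at most `search_radius`): a coarse grid at
#' `grid_step` followed by Nelder-Mead refinement to 0.01 Angstrom. The
#' radius at a centre is the minimal distance to any non-excluded atom
#' surface; a negative maximum is reported as-is with `blocked = TRUE`.
#'
#' @param frame a [frame()].
#' @param topology a [topology()].
#' @param station axial position, Angstrom.
#' @param spec a [pore_axis_spec()].
#' @param exclude selection of atoms (ions, water) to ignore.
#' @return list `center` (3-vector), `radius` (Angstrom), `blocked`.
#' @export
pore_radius_at_station <- function(frame, topology, station, spec,
                                   exclude = NULL) {
  keep <- rep(TRUE, n_atoms(topology))
  if (!is.null(exclude)) {
    ex <- suppressWarnings(resolve_selection(exclude, topology))
    keep[ex] <- FALSE
  }
  axyz <- frame$coords[keep, , drop = FALSE]
  avdw <- topology$atoms$vdw[keep]
  # atoms too far along x to ever bound the search region are irrelevant
  near <- abs(axyz[, 1] - station) <= spec$search_radius + max(avdw) + 5
  if (!any(near))
    stop("undefined station: no atoms within range of station ", station)
  axyz <- axyz[near, , drop = FALSE]
  avdw <- avdw[near]

  g <- seq(-spec$search_radius, spec$search_radius, by = spec$grid_step)
  gy <- rep(g, times = length(g))
  gz <- rep(g, each = length(g))
  ok <- gy^2 + gz^2 <= spec$search_radius^2
  gy <- gy[ok]; gz <- gz[ok]
  centers <- cbind(station, gy, gz)
  # evaluate in blocks to bound memory
  block <- 4000L
  best_r <- -Inf; best_c <- c(station, 0, 0)
  for (s in seq(1L, nrow(centers), by = block)) {
    e <- min(s + block - 1L, nrow(centers))
    r <- .min_clearance(centers[s:e, , drop = FALSE], axyz, avdw)
    i <- which.max(r)
    if (r[i] > best_r) { best_r <- r[i]; best_c <- centers[s:e, ][i, ] }
  }
  # local polish (deterministic start from the best grid point)
  obj <- function(p) {
    if (p[1]^2 + p[2]^2 > spec$search_radius^2) return(1e6)
    -.min_clearance(matrix(c(station, p[1], p[2]), 1), axyz, avdw)
  }
  fit <- optim(best_c[2:3], obj, method = "Nelder-Mead",
               control = list(reltol = 1e-8, abstol = 1e-4, maxit = 200))
  if (-fit$value > best_r) {
    best_r <- -fit$value
    best_c <- c(station, fit$par)
  }
  list(center = unname(best_c), radius = unname(best_r),
       blocked = best_r < 0)
}

#' Pore diameter profile along the axis
#'
#' Per station, mean and SD over the window frames of twice the maximal
#' inscribed sphere radius.
#'
#' @param traj a [trajectory()].
#' @param spec a [pore_axis_spec()].
#' @param window frame window (default all frames).
#' @param exclude selection of atoms to ignore (ions, water).
#' @return Object of class `pore_profile`: data frame `profile` with columns
#'   `station_A`, `mean_diameter_A`, `sd_A`, `blocked`; `min_mean_diameter`
#'   and `min_station`; matrix `per_frame` of diameters.
#' @export
pore_profile <- function(traj, spec, window = NULL, exclude = NULL) {
  idx <- resolve_window(window, n_frames(traj))
  stations <- seq(spec$x_min, spec$x_max, by = spec$station_spacing)
  per_frame <- matrix(NA_real_, length(stations), length(idx))
  blocked <- matrix(FALSE, length(stations), length(idx))
  for (j in seq_along(idx)) {
    fr <- traj$frames[[idx[j]]]
    for (i in seq_along(stations)) {
      res <- tryCatch(
        pore_radius_at_station(fr, traj$topology, stations[i], spec, exclude),
        error = function(e) NULL)
      if (!is.null(res)) {
        per_frame[i, j] <- 2 * res$radius
        blocked[i, j] <- res$blocked
      }
    }
  }
  mean_d <- rowMeans(per_frame)
  # population SD over the window frames (descriptive spread, not an
  # estimator of an underlying distribution)
  sd_d <- sqrt(rowMeans((per_frame - mean_d)^2))
  prof <- data.frame(station_A = stations, mean_diameter_A = mean_d,
                     sd_A = sd_d, blocked = rowSums(blocked) > 0)
  imin <- which.min(mean_d)
  structure(list(profile = prof, per_frame = per_frame,
                 min_mean_diameter = mean_d[imin],
                 min_station = stations[imin]),
            class = "pore_profile")
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("pore profile:", nrow(x$profile), "stations; minimal mean diameter",
      round(x$min_mean_diameter, 2), "A at station", x$min_station, "A\n")
  invisible(x)
}

#' Write a pore profile to CSV
#' @param profile a [pore_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pore_profile <- function(profile, path) {
  write.csv(profile$profile, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
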