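# Bespoke permeation statistics for paracellular pores: bottleneck-tetrad
# crossing detection, cuboid filtering of pore-passing ions, total axial
# displacement, mean ion counts in the pore, ion-residue contact-time
# profiles, and displacement-versus-voltage selectivity regression.

#' Center of the bottleneck tetrad
#'
#' The crossing plane of the pore is defined by the four symmetry-equivalent
#' residues at the pore centre (e.g. an H60 or D56 tetrad). The centre is the
#' unweighted centre of geometry of all tetrad atoms; mass weighting is
#' available as an option (the difference is negligible for symmetric
#' tetrads).
#'
#' @param frame a [frame()].
#' @param topology a [topology()].
#' @param tetrad selection resolving to the 4 tetrad residues.
#' @param mass_weighted weight atoms by approximate atomic mass.
#' @return numeric 3-vector.
#' @export
bottleneck_com <- function(frame, topology, tetrad, mass_weighted = FALSE) {
  idx <- resolve_selection(tetrad, topology)
  a <- topology$atoms[idx, , drop = FALSE]
  nres <- length(unique(paste(a$chain, a$res_num)))
  if (nres != 4L)
    stop("config error: bottleneck tetrad must resolve to exactly 4 ",
         "residues (got ", nres, ")")
  xyz <- frame$coords[idx, , drop = FALSE]
  if (mass_weighted) {
    mass <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
              P = 30.974)[toupper(a$element)]
    mass[is.na(mass)] <- 12.011
    unname(colSums(xyz * mass) / sum(mass))
  } else {
    unname(colMeans(xyz))
  }
}

#' Cuboid bounds from entrance residue C-alpha atoms
#'
#' The axis-aligned box restricting which ions count as pore-passing: its
#' bounds are the per-axis min/max over the window-averaged positions of the
#' 8 entrance C-alpha atoms (4 per pore end).
#'
#' @param traj a [trajectory()].
#' @param entrance_ca selection resolving to exactly 8 atoms.
#' @param window frame window for the averaging (default all frames).
#' @return Object of class `cuboid_bounds` with `x_lo..z_hi`.
#' @export
cuboid_bounds <- function(traj, entrance_ca, window = NULL) {
  idx <- resolve_selection(entrance_ca, traj$topology)
  if (length(idx) != 8L)
    stop("config error: entrance selection must resolve to exactly 8 ",
         "C-alpha atoms (got ", length(idx), ")")
  widx <- resolve_window(window, n_frames(traj))
  acc <- matrix(0, 8, 3)
  for (fi in widx) acc <- acc + traj$frames[[fi]]$coords[idx, , drop = FALSE]
  avg <- acc / length(widx)
  b <- structure(list(x_lo = min(avg[, 1]), x_hi = max(avg[, 1]),
                      y_lo = min(avg[, 2]), y_hi = max(avg[, 2]),
                      z_lo = min(avg[, 3]), z_hi = max(avg[, 3])),
                 class = "cuboid_bounds")
  if (b$x_lo >= b$x_hi || b$y_lo >= b$y_hi || b$z_lo >= b$z_hi)
    stop("config error: degenerate cuboid (lo >= hi on some axis)")
  b
}

# membership: x within bounds (inclusive), y and z strictly within
.in_cuboid <- function(xyz, b) {
  xyz[, 1] >= b$x_lo & xyz[, 1] <= b$x_hi &
  xyz[, 2] >  b$y_lo & xyz[, 2] <  b$y_hi &
  xyz[, 3] >  b$z_lo & xyz[, 3] <  b$z_hi
}

.ion_indices <- function(topology, species) {
  which(topology$atoms$res_name == species)
}

#' Detect pore-passing ions
#'
#' An ion is selected iff there are consecutive window frames between which
#' the sign of (x_ion - x_centre) changes, with the ion inside the cuboid at
#' both flanking frames (the bottleneck-centre x-plane is evaluated per
#' frame, so the centre may drift). One record is kept per ion - the first
#' crossing - since the displacement sum must not duplicate ions. With
#' `strict_transit = TRUE`, cuboid membership is instead required for every
#' window frame.
#'
#' @param traj a [trajectory()].
#' @param tetrad bottleneck tetrad selection (see [bottleneck_com()]).
#' @param cuboid a [cuboid_bounds()].
#' @param species ion residue name (e.g. `"CL"`).
#' @param window frame window (default all frames).
#' @param strict_transit require cuboid membership over the whole window.
#' @return data frame with one row per selected ion: `atom` (topology row),
#'   `ion_id`, `species`, `first_crossing_frame`, `direction` (+1/-1),
#'   `inside_cuboid`.
#' @export
detect_pore_passing_ions <- function(traj, tetrad, cuboid, species,
                                     window = NULL, strict_transit = FALSE) {
  widx <- resolve_window(window, n_frames(traj))
  ions <- .ion_indices(traj$topology, species)
  empty <- data.frame(atom = integer(0), ion_id = integer(0),
                      species = character(0),
                      first_crossing_frame = integer(0),
                      direction = integer(0), inside_cuboid = logical(0))
  if (length(ions) == 0L) return(empty)
  nw <- length(widx)
  com_x <- vapply(widx, function(fi)
    bottleneck_com(traj$frames[[fi]], traj$topology, tetrad)[1], numeric(1))
  # frames x ions arrays of x offset from the crossing plane and membership
  offs <- matrix(NA_real_, nw, length(ions))
  inside <- matrix(NA, nw, length(ions))
  for (j in seq_len(nw)) {
    xyz <- traj$frames[[widx[j]]]$coords[ions, , drop = FALSE]
    offs[j, ] <- xyz[, 1] - com_x[j]
    inside[j, ] <- .in_cuboid(xyz, cuboid)
  }
  rows <- lapply(seq_along(ions), function(k) {
    if (strict_transit && !all(inside[, k])) return(NULL)
    cross <- which(offs[-nw, k] * offs[-1L, k] < 0 &
                   inside[-nw, k] & inside[-1L, k])
    if (length(cross) == 0L) return(NULL)
    t0 <- cross[1L]
    data.frame(atom = ions[k],
               ion_id = traj$topology$atoms$res_num[ions[k]],
               species = species,
               first_crossing_frame = widx[t0 + 1L],
               direction = if (offs[t0 + 1L, k] > offs[t0, k]) 1L else -1L,
               inside_cuboid = TRUE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) empty else out
}

#' Total axial displacement of selected ions
#'
#' The permeation proxy: the sum over selected ions and over consecutive
#' window frames of the increment of the unwrapped pore-axis coordinate,
#' `D = sum_i sum_t (x_i(t+1) - x_i(t))`, which telescopes to
#' `sum_i (x_i(t_end) - x_i(t_start))`. Unwrapping uses explicit wrap
#' bookkeeping (synthetic trajectories) or minimum-image continuity when the
#' frames carry a box.
#'
#' @param traj a [trajectory()].
#' @param atoms topology row indices of the selected ions (e.g. the `atom`
#'   column from [detect_pore_passing_ions()]).
#' @param window frame window (default all frames).
#' @return signed displacement in Angstrom (0 with a warning for an empty
#'   selection).
#' @export
total_displacement <- function(traj, atoms, window = NULL) {
  if (length(atoms) == 0L) {
    warning("no ions selected; total displacement is 0", call. = FALSE)
    return(0)
  }
  widx <- resolve_window(window, n_frames(traj))
  x <- unwrapped_x(traj, atoms)[widx, , drop = FALSE]
  sum(diff(x))
}

#' Mean number of ions inside the cuboid
#'
#' @param traj a [trajectory()].
#' @param cuboid a [cuboid_bounds()].
#' @param species ion residue name.
#' @param window frame window (default all frames).
#' @return mean count over window frames.
#' @export
mean_ion_count <- function(traj, cuboid, species, window = NULL) {
  widx <- resolve_window(window, n_frames(traj))
  ions <- .ion_indices(traj$topology, species)
  if (length(ions) == 0L) return(0)
  mean(vapply(widx, function(fi)
    sum(.in_cuboid(traj$frames[[fi]]$coords[ions, , drop = FALSE], cuboid)),
    numeric(1)))
}

#' Ion contact-time profile of pore-lining residues
#'
#' For each residue number and each subunit (chain), the percentage of
#' window frames in which the residue's minimum atom-ion distance to at
#' least one ion of the species is strictly below the cutoff; percentages
#' are then averaged over the subunits.
#'
#' @param traj a [trajectory()].
#' @param res_nums residue numbers of the pore-lining residues.
#' @param chains chains (subunits) to average over.
#' @param species ion residue name.
#' @param cutoff contact cutoff, Angstrom (strict <; default 4).
#' @param window frame window (default all frames).
#' @return data frame `res_num`, `label`, `percent` (0-100).
#' @export
ion_contact_time <- function(traj, res_nums, chains, species, cutoff = 4.0,
                             window = NULL) {
  widx <- resolve_window(window, n_frames(traj))
  top <- traj$topology
  ions <- .ion_indices(top, species)
  per_chain <- matrix(0, length(res_nums), length(chains))
  for (ci in seq_along(chains)) {
    for (ri in seq_along(res_nums)) {
      ra <- which(top$atoms$chain == chains[ci] &
                  top$atoms$res_num == res_nums[ri])
      if (length(ra) == 0L || length(ions) == 0L) {
        per_chain[ri, ci] <- NA_real_
        next
      }
      hits <- vapply(widx, function(fi) {
        fr <- traj$frames[[fi]]
        .min_cross_dist(fr$coords[ra, , drop = FALSE],
                        fr$coords[ions, , drop = FALSE]) < cutoff
      }, logical(1))
      per_chain[ri, ci] <- 100 * mean(hits)
    }
  }
  labels <- vapply(seq_along(res_nums), function(ri) {
    at <- which(top$atoms$res_num == res_nums[ri] &
                top$atoms$chain %in% chains)
    if (length(at)) paste0(.one_letter(top$atoms$res_name[at[1]]),
                           res_nums[ri])
    else as.character(res_nums[ri])
  }, character(1))
  data.frame(res_num = res_nums, label = labels,
             percent = rowMeans(per_chain, na.rm = TRUE))
}

#' Transport summary for one voltage run
#'
#' Runs the full permeation pipeline on a trajectory carrying BNK/ENT marker
#' residues (as produced by the synthetic generator): cuboid from the
#' entrance C-alpha atoms, bottleneck-crossing ion selection per species,
#' total displacement over the selected ions, and mean in-cuboid ion count.
#'
#' @param traj a [trajectory()]; voltage is taken from `traj$synth$voltage`
#'   unless given.
#' @param species character vector of ion residue names; defaults to the
#'   generator's species.
#' @param voltage applied voltage (volts).
#' @param window frame window (default all frames).
#' @return Object of class `transport_result`: `voltage` plus data frame
#'   `species` with columns `species`, `total_displacement_A`,
#'   `n_selected_ions`, `mean_ions_in_cuboid`.
#' @export
measure_transport <- function(traj, species = NULL, voltage = NULL,
                              window = NULL) {
  if (is.null(voltage)) voltage <- traj$synth$voltage
  if (is.null(species)) species <- traj$synth$species
  if (is.null(species)) stop("species must be given for non-synthetic input")
  tetrad <- select_atoms(res_name = "BNK")
  entrance <- select_atoms(res_name = "ENT", atom_name = "CA")
  cb <- cuboid_bounds(traj, entrance, window = window)
  per <- lapply(species, function(sp) {
    rec <- detect_pore_passing_ions(traj, tetrad, cb, sp, window = window)
    D <- if (nrow(rec) == 0L) 0 else
      total_displacement(traj, rec$atom, window = window)
    data.frame(species = sp, total_displacement_A = D,
               n_selected_ions = nrow(rec),
               mean_ions_in_cuboid = mean_ion_count(traj, cb, sp,
                                                    window = window))
  })
  structure(list(voltage = voltage, species = do.call(rbind, per),
                 cuboid = cb),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat("transport result at", x$voltage, "V:\n")
  print(x$species, row.names = FALSE)
  invisible(x)
}

#' Displacement-versus-voltage selectivity regression
#'
#' Ordinary least-squares fit of total displacement against voltage, per
#' species, across a set of runs. The charge selectivity of the pore is read
#' from the relative magnitudes of the fitted slopes.
#'
#' @param results list of [measure_transport()] results (>= 2 distinct
#'   voltages).
#' @return Object of class `selectivity_fit`: data frame `fits` with
#'   `species`, `slope_A_per_V`, `slope_se`, `intercept_A`, `r_squared`,
#'   `n_points`; `points` with the underlying (voltage, D) data.
#' @export
selectivity_regression <- function(results) {
  pts <- do.call(rbind, lapply(results, function(r)
    cbind(voltage = r$voltage, r$species)))
  if (length(unique(pts$voltage)) < 2L)
    stop("degenerate fit: at least 2 distinct voltages required")
  fits <- lapply(split(pts, pts$species), function(d) {
    m <- lm(total_displacement_A ~ voltage, data = d)
    sm <- summary(m)
    data.frame(species = d$species[1],
               slope_A_per_V = unname(coef(m)[2]),
               slope_se = sm$coefficients[2, 2],
               intercept_A = unname(coef(m)[1]),
               r_squared = sm$r.squared,
               n_points = nrow(d))
  })
  structure(list(fits = do.call(rbind, c(fits, make.row.names = FALSE)),
                 points = pts),
            class = "selectivity_fit")
}

#' @export
print.selectivity_fit <- function(x, ...) {
  cat("selectivity regression (", nrow(x$points), " points ):\n", sep = "")
  print(x$fits, row.names = FALSE)
  invisible(x)
}
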