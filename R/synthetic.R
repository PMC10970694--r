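# Synthetic toy-pore scaffolds and drift-diffusion ion walks with known
# ground truth. The generator emulates the statistical structure the
# transport analysis assumes: a bounded, roughly cylindrical pore along +x,
# marker residue tetrads at the pore centre ("BNK") and entrances ("ENT"),
# and two ion species drifting along the axis with species-dependent,
# voltage-scaled mobility.

#' Build a toy cylindrical pore scaffold
#'
#' Places scaffold pseudo-atoms of radius `scaffold_atom_radius` on a
#' cylindrical shell of radius `pore_radius + scaffold_atom_radius` centred
#' on the +x axis, spanning `[-pore_length/2, +pore_length/2]`, densely
#' enough that no probe of radius `scaffold_atom_radius` escapes radially.
#' The free lumen of the resulting pore has radius `pore_radius`.
#'
#' @param pore_radius free lumen radius (Angstrom).
#' @param pore_length axial extent of the scaffold (Angstrom).
#' @param scaffold_atom_radius van der Waals radius assigned to every
#'   scaffold pseudo-atom (Angstrom).
#' @param axial_spacing spacing between rings along x (Angstrom); default
#'   equal to `scaffold_atom_radius`.
#' @param angular_count atoms per ring; default
#'   `ceiling(2*pi*(pore_radius + scaffold_atom_radius)/scaffold_atom_radius)`.
#' @param include_marker_tetrads if `TRUE`, add 4 single-atom "BNK" residues
#'   at x = 0 (bottleneck tetrad) and 8 "ENT" residues with a CA atom at each
#'   pore end (cuboid corners).
#' @param constriction optional `list(x =, pore_radius =)` adding a ring at
#'   axial position `x` whose local lumen radius is `pore_radius`.
#' @return `list(topology =, frame =)` as from [read_structure()].
#' @export
build_toy_pore <- function(pore_radius, pore_length,
                           scaffold_atom_radius = 1.5,
                           axial_spacing = scaffold_atom_radius,
                           angular_count = NULL,
                           include_marker_tetrads = TRUE,
                           constriction = NULL) {
  stopifnot(pore_radius > 0, pore_length > 0, scaffold_atom_radius > 0)
  a <- scaffold_atom_radius
  shell <- pore_radius + a
  if (is.null(angular_count)) angular_count <- ceiling(2 * pi * shell / a)
  # geometry check: surface-to-surface gaps must not exceed the atom radius
  chord <- 2 * shell * sin(pi / angular_count)
  if (chord - 2 * a > a || axial_spacing - 2 * a > a)
    stop("geometry error: scaffold spacing leaves radial gaps wider than ",
         "the scaffold atom radius")
  xs <- seq(-pore_length / 2, pore_length / 2, by = axial_spacing)
  ring_fun <- function(x0, r, n, phase = 0) {
    th <- phase + 2 * pi * (seq_len(n) - 1L) / n
    cbind(x = rep(x0, n), y = r * cos(th), z = r * sin(th))
  }
  coords <- do.call(rbind, lapply(seq_along(xs), function(i)
    ring_fun(xs[i], shell, angular_count, phase = (i %% 2) * pi / angular_count)))
  if (!is.null(constriction)) {
    stopifnot(is.list(constriction), constriction$pore_radius > 0,
              constriction$pore_radius < pore_radius)
    rc <- constriction$pore_radius + a
    nc <- ceiling(2 * pi * rc / a)
    coords <- rbind(coords, ring_fun(constriction$x, rc, nc))
  }
  ns <- nrow(coords)
  atoms <- data.frame(
    atom_id = seq_len(ns), atom_name = "C", element = "C",
    res_name = "SCF", res_num = seq_len(ns), chain = "S",
    vdw = a, stringsAsFactors = FALSE)
  if (include_marker_tetrads) {
    bnk <- ring_fun(0, shell, 4L)
    ent <- rbind(ring_fun(-pore_length / 2, shell, 4L),
                 ring_fun(+pore_length / 2, shell, 4L))
    marker <- data.frame(
      atom_id = ns + 1:12, atom_name = "CA", element = "C",
      res_name = rep(c("BNK", "ENT"), c(4L, 8L)),
      res_num = 1:12, chain = "P", vdw = a, stringsAsFactors = FALSE)
    atoms <- rbind(atoms, marker)
    coords <- rbind(coords, bnk, ent)
  }
  top <- topology(atoms)
  top$pore <- list(pore_radius = pore_radius, pore_length = pore_length,
                   scaffold_atom_radius = a)
  list(topology = top, frame = frame(coords))
}

#' Simulate a drift-diffusion ion walk inside a toy pore
#'
#' Ions of each species start uniformly at random inside the pore cylinder.
#' Per step, the axial coordinate advances by `drift_per_frame[species]` plus
#' Gaussian noise; y and z receive Gaussian noise with reflecting walls at
#' radial distance `pore_radius`. At `x = +-(pore_length/2 + 5)` an ion is
#' reinjected at the opposite end (periodic in x); wrap events are recorded so
#' that displacement statistics use unwrapped coordinates. All randomness
#' comes from one generator seeded with `seed`: first the initial positions
#' (axial, radial, angular, in topology order), then one x/y/z noise triple
#' per ion per step.
#'
#' @param pore result of [build_toy_pore()] (must include marker tetrads).
#' @param n_ions_per_species ions per species.
#' @param drift_per_frame named numeric vector, Angstrom/frame per species
#'   (names are residue names, e.g. `c("CL" = 0.35, "NA" = 0)`).
#' @param diffusion_sigma Gaussian step SD (Angstrom/frame).
#' @param n_frames number of saved frames; frame 1 is the initial
#'   configuration, so `n_frames - 1` steps are taken.
#' @param seed integer RNG seed.
#' @param voltage applied-voltage label (volts) carried into results.
#' @return A [trajectory()] over scaffold plus ion atoms, with wrap
#'   bookkeeping and the generator parameters attached as `$synth`.
#' @export
simulate_ion_walk <- function(pore, n_ions_per_species, drift_per_frame,
                              diffusion_sigma, n_frames, seed,
                              voltage = NA_real_) {
  stopifnot(diffusion_sigma >= 0, n_frames >= 2,
            !is.null(names(drift_per_frame)))
  top <- pore$topology
  if (!any(top$atoms$res_name == "BNK"))
    stop("pore must be built with marker tetrads")
  R <- top$pore$pore_radius
  L <- top$pore$pore_length
  period <- L + 10
  species <- names(drift_per_frame)
  n_sp <- length(species)
  n_ions <- n_ions_per_species * n_sp
  ion_species <- rep(species, each = n_ions_per_species)
  ns <- n_atoms(top)
  ion_atoms <- data.frame(
    atom_id = ns + seq_len(n_ions),
    atom_name = ion_species, element = ion_species,
    res_name = ion_species, res_num = seq_len(n_ions), chain = "I",
    vdw = .vdw_radius(ion_species), stringsAsFactors = FALSE)
  cols <- names(ion_atoms)
  full_top <- topology(rbind(top$atoms[, cols], ion_atoms))
  full_top$pore <- top$pore

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  x <- runif(n_ions, -L / 2, L / 2)
  r <- R * sqrt(runif(n_ions))
  th <- runif(n_ions, 0, 2 * pi)
  y <- r * cos(th); z <- r * sin(th)
  drift <- unname(drift_per_frame[ion_species])

  scaffold_xyz <- pore$frame$coords
  frames <- vector("list", n_frames)
  wrap <- matrix(0, n_frames, ns + n_ions)
  wcur <- numeric(n_ions)
  frames[[1]] <- frame(rbind(scaffold_xyz, cbind(x, y, z)), time = 0)
  for (t in 2:n_frames) {
    x <- x + drift + rnorm(n_ions, 0, diffusion_sigma)
    y <- y + rnorm(n_ions, 0, diffusion_sigma)
    z <- z + rnorm(n_ions, 0, diffusion_sigma)
    rad <- sqrt(y^2 + z^2)
    out <- rad > R
    if (any(out)) {
      scale <- pmax(2 * R - rad[out], 0) / rad[out]
      y[out] <- y[out] * scale
      z[out] <- z[out] * scale
    }
    hi <- x > L / 2 + 5
    lo <- x < -(L / 2 + 5)
    x[hi] <- x[hi] - period; wcur[hi] <- wcur[hi] + 1
    x[lo] <- x[lo] + period; wcur[lo] <- wcur[lo] - 1
    wrap[t, ns + seq_len(n_ions)] <- wcur
    frames[[t]] <- frame(rbind(scaffold_xyz, cbind(x, y, z)), time = t - 1)
  }
  traj <- trajectory(full_top, frames, wrap = wrap, wrap_period = period)
  traj$synth <- list(n_ions_per_species = n_ions_per_species,
                     drift_per_frame = drift_per_frame,
                     diffusion_sigma = diffusion_sigma,
                     n_frames = n_frames, seed = seed, voltage = voltage,
                     species = species)
  traj
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Standard transport-experiment presets
#'
#' Bundles [build_toy_pore()] and [simulate_ion_walk()] into the study
#' conditions used throughout the package's validation: a lumen of radius
#' 5 Angstrom and length 40 Angstrom, 20 ions per species, 400 frames, step
#' noise 0.3 Angstrom/frame, and drift proportional to the applied voltage
#' with mobility 0.25 Angstrom/frame/V. The `"anion-selective"` preset gives
#' that mobility to Cl- only (Na+ mobility 0), emulating an anion-selective
#' pore; `"symmetric"` gives it to both species (zero-selectivity control).
#'
#' @param preset `"anion-selective"` or `"symmetric"`.
#' @param voltage applied voltage in volts (signed).
#' @param seed integer RNG seed.
#' @param n_ions_per_species,n_frames,diffusion_sigma,mobility,pore_radius,pore_length
#'   overrides of the preset conditions.
#' @return A [trajectory()], as from [simulate_ion_walk()].
#' @export
simulate_transport <- function(preset = c("anion-selective", "symmetric"),
                               voltage, seed,
                               n_ions_per_species = 20, n_frames = 400,
                               diffusion_sigma = 0.3, mobility = 0.25,
                               pore_radius = 5, pore_length = 40) {
  preset <- match.arg(preset)
  pore <- build_toy_pore(pore_radius, pore_length, scaffold_atom_radius = 2,
                         axial_spacing = 2)
  drift <- switch(preset,
    "anion-selective" = c(CL = mobility * voltage, "NA" = 0),
    "symmetric"       = c(CL = mobility * voltage, "NA" = mobility * voltage))
  simulate_ion_walk(pore, n_ions_per_species, drift, diffusion_sigma,
                    n_frames, seed, voltage = voltage)
}

#' Write synthetic outputs to disk
#'
#' Writes the scaffold as a standard PDB, the ion trajectory as the internal
#' frame-table CSV, and all generator parameters as JSON, so a run can be
#' reproduced from its artefacts.
#'
#' @param traj trajectory from [simulate_ion_walk()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_synth_outputs <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  is_ion <- traj$topology$atoms$chain == "I"
  scaffold_idx <- which(!is_ion)
  scaffold_top <- topology(traj$topology$atoms[scaffold_idx, , drop = FALSE])
  f_pdb <- file.path(dir, "scaffold.pdb")
  write_structure(scaffold_top,
                  frame(traj$frames[[1]]$coords[scaffold_idx, , drop = FALSE]),
                  f_pdb)
  f_csv <- file.path(dir, "ions.csv")
  write_frame_table(traj, f_csv, atoms = which(is_ion))
  f_json <- file.path(dir, "params.json")
  jsonlite::write_json(traj$synth, f_json, auto_unbox = TRUE, digits = NA)
  invisible(c(scaffold = f_pdb, ions = f_csv, params = f_json))
}
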