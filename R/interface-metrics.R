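# Scalar and time-series interface metrics: backbone hydrogen-bond counts,
# named atom-pair distance series, persistence-thresholded contact counts,
# Shrake-Rupley solvent-accessible surface area, and backbone RMSD.

#' Hydrogen-bond geometric criterion
#'
#' Default criterion: donor-acceptor heavy-atom distance <= 3.5 Angstrom and
#' D-H...A angle >= 120 degrees when amide hydrogens are present. In
#' heavy-atom-only mode (the default here, since typical inputs are
#' heavy-atom models) the N...O distance is combined with a C(=O)...N angle
#' >= 100 degrees at the acceptor.
#'
#' @param donor_acceptor_max maximum donor-acceptor distance, Angstrom.
#' @param angle_min minimum angle, degrees.
#' @param heavy_atom_only if `TRUE`, use the N...O / carbonyl-angle form.
#' @return Object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(donor_acceptor_max = 3.5,
                            angle_min = if (heavy_atom_only) 100 else 120,
                            heavy_atom_only = TRUE) {
  stopifnot(donor_acceptor_max > 0, angle_min >= 0, angle_min <= 180)
  structure(list(donor_acceptor_max = donor_acceptor_max,
                 angle_min = angle_min, heavy_atom_only = heavy_atom_only),
            class = "hbond_criterion")
}

.angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

# backbone donor/acceptor inventory for one segment
.bb_inventory <- function(topology, frame, idx) {
  a <- topology$atoms
  bb <- idx[a$is_backbone[idx]]
  res_key <- paste(a$chain, a$res_num)
  nm <- a$atom_name
  list(
    N = bb[nm[bb] == "N"],
    O = bb[nm[bb] == "O"],
    C = bb[nm[bb] == "C"],
    H = bb[nm[bb] %in% c("H", "H1", "H2", "H3")],
    res = res_key, coords = frame$coords)
}

#' Count backbone hydrogen bonds between two segments
#'
#' Counts donor-acceptor pairs (backbone amide N to backbone carbonyl O,
#' both directions across the two segments) satisfying the geometric
#' criterion.
#'
#' @param frame a [frame()].
#' @param topology a [topology()].
#' @param seg_a,seg_b [select_atoms()] expressions for the two segments.
#' @param crit an [hbond_criterion()].
#' @return integer count.
#' @export
count_backbone_hbonds <- function(frame, topology, seg_a, seg_b,
                                  crit = hbond_criterion()) {
  ia <- suppressWarnings(resolve_selection(seg_a, topology))
  ib <- suppressWarnings(resolve_selection(seg_b, topology))
  A <- .bb_inventory(topology, frame, ia)
  B <- .bb_inventory(topology, frame, ib)
  if (length(A$N) + length(A$O) == 0L || length(B$N) + length(B$O) == 0L)
    stop("segment contains no backbone N or O atoms")
  .count_dir(A, B, topology, crit) + .count_dir(B, A, topology, crit)
}

# donors in D, acceptors in Acc
.count_dir <- function(D, Acc, topology, crit) {
  xyz <- D$coords
  res_of <- paste(topology$atoms$chain, topology$atoms$res_num)
  cnt <- 0L
  for (ni in D$N) {
    for (oi in Acc$O) {
      d <- sqrt(sum((xyz[ni, ] - xyz[oi, ])^2))
      if (d > crit$donor_acceptor_max) next
      if (crit$heavy_atom_only) {
        ci <- Acc$C[res_of[Acc$C] == res_of[oi]]
        if (length(ci) != 1L) next
        ang <- .angle_deg(xyz[ci, ] - xyz[oi, ], xyz[ni, ] - xyz[oi, ])
        if (ang >= crit$angle_min) cnt <- cnt + 1L
      } else {
        hs <- D$H[res_of[D$H] == res_of[ni]]
        ok <- FALSE
        for (hi in hs) {
          ang <- .angle_deg(xyz[ni, ] - xyz[hi, ], xyz[oi, ] - xyz[hi, ])
          if (ang >= crit$angle_min) { ok <- TRUE; break }
        }
        if (ok) cnt <- cnt + 1L
      }
    }
  }
  cnt
}

#' Named atom-pair distance series over a trajectory
#'
#' For a named single-atom pair (e.g. the F68 C-gamma to L156 C-gamma
#' distance of a linear-cis interface) replicated over equivalent
#' interfaces, returns the per-frame mean over the pairs plus per-pair time
#' means and SDs over a window.
#'
#' @param traj a [trajectory()].
#' @param res_a,res_b residue numbers of the two residues.
#' @param atom_a,atom_b atom names (e.g. `"CG"`, `"CA"`).
#' @param pairs list of `list(chain_a =, chain_b =)`, one per interface.
#' @param window window for the per-pair summaries (default all frames).
#' @return list with `time` (ns), `series` (per-frame mean, all frames),
#'   `per_frame` (frames x pairs matrix) and `per_pair` (data frame of
#'   window means and SDs).
#' @export
atom_pair_distance_series <- function(traj, res_a, atom_a, res_b, atom_b,
                                      pairs, window = NULL) {
  top <- traj$topology
  find_atom <- function(chain, res, name) {
    i <- which(top$atoms$chain == chain & top$atoms$res_num == res &
               top$atoms$atom_name == name)
    if (length(i) != 1L)
      stop("atom lookup failed: chain ", chain, " resnum ", res,
           " atom ", name)
    i
  }
  ia <- vapply(pairs, function(p) find_atom(p$chain_a, res_a, atom_a), integer(1))
  ib <- vapply(pairs, function(p) find_atom(p$chain_b, res_b, atom_b), integer(1))
  nfr <- n_frames(traj)
  per_frame <- matrix(NA_real_, nfr, length(pairs))
  for (fi in seq_len(nfr)) {
    xyz <- traj$frames[[fi]]$coords
    per_frame[fi, ] <- sqrt(rowSums((xyz[ia, , drop = FALSE] -
                                     xyz[ib, , drop = FALSE])^2))
  }
  widx <- resolve_window(window, nfr)
  per_pair <- data.frame(
    pair = vapply(pairs, function(p) paste0(p$chain_a, "-", p$chain_b),
                  character(1)),
    mean = colMeans(per_frame[widx, , drop = FALSE]),
    sd = apply(per_frame[widx, , drop = FALSE], 2, sd))
  list(time = traj$times, series = rowMeans(per_frame),
       per_frame = per_frame, per_pair = per_pair)
}

#' Side-chain charged-group heavy atoms of a residue type
#'
#' Atom names used to score electrostatic pair persistence: the terminal
#' charged-group heavy atoms of Arg/Lys/Asp/Glu side chains. With
#' `include_backbone = TRUE` the backbone O and N are added (for criteria
#' that admit main-chain interactions).
#'
#' @param res_name 3-letter residue name.
#' @param include_backbone include backbone O/N.
#' @return character vector of atom names.
#' @export
charged_group_atoms <- function(res_name, include_backbone = FALSE) {
  base <- switch(toupper(res_name),
                 ARG = c("NH1", "NH2", "NE"),
                 LYS = "NZ",
                 ASP = c("OD1", "OD2"),
                 GLU = c("OE1", "OE2"),
                 character(0))
  if (include_backbone) base <- c(base, "O", "N")
  base
}

#' Persistence-thresholded interacting pair count
#'
#' A pair "interacts" in a frame iff the minimum distance between the atoms
#' resolved by its two selections is at most `contact_max`. The persistence
#' fraction is the share of window frames in which the pair interacts; the
#' reported count is the number of pairs whose fraction strictly exceeds
#' `threshold`.
#'
#' @param traj a [trajectory()].
#' @param pairs list of `list(a = selection, b = selection, label = )`.
#' @param contact_max interaction cutoff, Angstrom (default 4).
#' @param threshold persistence fraction cutoff (strict >; default 0.35).
#' @param window frame window.
#' @return Object of class `persistence_result`: data frame `pairs` with
#'   per-pair fractions, `count_above_threshold`, `threshold`.
#' @export
persistent_pair_count <- function(traj, pairs, contact_max = 4.0,
                                  threshold = 0.35, window = NULL) {
  idx <- resolve_window(window, n_frames(traj))
  top <- traj$topology
  sides <- lapply(pairs, function(p)
    list(a = suppressWarnings(resolve_selection(p$a, top)),
         b = suppressWarnings(resolve_selection(p$b, top))))
  frac <- vapply(seq_along(pairs), function(k) {
    s <- sides[[k]]
    if (length(s$a) == 0L || length(s$b) == 0L) return(0)
    hits <- vapply(idx, function(fi) {
      fr <- traj$frames[[fi]]
      .min_cross_dist(fr$coords[s$a, , drop = FALSE],
                      fr$coords[s$b, , drop = FALSE]) <= contact_max
    }, logical(1))
    mean(hits)
  }, numeric(1))
  labels <- vapply(seq_along(pairs), function(k) {
    lb <- pairs[[k]]$label
    if (is.null(lb)) paste0("pair", k) else lb
  }, character(1))
  structure(list(
    pairs = data.frame(pair = labels, fraction_of_frames = frac,
                       counted = frac > threshold),
    count_above_threshold = sum(frac > threshold),
    threshold = threshold, contact_max = contact_max),
    class = "persistence_result")
}

# ---- SASA -------------------------------------------------------------------

# Deterministic Fibonacci-sphere lattice of n unit vectors.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom SASA by quadrature on a deterministic Fibonacci-sphere lattice:
#' area = (exposed points / n_points) x 4 pi (r_vdw + probe)^2. Atoms outside
#' the selection still occlude. Per-residue sums and side-chain-normalized
#' values (area divided by the residue's side-chain heavy-atom count) are
#' returned alongside.
#'
#' @param frame a [frame()].
#' @param topology a [topology()].
#' @param selection atoms to report areas for (occlusion uses all atoms).
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points quadrature points per atom (default 960; minimum 16).
#' @return Object of class `sasa_result`: `per_atom` and `per_residue` data
#'   frames, `total`, `probe_radius`, `n_points`.
#' @export
sasa <- function(frame, topology, selection = select_atoms(),
                 probe = 1.4, n_points = 960) {
  if (n_points < 16) stop("n_points must be at least 16")
  idx <- resolve_selection(selection, topology)
  if (length(idx) == 0L) stop("empty selection")
  xyz <- frame$coords
  rad <- topology$atoms$vdw + probe
  pts <- fibonacci_sphere(n_points)
  area <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    ri <- rad[i]
    # neighbours whose inflated spheres can intersect atom i's
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (ri + rad)^2 & seq_along(rad) != i)
    surf <- sweep(pts * ri, 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums(sweep(surf[exposed, , drop = FALSE], 2, xyz[j, ])^2)
      exposed[exposed] <- dj2 >= rad[j]^2
    }
    area[k] <- sum(exposed) / n_points * 4 * pi * ri^2
  }
  a <- topology$atoms[idx, , drop = FALSE]
  res_key <- paste0(a$chain, ":", a$res_name, a$res_num)
  per_res <- aggregate(area, list(residue = res_key), sum)
  names(per_res)[2] <- "area"
  # side-chain heavy-atom count per residue, from the full topology
  full <- topology$atoms
  full_key <- paste0(full$chain, ":", full$res_name, full$res_num)
  sc_heavy <- full$is_sidechain & toupper(full$element) != "H"
  cnt <- tapply(sc_heavy, full_key, sum)
  per_res$sidechain_heavy_atoms <- as.integer(cnt[per_res$residue])
  per_res$normalized_area <- ifelse(per_res$sidechain_heavy_atoms > 0,
                                    per_res$area / per_res$sidechain_heavy_atoms,
                                    NA_real_)
  structure(list(
    per_atom = data.frame(atom = idx, name = a$atom_name, residue = res_key,
                          area = area),
    per_residue = per_res, total = sum(area),
    probe_radius = probe, n_points = n_points),
    class = "sasa_result")
}

# ---- RMSD -------------------------------------------------------------------

# Kabsch least-squares rigid superposition of mobile onto fixed.
.kabsch <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  M <- sweep(mobile, 2, cm); F <- sweep(fixed, 2, cf)
  s <- svd(crossprod(M, F))
  d <- sign(det(tcrossprod(s$v, s$u)))
  Rm <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(M %*% t(Rm), 2, cf, "+")
}

#' Backbone RMSD over a trajectory
#'
#' Per-frame root-mean-square deviation of selected atoms from a reference
#' frame, after optimal least-squares rigid superposition (Kabsch) when
#' `superpose = TRUE`.
#'
#' @param traj a [trajectory()].
#' @param selection atoms entering the RMSD (e.g. backbone of the protein).
#' @param reference a [frame()]; defaults to the trajectory's first frame.
#' @param superpose superpose each frame onto the reference first.
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
backbone_rmsd <- function(traj, selection, reference = NULL,
                          superpose = TRUE) {
  idx <- resolve_selection(selection, traj$topology)
  if (length(idx) == 0L) stop("empty selection")
  if (superpose && length(idx) < 3L)
    stop("superposition requires at least 3 selected atoms")
  if (is.null(reference)) reference <- traj$frames[[1]]
  ref <- reference$coords[idx, , drop = FALSE]
  vapply(traj$frames, function(f) {
    mob <- f$coords[idx, , drop = FALSE]
    if (superpose) mob <- .kabsch(mob, ref)
    sqrt(mean(rowSums((mob - ref)^2)))
  }, numeric(1))
}
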