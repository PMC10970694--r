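#' @importFrom stats optim lm coef rnorm runif sd setNames aggregate
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom tools md5sum
NULL

# Backbone atom names for standard protein residues (heavy + amide/alpha H).
.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "H1", "H2", "H3", "HA")

# Bondi-style van der Waals radii (Angstrom) by element.
.vdw_table <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
  NA. = 2.27, CL = 1.75, K = 2.75, F = 1.47, BR = 1.85, I = 1.98,
  MG = 1.73, CA. = 2.31, ZN = 1.39
)

# Residue-level formal charges (elementary charges) at neutral pH;
# histidine neutral. Monatomic ion "residues" carry their ionic charge.
.residue_charge <- c(
  ARG = 1L, LYS = 1L, ASP = -1L, GLU = -1L, HIS = 0L,
  "NA" = 1L, CL = -1L, K = 1L, MG = 2L, CA = 2L, ZN = 2L
)

.ion_residues <- c("NA", "CL", "K", "MG", "CA", "ZN")

# Atom carrying the residue's formal charge (so per-residue sums of the
# per-atom column recover the residue charge on heavy-atom models).
.charge_carrier <- c(ARG = "CZ", LYS = "NZ", ASP = "CG", GLU = "CD")

.vdw_radius <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  key[key == "CA"] <- "CA."
  r <- unname(.vdw_table[key])
  if (anyNA(r)) {
    unknown <- unique(element[is.na(r)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default vdW radius 1.70 A", call. = FALSE)
    r[is.na(r)] <- 1.70
  }
  r
}

# Guess element symbol from a PDB atom name, with the residue name used to
# disambiguate monatomic ions (e.g. atom "NA" in residue "NA" is sodium,
# while atom "NA " in a protein would be nitrogen).
.element_from_name <- function(atom_name, res_name) {
  an <- toupper(trimws(atom_name))
  rn <- toupper(trimws(res_name))
  ion <- rn %in% c("NA", "CL", "K", "MG", "CA", "ZN", "BR", "I") & an == rn
  first <- sub("^[0-9]*", "", an)
  el <- substr(first, 1, 1)
  el[ion] <- rn[ion]
  el
}

#' Construct a topology
#'
#' A topology is the atom-level metadata shared by every frame of a
#' trajectory: identities, residue assignment, van der Waals radii and formal
#' charges. The row order of `atoms` is the canonical coordinate order.
#'
#' @param atoms data frame with columns `atom_id`, `atom_name`, `element`,
#'   `res_name`, `res_num`, `chain`; optional `vdw`, `is_backbone`,
#'   `is_sidechain`, `formal_charge` are filled from internal tables when
#'   absent.
#' @return An object of class `topology` with elements `atoms` (data frame)
#'   and `chains` (character vector in order of first appearance).
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom_id", "atom_name", "element", "res_name", "res_num", "chain")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty input: topology must contain at least one atom")
  atoms$atom_name <- trimws(atoms$atom_name)
  atoms$res_name <- trimws(atoms$res_name)
  key <- paste(atoms$chain, atoms$res_num, atoms$atom_name, sep = "|")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate atom (chain, residue number, atom name): ", dup)
  }
  if (is.null(atoms$vdw)) atoms$vdw <- .vdw_radius(atoms$element)
  if (any(atoms$vdw <= 0)) stop("vdw_radius must be > 0 for every atom")
  if (is.null(atoms$is_backbone))
    atoms$is_backbone <- atoms$atom_name %in% .backbone_atoms &
      !(toupper(atoms$res_name) %in% .ion_residues)
  if (is.null(atoms$is_sidechain))
    atoms$is_sidechain <- !atoms$is_backbone
  if (is.null(atoms$formal_charge)) {
    rn <- toupper(atoms$res_name)
    fc <- integer(nrow(atoms))
    carrier <- .charge_carrier[rn]
    rescharge <- .residue_charge[rn]
    # monatomic ion residues: charge on their single atom
    ion <- rn %in% .ion_residues
    fc[ion] <- rescharge[ion]
    hit <- !is.na(carrier) & atoms$atom_name == carrier
    fc[hit] <- rescharge[hit]
    atoms$formal_charge <- fc
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, chains = unique(atoms$chain)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$res_num))), "residues,",
      length(x$chains), "chain(s)\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Construct a single coordinate frame
#'
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param time frame time in ns.
#' @param box optional orthorhombic box lengths (3 values, Angstrom).
#' @return Object of class `frame`.
#' @export
frame <- function(coords, time = 0, box = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  if (!is.null(box)) stopifnot(length(box) == 3L, all(box > 0))
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(time = time, coords = coords, box = box), class = "frame")
}

#' Construct a trajectory
#'
#' Frame times must be strictly increasing with a uniform stride
#' (tolerance 1e-6 ns), because downstream statistics weight frames equally.
#'
#' @param topology a [topology()].
#' @param frames list of [frame()] objects, each with as many coordinate rows
#'   as the topology has atoms.
#' @param wrap optional cumulative wrap-count matrix (frames x atoms) from a
#'   periodic generator, together with `wrap_period`, used to reconstruct
#'   unwrapped axial coordinates.
#' @param wrap_period period (Angstrom) associated with `wrap`.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, wrap = NULL, wrap_period = NULL) {
  stopifnot(inherits(topology, "topology"), is.list(frames), length(frames) >= 1L)
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    if (!inherits(frames[[i]], "frame")) stop("frames must be frame objects")
    if (nrow(frames[[i]]$coords) != na)
      stop("shape error: frame ", i, " has ", nrow(frames[[i]]$coords),
           " atoms, topology has ", na)
  }
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("frame times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6)
      stop("non-uniform frame times (stride tolerance 1e-6 ns)")
  }
  if (!is.null(wrap)) {
    stopifnot(nrow(wrap) == length(frames), ncol(wrap) == na,
              is.numeric(wrap_period), wrap_period > 0)
  }
  structure(list(topology = topology, frames = frames, times = times,
                 stride = if (length(times) > 1L) mean(diff(times)) else NA_real_,
                 wrap = wrap, wrap_period = wrap_period),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory:", length(x$frames), "frames x", n_atoms(x$topology),
      "atoms; stride", format(x$stride), "ns\n")
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

#' Coordinate matrix of one frame
#' @param traj a [trajectory()].
#' @param i frame index (1-based).
#' @return numeric matrix n_atoms x 3.
#' @export
frame_coords <- function(traj, i) traj$frames[[i]]$coords

#' Resolve a frame-window specification
#'
#' Windows select the frames a statistic averages over. Accepted forms:
#' `NULL` (all frames), an integer vector of frame indices, `"last:f"` for the
#' trailing fraction `f` of frames (e.g. `"last:0.5"`), or `"frames:A:B"` for
#' the half-open 0-based range \[A, B).
#'
#' @param window window specification.
#' @param n number of frames in the trajectory.
#' @return sorted integer vector of 1-based frame indices.
#' @export
resolve_window <- function(window, n) {
  if (is.null(window)) return(seq_len(n))
  if (is.numeric(window)) {
    idx <- sort(unique(as.integer(window)))
    if (length(idx) == 0L) stop("empty window")
    if (any(idx < 1L | idx > n)) stop("window indices out of range 1..", n)
    return(idx)
  }
  if (is.character(window) && length(window) == 1L) {
    if (startsWith(window, "last:")) {
      f <- as.numeric(sub("^last:", "", window))
      if (!is.finite(f) || f <= 0 || f > 1) stop("invalid window fraction: ", window)
      k <- max(1L, ceiling(f * n))
      return(seq.int(n - k + 1L, n))
    }
    if (startsWith(window, "frames:")) {
      ab <- strsplit(sub("^frames:", "", window), ":", fixed = TRUE)[[1]]
      a <- as.integer(ab[1]); b <- as.integer(ab[2])
      if (is.na(a) || is.na(b) || a < 0L || b <= a || b > n)
        stop("invalid frame range: ", window)
      return(seq.int(a + 1L, b))
    }
  }
  stop("unrecognized window specification")
}

# ---- selections -------------------------------------------------------------

#' Build an atom selection expression
#'
#' A selection is a conjunction of predicates over topology columns; `NULL`
#' (or `NA` for the logical flags) leaves a predicate unconstrained.
#' Selections are pure functions of (expression, topology): resolving the
#' same selection twice yields the same sorted index vector.
#'
#' @param chain chain identifiers to keep.
#' @param res_num residue numbers to keep (vector; use `a:b` for ranges).
#' @param res_name residue names to keep.
#' @param atom_name atom names to keep.
#' @param element element symbols to keep.
#' @param backbone if `TRUE`/`FALSE`, require/exclude backbone atoms.
#' @param sidechain if `TRUE`/`FALSE`, require/exclude side-chain atoms.
#' @return Object of class `selection`.
#' @export
select_atoms <- function(chain = NULL, res_num = NULL, res_name = NULL,
                         atom_name = NULL, element = NULL,
                         backbone = NA, sidechain = NA) {
  structure(list(chain = chain, res_num = res_num, res_name = res_name,
                 atom_name = atom_name, element = element,
                 backbone = backbone, sidechain = sidechain),
            class = "selection")
}

#' Resolve a selection against a topology
#'
#' @param sel a [select_atoms()] expression.
#' @param topology a [topology()].
#' @return Sorted integer vector of atom indices (rows of `topology$atoms`).
#'   An empty match returns `integer(0)` with attribute `empty = TRUE` and a
#'   warning, not an error.
#' @export
resolve_selection <- function(sel, topology) {
  stopifnot(inherits(sel, "selection"), inherits(topology, "topology"))
  a <- topology$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(sel$chain))     keep <- keep & a$chain %in% sel$chain
  if (!is.null(sel$res_num))   keep <- keep & a$res_num %in% sel$res_num
  if (!is.null(sel$res_name))  keep <- keep & a$res_name %in% sel$res_name
  if (!is.null(sel$atom_name)) keep <- keep & a$atom_name %in% sel$atom_name
  if (!is.null(sel$element))   keep <- keep & toupper(a$element) %in% toupper(sel$element)
  if (!is.na(sel$backbone))    keep <- keep & (a$is_backbone == sel$backbone)
  if (!is.na(sel$sidechain))   keep <- keep & (a$is_sidechain == sel$sidechain)
  idx <- which(keep)
  if (length(idx) == 0L) {
    warning("selection matched zero atoms", call. = FALSE)
    attr(idx, "empty") <- TRUE
  }
  idx
}

# ---- PDB reading/writing ----------------------------------------------------

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_lines <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_lines) == 0L)
    stop("empty input: no ATOM/HETATM records found")
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("format error at line ", i, ": ATOM/HETATM record shorter than 54 columns")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("format error at line ", i, ": non-numeric coordinate field")
  }
  invisible(atom_lines)
}

#' Read a structure from a PDB file
#'
#' Reads ATOM/HETATM records (wwPDB v3.3 columns) into a [topology()] plus a
#' single [frame()]. Van der Waals radii and formal charges are assigned from
#' internal element/residue tables. altLoc codes other than '' or 'A' are
#' dropped with a warning. For multi-MODEL files only the first model's
#' coordinates are returned; use [read_trajectory()] for all models.
#'
#' @param path PDB file path.
#' @return `list(topology =, frame =)`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atom <- pdb$atom
  alt_bad <- !(is.na(atom$alt) | atom$alt %in% c("", "A"))
  if (any(alt_bad)) {
    warning("dropping ", sum(alt_bad), " atom(s) with altLoc other than ''/'A'",
            call. = FALSE)
    atom <- atom[!alt_bad, , drop = FALSE]
  }
  if (nrow(atom) == 0L) stop("empty input: no atoms after altLoc filtering")
  chain <- atom$chain
  chain[is.na(chain)] <- ""
  element <- atom$elesy
  blank <- is.na(element) | trimws(element) == ""
  element[blank] <- .element_from_name(atom$elety[blank], atom$resid[blank])
  element <- trimws(element)
  top <- topology(data.frame(
    atom_id = atom$eleno, atom_name = atom$elety, element = element,
    res_name = atom$resid, res_num = atom$resno, chain = chain,
    stringsAsFactors = FALSE))
  coords <- cbind(atom$x, atom$y, atom$z)
  list(topology = top, frame = frame(coords))
}

#' Write a structure (or trajectory frames) to a PDB file
#'
#' @param topology a [topology()].
#' @param frames a single [frame()] or list of frames; more than one frame is
#'   written as a multi-MODEL file.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, frames, path) {
  if (inherits(frames, "frame")) frames <- list(frames)
  na <- n_atoms(topology)
  xyz <- do.call(rbind, lapply(frames, function(f) as.vector(t(f$coords))))
  a <- topology$atoms
  bio3d::write.pdb(file = path, xyz = xyz,
                   eleno = a$atom_id, elety = a$atom_name,
                   resid = a$res_name, resno = a$res_num,
                   chain = ifelse(a$chain == "", " ", a$chain))
  invisible(path)
}

#' Read a trajectory
#'
#' Two formats are supported: a multi-MODEL PDB file (topology taken from the
#' file; `topology` argument optional), or the package's internal frame-table
#' CSV with header `frame,time_ns,atom_id,x,y,z`, one row per atom per frame
#' (requires `topology`).
#'
#' @param path input file.
#' @param topology required for frame-table input; optional for PDB.
#' @param stride_ns frame spacing in ns used to assign times to PDB models
#'   (default 1).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, topology = NULL, stride_ns = 1) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^\"?frame\"?\\s*,", first)) {
    if (is.null(topology)) stop("frame-table input requires a topology")
    tab <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("frame", "time_ns", "atom_id", "x", "y", "z")
    if (!all(need %in% names(tab))) stop("frame-table missing required columns")
    na <- n_atoms(topology)
    ids <- topology$atoms$atom_id
    frames <- lapply(split(tab, tab$frame), function(ft) {
      fi <- ft$frame[1]
      if (nrow(ft) != na)
        stop("shape error: frame ", fi, " has ", nrow(ft),
             " atoms, topology has ", na)
      ord <- match(ids, ft$atom_id)
      if (anyNA(ord)) stop("shape error: frame ", fi, " is missing atom ids")
      frame(cbind(ft$x, ft$y, ft$z)[ord, , drop = FALSE], time = ft$time_ns[1])
    })
    frames <- frames[order(vapply(frames, function(f) f$time, numeric(1)))]
    return(trajectory(topology, unname(frames)))
  }
  # multi-model PDB
  .validate_pdb_lines(readLines(path, warn = FALSE))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  if (is.null(topology)) topology <- read_structure(path)$topology
  nm <- nrow(pdb$xyz)
  na <- n_atoms(topology)
  if (ncol(pdb$xyz) != 3L * na)
    stop("shape error: model atom count ", ncol(pdb$xyz) / 3,
         " does not match topology (", na, ")")
  frames <- lapply(seq_len(nm), function(i)
    frame(matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE),
          time = (i - 1) * stride_ns))
  trajectory(topology, frames)
}

#' Write a trajectory to the internal frame-table CSV format
#'
#' Plain-text CSV with header `frame,time_ns,atom_id,x,y,z`; coordinates are
#' printed at 6 decimals, which round-trips bit-exactly through
#' [read_trajectory()].
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param atoms optional atom indices to write (default all).
#' @return `path`, invisibly.
#' @export
write_frame_table <- function(traj, path, atoms = NULL) {
  if (is.null(atoms)) atoms <- seq_len(n_atoms(traj$topology))
  ids <- traj$topology$atoms$atom_id[atoms]
  rows <- lapply(seq_len(n_frames(traj)), function(i) {
    xyz <- round(traj$frames[[i]]$coords[atoms, , drop = FALSE], 6)
    data.frame(frame = i, time_ns = traj$times[i], atom_id = ids,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Unwrapped axial (x) coordinates for selected atoms
#'
#' Reconstructs continuous x-coordinates across periodic boundaries, either
#' from explicit wrap bookkeeping carried by a synthetic trajectory or by
#' minimum-image continuity between consecutive frames when the frames carry a
#' box. Without either, coordinates are returned as stored.
#'
#' @param traj a [trajectory()].
#' @param atoms atom indices.
#' @return numeric matrix n_frames x length(atoms) of unwrapped x.
#' @export
unwrapped_x <- function(traj, atoms) {
  x <- vapply(traj$frames, function(f) f$coords[atoms, 1], numeric(length(atoms)))
  x <- matrix(x, nrow = length(atoms))  # atoms x frames
  if (!is.null(traj$wrap)) {
    w <- t(traj$wrap[, atoms, drop = FALSE])
    x <- x + w * traj$wrap_period
  } else if (!is.null(traj$frames[[1]]$box)) {
    bx <- traj$frames[[1]]$box[1]
    for (j in seq_len(ncol(x))[-1]) {
      dx <- x[, j] - x[, j - 1]
      x[, j] <- x[, j - 1] + dx - bx * round(dx / bx)
    }
  }
  t(x)
}
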