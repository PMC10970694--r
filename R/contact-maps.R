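# Residue-residue contact-map fingerprints: mean closest-atom distances
# between two residue ranges, averaged over the equivalent interfaces of an
# oligomer and over a trajectory window. The per-interface averaging follows
# the way symmetric subunit interfaces are pooled in oligomeric channel
# models: each (frame x interface) sample contributes equally.

#' Define an interface group
#'
#' Names a set of equivalent residue-range pairs across subunits (e.g. the
#' multiple copies of a cis-interface in an oligomer). Each pair is a
#' `list(a =, b =)` of [select_atoms()] expressions restricting one side each
#' (typically by chain); the two residue-number ranges define the map axes.
#'
#' @param name label.
#' @param pairs list of `list(a = selection, b = selection)`.
#' @param range_a,range_b integer vectors of residue numbers for the rows
#'   (side a) and columns (side b) of the map.
#' @return Object of class `interface_group`.
#' @export
interface_group <- function(name, pairs, range_a, range_b) {
  stopifnot(length(pairs) >= 1L)
  for (p in pairs) stopifnot(inherits(p$a, "selection"), inherits(p$b, "selection"))
  structure(list(name = name, pairs = pairs,
                 range_a = as.integer(range_a), range_b = as.integer(range_b)),
            class = "interface_group")
}

# atom indices of one residue within a side-selection
.residue_atoms <- function(topology, side_idx, res) {
  side_idx[topology$atoms$res_num[side_idx] == res]
}

#' Minimum inter-residue atom distance in one frame
#'
#' The closest-atoms distance between two residues: the minimum over all
#' atom pairs of the Euclidean distance. All atoms present in the topology
#' for the residue (including hydrogens, if any) participate.
#'
#' @param frame a [frame()].
#' @param topology a [topology()].
#' @param res_a,res_b residue references: `list(chain =, res_num =)`.
#' @return distance in Angstrom.
#' @export
min_residue_distance <- function(frame, topology, res_a, res_b) {
  ia <- which(topology$atoms$chain == res_a$chain &
              topology$atoms$res_num == res_a$res_num)
  ib <- which(topology$atoms$chain == res_b$chain &
              topology$atoms$res_num == res_b$res_num)
  if (length(ia) == 0L)
    stop("residue not found: chain ", res_a$chain, " resnum ", res_a$res_num)
  if (length(ib) == 0L)
    stop("residue not found: chain ", res_b$chain, " resnum ", res_b$res_num)
  .min_cross_dist(frame$coords[ia, , drop = FALSE],
                  frame$coords[ib, , drop = FALSE])
}

# minimum distance between two coordinate sets
.min_cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(min(d2), 0))
}

#' Residue contact map averaged over frames and interfaces
#'
#' Entry (i, j) is the mean, over the window frames and over every pair in
#' the group, of the closest-atoms distance between residue `range_a[i]` on
#' side a and residue `range_b[j]` on side b. Averaging is a single flat
#' mean over (frame x interface) samples. Residues missing from a given
#' interface simply do not contribute (tracked in `n_samples`).
#'
#' @param traj a [trajectory()].
#' @param group an [interface_group()].
#' @param window frame window (see [resolve_window()]); default all frames.
#' @return Object of class `contact_map`: `row_residues`, `col_residues`,
#'   `mean_distance` (matrix, Angstrom), `n_samples` (matrix).
#' @export
contact_map <- function(traj, group, window = NULL) {
  idx <- resolve_window(window, n_frames(traj))
  top <- traj$topology
  nr <- length(group$range_a); nc <- length(group$range_b)
  acc <- matrix(0, nr, nc)
  nsmp <- matrix(0L, nr, nc)
  sides <- lapply(group$pairs, function(p)
    list(a = suppressWarnings(resolve_selection(p$a, top)),
         b = suppressWarnings(resolve_selection(p$b, top))))
  for (fi in idx) {
    fr <- traj$frames[[fi]]
    for (s in sides) {
      for (i in seq_len(nr)) {
        ia <- .residue_atoms(top, s$a, group$range_a[i])
        if (length(ia) == 0L) next
        A <- fr$coords[ia, , drop = FALSE]
        for (j in seq_len(nc)) {
          ib <- .residue_atoms(top, s$b, group$range_b[j])
          if (length(ib) == 0L) next
          acc[i, j] <- acc[i, j] +
            .min_cross_dist(A, fr$coords[ib, , drop = FALSE])
          nsmp[i, j] <- nsmp[i, j] + 1L
        }
      }
    }
  }
  mean_d <- acc / ifelse(nsmp > 0L, nsmp, NA_integer_)
  rn <- .residue_labels(top, group$pairs[[1]]$a, group$range_a)
  cn <- .residue_labels(top, group$pairs[[1]]$b, group$range_b)
  dimnames(mean_d) <- dimnames(nsmp) <- list(rn, cn)
  structure(list(row_residues = rn, col_residues = cn,
                 mean_distance = mean_d, n_samples = nsmp,
                 name = group$name),
            class = "contact_map")
}

# "F68"-style labels: residue one-letter/name + number, from the first pair
.residue_labels <- function(topology, sel, range) {
  idx <- suppressWarnings(resolve_selection(sel, topology))
  vapply(range, function(r) {
    at <- .residue_atoms(topology, idx, r)
    if (length(at) == 0L) return(as.character(r))
    paste0(.one_letter(topology$atoms$res_name[at[1]]), r)
  }, character(1))
}

.aa3to1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

.one_letter <- function(res_name) {
  out <- .aa3to1[toupper(res_name)]
  ifelse(is.na(out), res_name, unname(out))
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact map", if (nzchar(x$name)) paste0("'", x$name, "'"), ":",
      length(x$row_residues), "x", length(x$col_residues), "residues\n")
  print(round(x$mean_distance, 2))
  invisible(x)
}

#' Classify contacts in a contact map
#'
#' @param map a [contact_map()].
#' @param threshold contact cutoff in Angstrom; an entry is a contact iff
#'   its mean distance is strictly below the threshold (default 5).
#' @return logical matrix of the map's shape.
#' @export
classify_contacts <- function(map, threshold = 5.0) {
  stopifnot(inherits(map, "contact_map"))
  map$mean_distance < threshold
}

#' Write a contact map to CSV
#'
#' Rows/columns carry `RESNAME+number` labels (e.g. `F68`).
#'
#' @param map a [contact_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  df <- as.data.frame(round(map$mean_distance, 4))
  df <- cbind(residue = map$row_residues, df)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
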