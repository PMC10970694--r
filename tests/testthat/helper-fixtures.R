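# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

# minimal topology from parallel vectors
fix_topology <- function(atom_name, res_name, res_num, chain,
                         element = "C", vdw = NULL) {
  df <- data.frame(atom_id = seq_along(atom_name), atom_name = atom_name,
                   element = element, res_name = res_name, res_num = res_num,
                   chain = chain, stringsAsFactors = FALSE)
  if (!is.null(vdw)) df$vdw <- vdw
  topology(df)
}

# idealised extended peptide chain: N, CA, C, O per residue, 3.8 A per
# residue along +x, at a given y/z offset
fix_peptide_chain <- function(chain, n_res, origin = c(0, 0, 0),
                              res_name = "ALA") {
  names4 <- c("N", "CA", "C", "O")
  offs <- rbind(c(0.0, 0.0, 0), c(1.2, 0.6, 0), c(2.4, 0.0, 0),
                c(2.4, -1.2, 0))
  atoms <- data.frame(
    atom_name = rep(names4, n_res),
    res_name = res_name,
    res_num = rep(seq_len(n_res), each = 4L),
    chain = chain, stringsAsFactors = FALSE)
  coords <- do.call(rbind, lapply(seq_len(n_res), function(i)
    sweep(offs, 2, origin + c((i - 1) * 3.8, 0, 0), "+")))
  list(atoms = atoms, coords = coords)
}

fix_peptide_topology <- function(chains, n_res, origins = NULL) {
  if (is.null(origins)) origins <- lapply(seq_along(chains), function(i)
    c(0, (i - 1) * 10, 0))
  parts <- Map(fix_peptide_chain, chains, n_res, origins)
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$element <- substr(atoms$atom_name, 1, 1)
  list(topology = topology(atoms),
       frame = frame(do.call(rbind, lapply(parts, `[[`, "coords"))))
}

# random multi-chain oligomer with a few atoms per residue, plus a short
# random trajectory around the start coordinates
fix_random_oligomer <- function(n_chains = 5, n_res = 10, atoms_per_res = 3,
                                n_frames = 5, seed = 1, spread = 8) {
  set.seed(seed)
  chains <- LETTERS[seq_len(n_chains)]
  anames <- c("CA", "CB", "CG")[seq_len(atoms_per_res)]
  atoms <- expand.grid(atom_name = anames, res_num = seq_len(n_res),
                       chain = chains, stringsAsFactors = FALSE)
  atoms <- data.frame(atom_id = seq_len(nrow(atoms)),
                      atom_name = atoms$atom_name, element = "C",
                      res_name = "ALA", res_num = atoms$res_num,
                      chain = atoms$chain, stringsAsFactors = FALSE)
  top <- topology(atoms)
  base <- matrix(rnorm(nrow(atoms) * 3, sd = spread), ncol = 3)
  frames <- lapply(seq_len(n_frames), function(i)
    frame(base + matrix(rnorm(nrow(atoms) * 3, sd = 0.5), ncol = 3),
          time = i - 1))
  trajectory(top, frames)
}

# a trajectory holding given per-frame coordinates for a fixed topology
fix_traj <- function(top, coord_list) {
  trajectory(top, lapply(seq_along(coord_list), function(i)
    frame(coord_list[[i]], time = i - 1)))
}

# marker scaffold + hand-placed ions: BNK tetrad at x = 0, ENT corner
# markers at x = +-xe spanning +-(w) in y/z, then one frame per row of each
# ion's coordinate matrix
fix_marker_traj <- function(ion_xyz_list, species = "CL", xe = 10, w = 5) {
  ion_xyz_list <- lapply(ion_xyz_list, function(m) matrix(m, ncol = 3))
  n_ions <- nrow(ion_xyz_list[[1]])
  bnk <- rbind(c(0, 1, 1), c(0, -1, 1), c(0, 1, -1), c(0, -1, -1))
  ent <- rbind(c(-xe, w, 0), c(-xe, -w, 0), c(-xe, 0, w), c(-xe, 0, -w),
               c(xe, w, 0), c(xe, -w, 0), c(xe, 0, w), c(xe, 0, -w))
  top <- fix_topology(
    atom_name = c(rep("CA", 12), rep(species, n_ions)),
    res_name = c(rep("BNK", 4), rep("ENT", 8), rep(species, n_ions)),
    res_num = c(1:12, seq_len(n_ions)),
    chain = c(rep("P", 12), rep("I", n_ions)),
    element = c(rep("C", 12), rep(species, n_ions)))
  fix_traj(top, lapply(ion_xyz_list, function(xyz)
    rbind(bnk, ent, matrix(xyz, ncol = 3))))
}

# trajectory realizing a given logical contact pattern (pairs x frames):
# each pair sits at 3 A when "interacting", 8 A otherwise
persistence_fixture <- function(pattern) {
  k <- nrow(pattern); nf <- ncol(pattern)
  top <- fix_topology(
    atom_name = rep(c("NZ", "OE1"), k), res_name = rep(c("LYS", "GLU"), k),
    res_num = rep(seq_len(k), each = 2), chain = rep(c("A", "B"), k),
    element = rep(c("N", "O"), k))
  coords <- lapply(seq_len(nf), function(fi) {
    do.call(rbind, lapply(seq_len(k), function(p) {
      y <- 100 * p
      d <- if (pattern[p, fi]) 3.0 else 8.0
      rbind(c(0, y, 0), c(d, y, 0))
    }))
  })
  pairs <- lapply(seq_len(k), function(p)
    list(a = select_atoms(chain = "A", res_num = p, atom_name = "NZ"),
         b = select_atoms(chain = "B", res_num = p, atom_name = "OE1"),
         label = paste0("K", p, "-E", p)))
  list(traj = fix_traj(top, coords), pairs = pairs)
}

# text of a tiny hand-written PDB file
fix_pdb_lines <- function(n = 1) {
  hdr <- sprintf(
    "ATOM  %5d  CA  ALA A%4d       0.000   0.000   0.000  1.00  0.00           C",
    seq_len(n), seq_len(n))
  c(hdr, "END")
}
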