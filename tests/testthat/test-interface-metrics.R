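# helper: a two-segment topology from explicit per-atom tables
hb_fixture <- function(a_atoms, b_atoms) {
  atoms <- rbind(
    data.frame(atom_name = a_atoms$name, chain = "A", res_num = a_atoms$res),
    data.frame(atom_name = b_atoms$name, chain = "B", res_num = b_atoms$res))
  top <- fix_topology(atom_name = atoms$atom_name, res_name = "GLY",
                      res_num = atoms$res_num, chain = atoms$chain,
                      element = substr(atoms$atom_name, 1, 1))
  list(top = top, fr = frame(rbind(a_atoms$xyz, b_atoms$xyz)),
       sa = select_atoms(chain = "A"), sb = select_atoms(chain = "B"))
}

# independent reimplementation of the heavy-atom criterion
oracle_hbond_count <- function(top, xyz, dmax = 3.5, amin = 100) {
  a <- top$atoms
  cnt <- 0L
  for (dir in 1:2) {
    don <- if (dir == 1) "A" else "B"
    acc <- if (dir == 1) "B" else "A"
    Ns <- which(a$chain == don & a$atom_name == "N")
    Os <- which(a$chain == acc & a$atom_name == "O")
    for (ni in Ns) for (oi in Os) {
      ci <- which(a$chain == acc & a$res_num == a$res_num[oi] &
                  a$atom_name == "C")
      if (length(ci) != 1) next
      d <- sqrt(sum((xyz[ni, ] - xyz[oi, ])^2))
      v1 <- xyz[ci, ] - xyz[oi, ]; v2 <- xyz[ni, ] - xyz[oi, ]
      ang <- acos(min(max(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
      if (d <= dmax && ang >= amin) cnt <- cnt + 1L
    }
  }
  cnt
}

test_that("an ideal collinear amide-carbonyl pair counts as one hydrogen bond", {
  fx <- hb_fixture(
    list(name = c("N", "CA", "C", "O"), res = 1L,
         xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.5, 5, 5), c(2.5, 6, 5))),
    list(name = c("N", "CA", "C", "O"), res = 1L,
         xyz = rbind(c(20, 0, 0), c(21, 0, 0), c(0, 0, 4.5), c(0, 0, 2.9))))
  expect_equal(count_backbone_hbonds(fx$fr, fx$top, fx$sa, fx$sb), 1L)
  # segments far apart -> none
  fx2 <- hb_fixture(
    list(name = c("N", "CA", "C", "O"), res = 1L,
         xyz = rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.5, 1, 0), c(2.5, 2, 0))),
    list(name = c("N", "CA", "C", "O"), res = 1L,
         xyz = rbind(c(0, 20, 0), c(1.5, 20, 0), c(2.5, 21, 0), c(2.5, 22, 0))))
  expect_equal(count_backbone_hbonds(fx2$fr, fx2$top, fx2$sa, fx2$sb), 0L)
})

test_that("explicit-hydrogen criterion scores the D-H...A geometry", {
  fx <- hb_fixture(
    list(name = c("N", "H", "CA"), res = 1L,
         xyz = rbind(c(0, 0, 0), c(0, 0, 1), c(-1.5, 0, 0))),
    list(name = c("O", "C", "CA"), res = 1L,
         xyz = rbind(c(0, 0, 2.9), c(0, 1.0, 3.4), c(0, 2.2, 3.4))))
  crit <- hbond_criterion(heavy_atom_only = FALSE)
  expect_equal(count_backbone_hbonds(fx$fr, fx$top, fx$sa, fx$sb, crit), 1L)
  # bent D-H...A (< 120 degrees) is rejected
  fxb <- hb_fixture(
    list(name = c("N", "H", "CA"), res = 1L,
         xyz = rbind(c(0, 0, 0), c(0, 0, 1), c(-1.5, 0, 0))),
    list(name = c("O", "C", "CA"), res = 1L,
         xyz = rbind(c(0, 2.9, 0.8), c(0, 3.9, 1.3), c(0, 5.1, 1.3))))
  expect_equal(count_backbone_hbonds(fxb$fr, fxb$top, fxb$sa, fxb$sb, crit), 0L)
})

test_that("hydrogen-bond counts match exhaustive enumeration on random strands", {
  set.seed(41)
  for (k in 1:50) {
    n_res <- 3
    mk <- function(res0, base) {
      xyz <- base + matrix(runif(n_res * 4 * 3, 0, 6), ncol = 3)
      list(name = rep(c("N", "CA", "C", "O"), n_res),
           res = rep(seq_len(n_res), each = 4), xyz = xyz)
    }
    fx <- hb_fixture(mk(1, 0), mk(1, 2))
    expect_equal(count_backbone_hbonds(fx$fr, fx$top, fx$sa, fx$sb),
                 oracle_hbond_count(fx$top, fx$fr$coords))
  }
})

test_that("hydrogen-bond counts are invariant under rigid motion", {
  set.seed(13)
  fx <- hb_fixture(
    list(name = rep(c("N", "CA", "C", "O"), 2), res = rep(1:2, each = 4),
         xyz = matrix(runif(24, 0, 5), ncol = 3)),
    list(name = rep(c("N", "CA", "C", "O"), 2), res = rep(1:2, each = 4),
         xyz = matrix(runif(24, 0, 5), ncol = 3)))
  base <- count_backbone_hbonds(fx$fr, fx$top, fx$sa, fx$sb)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- frame(sweep(fx$fr$coords %*% t(R), 2, c(5, -3, 11), "+"))
  expect_equal(count_backbone_hbonds(moved, fx$top, fx$sa, fx$sb), base)
})

test_that("atom-pair distance series reduce correctly over pairs and time", {
  top <- fix_topology(atom_name = rep("CG", 4), res_name = "PHE",
                      res_num = rep(68L, 4), chain = c("A", "B", "C", "D"))
  # pair A-B constant at 7.7; pair C-D constant at 6 then 8 is a second case
  co <- rbind(c(0, 0, 0), c(7.7, 0, 0), c(0, 50, 0), c(6, 50, 0))
  traj <- fix_traj(top, rep(list(co), 10))
  r <- atom_pair_distance_series(traj, 68, "CG", 68, "CG",
                                 list(list(chain_a = "A", chain_b = "B")))
  expect_equal(r$series, rep(7.7, 10))
  expect_equal(r$per_pair$mean, 7.7)
  expect_equal(r$per_pair$sd, 0)
  r2 <- atom_pair_distance_series(traj, 68, "CG", 68, "CG",
                                  list(list(chain_a = "A", chain_b = "B"),
                                       list(chain_a = "C", chain_b = "D")))
  expect_equal(unique(r2$series), mean(c(7.7, 6)))
  expect_error(
    atom_pair_distance_series(traj, 68, "CZ", 68, "CG",
                              list(list(chain_a = "A", chain_b = "B"))),
    "lookup")
})

test_that("distance series equal direct recomputation on random-walk coordinates", {
  set.seed(99)
  top <- fix_topology(atom_name = rep("CA", 2), res_name = "GLY",
                      res_num = c(1L, 1L), chain = c("A", "B"))
  coords <- list(matrix(rnorm(6), 2))
  for (i in 2:20) coords[[i]] <- coords[[i - 1]] + matrix(rnorm(6, sd = 0.3), 2)
  traj <- fix_traj(top, coords)
  r <- atom_pair_distance_series(traj, 1, "CA", 1, "CA",
                                 list(list(chain_a = "A", chain_b = "B")))
  direct <- vapply(coords, function(m) sqrt(sum((m[1, ] - m[2, ])^2)),
                   numeric(1))
  expect_equal(r$series, direct, tolerance = 1e-9)
})

test_that("persistence fractions and the strict 35% threshold behave as defined", {
  fx <- persistence_fixture(matrix(c(rep(TRUE, 8), rep(FALSE, 12),  # 40%
                                     rep(TRUE, 7), rep(FALSE, 13)), # 35%
                                   nrow = 2, byrow = TRUE, ncol = 20))
  r <- persistent_pair_count(fx$traj, fx$pairs)
  expect_equal(r$pairs$fraction_of_frames, c(0.40, 0.35))
  expect_identical(r$pairs$counted, c(TRUE, FALSE))
  expect_equal(r$count_above_threshold, 1L)
})

test_that("persistence counting matches direct counting on random patterns", {
  set.seed(66)
  for (k in 1:10) {
    pat <- matrix(runif(4 * 12) < 0.4, nrow = 4)
    fx <- persistence_fixture(pat)
    r <- persistent_pair_count(fx$traj, fx$pairs)
    expect_equal(r$pairs$fraction_of_frames, rowMeans(pat))
    expect_equal(r$count_above_threshold, sum(rowMeans(pat) > 0.35))
  }
})

test_that("persistence fractions are invariant under frame reordering", {
  pat <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE), nrow = 1)
  fx1 <- persistence_fixture(pat)
  fx2 <- persistence_fixture(pat[, c(4, 2, 6, 1, 3, 5), drop = FALSE])
  expect_equal(persistent_pair_count(fx1$traj, fx1$pairs)$pairs$fraction_of_frames,
               persistent_pair_count(fx2$traj, fx2$pairs)$pairs$fraction_of_frames)
})

test_that("charged-group atom tables cover the four charged residue types", {
  expect_setequal(charged_group_atoms("ARG"), c("NH1", "NH2", "NE"))
  expect_equal(charged_group_atoms("LYS"), "NZ")
  expect_true(all(c("O", "N") %in% charged_group_atoms("GLU", TRUE)))
  expect_length(charged_group_atoms("ALA"), 0L)
})

# ---- SASA -------------------------------------------------------------------

test_that("an isolated atom recovers the analytic sphere area", {
  top <- fix_topology("X", "UNK", 1L, "A", element = "C", vdw = 1.9)
  s <- sasa(frame(matrix(0, 1, 3)), top)
  expect_lt(abs(s$total - 4 * pi * 3.3^2) / (4 * pi * 3.3^2), 0.01)
})

test_that("a fully enclosed atom has essentially no accessible area", {
  shell <- parapore:::fibonacci_sphere(80) * 2.0
  top <- fix_topology(atom_name = paste0("S", 0:80), res_name = "UNK",
                      res_num = 0:80, chain = "A", element = "C",
                      vdw = rep(1.5, 81))
  fr <- frame(rbind(c(0, 0, 0), shell))
  s <- sasa(fr, top, select_atoms(res_num = 0L))
  expect_lt(s$per_atom$area, 1)
})

test_that("two-sphere areas match the spherical-cap closed form within 2%", {
  probe <- 1.4
  cases <- list(c(1.7, 1.7, 3.0), c(1.9, 1.5, 2.5), c(1.52, 1.8, 4.0))
  for (cs in cases) {
    r1 <- cs[1]; r2 <- cs[2]; d <- cs[3]
    R1 <- r1 + probe; R2 <- r2 + probe
    top <- fix_topology(atom_name = c("X1", "X2"), res_name = "UNK",
                        res_num = 1:2, chain = "A", element = "C",
                        vdw = c(r1, r2))
    fr <- frame(rbind(c(0, 0, 0), c(d, 0, 0)))
    s <- sasa(fr, top)
    x1 <- (d^2 + R1^2 - R2^2) / (2 * d)
    x2 <- (d^2 + R2^2 - R1^2) / (2 * d)
    exact1 <- 4 * pi * R1^2 - 2 * pi * R1 * (R1 - x1)
    exact2 <- 4 * pi * R2^2 - 2 * pi * R2 * (R2 - x2)
    expect_lt(abs(s$per_atom$area[1] - exact1) / exact1, 0.02)
    expect_lt(abs(s$per_atom$area[2] - exact2) / exact2, 0.02)
  }
})

test_that("total SASA is bounded by the sum of isolated-atom areas", {
  set.seed(3)
  n <- 8
  top <- fix_topology(atom_name = paste0("X", 1:n), res_name = "UNK",
                      res_num = 1:n, chain = "A", element = "C",
                      vdw = rep(1.7, n))
  fr <- frame(matrix(runif(n * 3, 0, 6), ncol = 3))
  s <- sasa(fr, top)
  iso <- n * 4 * pi * 3.1^2
  expect_lte(s$total, iso + 1e-6)
  # non-overlapping arrangement attains the bound
  fr2 <- frame(cbind(seq(0, by = 10, length.out = n), 0, 0))
  s2 <- sasa(fr2, top)
  expect_equal(s2$total, iso, tolerance = 1e-6)
})

test_that("SASA normalization divides by side-chain heavy atoms and validates n_points", {
  top <- fix_topology(atom_name = c("N", "CA", "C", "O", "CB", "CG"),
                      res_name = "XYZ", res_num = rep(1L, 6), chain = "A",
                      element = c("N", "C", "C", "O", "C", "C"))
  fr <- frame(cbind(seq(0, 50, length.out = 6), 0, 0))
  s <- sasa(fr, top)
  expect_equal(s$per_residue$sidechain_heavy_atoms, 2L)  # CB, CG
  expect_equal(s$per_residue$normalized_area, s$per_residue$area / 2)
  expect_error(sasa(fr, top, n_points = 8), "n_points")
})

# ---- RMSD -------------------------------------------------------------------

test_that("RMSD is zero for identical frames and rigid transforms", {
  set.seed(8)
  n <- 12
  base <- matrix(rnorm(n * 3, sd = 5), ncol = 3)
  top <- fix_topology(atom_name = paste0("A", 1:n), res_name = "GLY",
                      res_num = 1:n, chain = "A")
  th <- 1.1
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  rot <- sweep(base %*% t(R), 2, c(3, -7, 2), "+")
  traj <- fix_traj(top, list(base, base, rot))
  r <- backbone_rmsd(traj, select_atoms(chain = "A"))
  expect_equal(r[1], 0, tolerance = 1e-9)
  expect_equal(r[2], 0, tolerance = 1e-9)
  expect_lt(r[3], 1e-6)
})

test_that("a single displaced atom gives RMSD d/sqrt(n) without superposition", {
  set.seed(10)
  n <- 10; d <- 0.7
  base <- matrix(rnorm(n * 3), ncol = 3)
  moved <- base
  moved[4, 3] <- moved[4, 3] + d
  top <- fix_topology(atom_name = paste0("A", 1:n), res_name = "GLY",
                      res_num = 1:n, chain = "A")
  traj <- fix_traj(top, list(base, moved))
  r <- backbone_rmsd(traj, select_atoms(chain = "A"), superpose = FALSE)
  expect_equal(r[2], d / sqrt(n), tolerance = 1e-12)
})

test_that("superposed RMSD never exceeds raw RMSD and matches bio3d's fit", {
  set.seed(12)
  n <- 15
  base <- matrix(rnorm(n * 3, sd = 4), ncol = 3)
  top <- fix_topology(atom_name = paste0("A", 1:n), res_name = "GLY",
                      res_num = 1:n, chain = "A")
  coords <- list(base)
  for (i in 2:6) coords[[i]] <- coords[[i - 1]] + matrix(rnorm(n * 3, sd = 0.4),
                                                         ncol = 3)
  traj <- fix_traj(top, coords)
  sel <- select_atoms(chain = "A")
  fit <- backbone_rmsd(traj, sel)
  raw <- backbone_rmsd(traj, sel, superpose = FALSE)
  expect_true(all(fit <= raw + 1e-9))
  ref <- as.vector(t(base))
  indep <- vapply(coords, function(m)
    bio3d::rmsd(ref, as.vector(t(m)), fit = TRUE), numeric(1))
  expect_equal(fit, indep, tolerance = 1e-3)
})

test_that("superposition refuses degenerate selections", {
  top <- fix_topology(atom_name = c("A1", "A2"), res_name = "GLY",
                      res_num = 1:2, chain = "A")
  traj <- fix_traj(top, list(matrix(rnorm(6), 2)))
  expect_error(backbone_rmsd(traj, select_atoms(chain = "A")), "at least 3")
})
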