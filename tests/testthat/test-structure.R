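test_that("bond lengths are Euclidean distances, invariant to rigid motion", {
  fr <- matrix(c(0, 0, 0, 0, 0, 1.46), 2, 3, byrow = TRUE)
  expect_equal(bond_length(fr, c(1, 2)), 1.46, tolerance = 1e-14)
  withr::with_seed(1, {
    fr2 <- matrix(rnorm(30), 10, 3)
    for (p in list(c(1, 2), c(3, 7), c(9, 10))) {
      expect_equal(bond_length(fr2, p), sqrt(sum((fr2[p[1], ] - fr2[p[2], ])^2)),
                   tolerance = 1e-12)
    }
    R <- rotation_matrix_xyz(0.3, -1.1, 2.0)
    moved <- sweep(fr2 %*% t(R), 2, c(5, -2, 1), `+`)
    expect_equal(bond_length(moved, c(3, 7)), bond_length(fr2, c(3, 7)),
                 tolerance = 1e-12)
  })
  expect_error(bond_length(rbind(c(1, 1, 1), c(1, 1, 1)), c(1, 2)),
               class = "mpaspec_validation_error")
})

test_that("bla reproduces forced arithmetic and generator bookkeeping", {
  chain <- make_chain_trajectory(n_frames = 1, bond_sd = 0,
                                 dihedral_sd = 0, seed = 1)
  fr <- chain$trajectory$coords[, , 1]
  expect_equal(bla(fr, chain$topology), 1.46 - 1.36, tolerance = 1e-12)
  eq <- make_chain_trajectory(n_frames = 1, sigma_length = 1.40,
                              pi_length = 1.40, bond_sd = 0,
                              dihedral_sd = 0, seed = 1)
  expect_equal(bla(eq$trajectory$coords[, , 1], eq$topology), 0,
               tolerance = 1e-12)
  noisy <- make_chain_trajectory(n_frames = 20, bond_sd = 0.02,
                                 dihedral_sd = 15, seed = 9)
  tl <- structure_timeline(noisy$trajectory, noisy$topology)
  expect_equal(tl$bla, noisy$truth$bla_true, tolerance = 1e-6)
})

test_that("dihedrals follow the standard sign convention and flip under mirroring", {
  p <- matrix(c(1, 0, 0, 0, 0, 0, 0, 1.5, 0, 0.3, 1.5, 1.0),
              4, 3, byrow = TRUE)
  ang <- dihedral_angle(p, 1:4)
  # independent oracle: bio3d torsion
  expect_equal(ang, bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4),
               tolerance = 1e-6, ignore_attr = TRUE)
  mirror <- p; mirror[, 3] <- -mirror[, 3]
  expect_equal(dihedral_angle(mirror, 1:4), -ang, tolerance = 1e-10)
  # trans (planar) quadruple
  trans <- matrix(c(0, 1, 0, 0, 0, 0, 1, 0, 0, 1, -1, 0), 4, 3, byrow = TRUE)
  expect_equal(abs(dihedral_angle(trans, 1:4)), 180, tolerance = 1e-10)
  collinear <- matrix(c(0, 0, 0, 1, 0, 0, 2, 0, 0, 3, 1, 0), 4, 3,
                      byrow = TRUE)
  expect_error(dihedral_angle(collinear, 1:4),
               class = "mpaspec_validation_error")
})

test_that("constructed torsions are recovered exactly by the dihedral reader", {
  built <- make_chain_trajectory(n_frames = 1, bond_sd = 0,
                                 dihedral_mean = 135, dihedral_sd = 0,
                                 seed = 1)
  fr <- built$trajectory$coords[, , 1]
  th <- apply(built$topology$dihedrals, 1,
              function(q) dihedral_angle(fr, q))
  expect_equal(th, rep(135, 10), tolerance = 1e-6)
})

test_that("planarity hits its limits and forced arithmetic", {
  planar <- make_chain_trajectory(n_frames = 1, bond_sd = 0,
                                  dihedral_mean = 180, dihedral_sd = 0,
                                  seed = 1)
  expect_equal(planarity(planar$trajectory$coords[, , 1], planar$topology),
               10, tolerance = 1e-9)
  twisted <- make_chain_trajectory(n_frames = 1, bond_sd = 0,
                                   dihedral_mean = 90, dihedral_sd = 0,
                                   seed = 1)
  expect_equal(planarity(twisted$trajectory$coords[, , 1],
                         twisted$topology), 0, tolerance = 1e-9)
  # one dihedral at 135, nine at 180 -> P = 9.5 via the component form
  expect_equal(sum(mpaspec:::planarity_component(c(135, rep(180, 9)))), 9.5,
               tolerance = 1e-12)
})

test_that("planarity components are even, periodic, and rigid-motion invariant", {
  th <- c(-170, -95, -45, 10, 90, 135, 180)
  pc <- mpaspec:::planarity_component
  expect_equal(pc(th), pc(-th), tolerance = 1e-12)
  expect_equal(pc(th), pc(ifelse(th + 360 > 180, th - 360, th + 360)),
               tolerance = 1e-12)
  chain <- make_chain_trajectory(n_frames = 1, dihedral_sd = 20, seed = 4)
  fr <- chain$trajectory$coords[, , 1]
  R <- rotation_matrix_xyz(1.2, 0.4, -0.8)
  moved <- sweep(fr %*% t(R), 2, c(10, -3, 7), `+`)
  expect_equal(planarity(moved, chain$topology),
               planarity(fr, chain$topology), tolerance = 1e-9)
})

test_that("timelines match single-frame calls and order by twist amplitude", {
  chain <- make_chain_trajectory(n_frames = 5, dihedral_sd = 15,
                                 bond_sd = 0.02, seed = 21)
  tl <- structure_timeline(chain$trajectory, chain$topology)
  for (k in c(1, 3, 5)) {
    fr <- chain$trajectory$coords[, , k]
    expect_equal(tl$bla[k], bla(fr, chain$topology), tolerance = 1e-12)
    expect_equal(tl$planarity[k], planarity(fr, chain$topology),
                 tolerance = 1e-12)
  }
  # identical frames -> constant timeline
  const <- make_chain_trajectory(n_frames = 3, bond_sd = 0,
                                 dihedral_sd = 0, seed = 1)
  tlc <- structure_timeline(const$trajectory, const$topology)
  expect_equal(max(tlc$bla) - min(tlc$bla), 0, tolerance = 1e-12)
  # wider dihedral spread -> lower mean planarity (Monte-Carlo ordering)
  narrow <- make_chain_trajectory(n_frames = 60, dihedral_sd = 10, seed = 30)
  wide <- make_chain_trajectory(n_frames = 60, dihedral_sd = 25, seed = 31)
  p_narrow <- mean(structure_timeline(narrow$trajectory,
                                      narrow$topology)$planarity)
  p_wide <- mean(structure_timeline(wide$trajectory,
                                    wide$topology)$planarity)
  expect_lt(p_wide, p_narrow)
  expect_lt(p_narrow, 10)
})

test_that("xyz trajectories and topologies round-trip through their file formats", {
  chain <- make_chain_trajectory(n_frames = 4, dihedral_sd = 12, seed = 2)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  topo_path <- withr::local_tempfile(fileext = ".json")
  write_xyz_trajectory(chain$trajectory, xyz)
  write_topology(chain$topology, topo_path)
  traj <- read_xyz_trajectory(xyz)
  topo <- read_topology(topo_path)
  expect_equal(traj$coords, chain$trajectory$coords, tolerance = 1e-9)
  expect_equal(traj$times_fs, chain$trajectory$times_fs)
  expect_equal(topo$dihedrals, chain$topology$dihedrals)
  tl_a <- structure_timeline(traj, topo)
  tl_b <- structure_timeline(chain$trajectory, chain$topology)
  expect_equal(tl_a$planarity, tl_b$planarity, tolerance = 1e-8)
  expect_error(read_xyz_trajectory(tempfile()), class = "mpaspec_io_error")
})

test_that("topology invariants are enforced", {
  expect_error(new_topology <- mpaspec:::new_topology(
    sigma_bonds = cbind(1:5, 2:6), pi_bonds = cbind(6:10, 7:11),
    dihedrals = cbind(1:10, 3:12, 4:13, 5:14)),
    class = "mpaspec_validation_error")
})

test_that("timeline summaries report moments and histograms", {
  chain <- make_chain_trajectory(n_frames = 80, dihedral_sd = 12, seed = 6)
  tl <- structure_timeline(chain$trajectory, chain$topology)
  s <- timeline_summary(tl)
  expect_setequal(s$moments$descriptor, c("bla", "planarity"))
  expect_true(all(s$histograms$bla$count >= 0))
  expect_equal(sum(s$histograms$planarity$count), 80)
})
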