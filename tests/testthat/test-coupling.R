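test_that("exact Coulomb interaction matches closed forms and the double-loop oracle", {
  cl <- charge_cloud(rbind(c(0, 0, 0)), 1)
  env <- tibble::tibble(x = 1, y = 0, z = 0, q = 1)
  ex <- exact_interaction(cl, env)
  expect_equal(ex$energy, 1, tolerance = 1e-14)
  expect_equal(sqrt(sum(ex$forces^2)), 1, tolerance = 1e-14)
  expect_equal(ex$forces[1, 1], 1)  # repulsive, pointing away
  # symmetry under swapping roles
  cl2 <- make_charge_cloud(8, extent = 3, seed = 1)
  env2 <- withr::with_seed(2, random_env_shell(6, 5, 9))
  e_ab <- exact_interaction(cl2, env2)$energy
  e_ba <- exact_interaction(charge_cloud(as.matrix(env2[, 1:3]), env2$q),
                            tibble::tibble(x = cl2$positions[, 1],
                                           y = cl2$positions[, 2],
                                           z = cl2$positions[, 3],
                                           q = cl2$charges))$energy
  expect_equal(e_ab, e_ba, tolerance = 1e-12)
  # 20 random charges vs brute force
  cl3 <- make_charge_cloud(20, extent = 4, seed = 3)
  env3 <- withr::with_seed(4, random_env_shell(10, 6, 12))
  got <- exact_interaction(cl3, env3)
  want <- oracle_coulomb(cl3$positions, cl3$charges,
                         as.matrix(env3[, 1:3]), env3$q)
  expect_equal(got$energy, want$energy, tolerance = 1e-12)
  expect_equal(got$forces, want$forces, tolerance = 1e-12)
  expect_error(exact_interaction(cl, tibble::tibble(x = 0, y = 0, z = 0,
                                                    q = 1)),
               class = "mpaspec_validation_error")
})

test_that("multipole moments reproduce point-charge and point-dipole limits", {
  dip <- charge_cloud(rbind(c(0, 0, 0.5), c(0, 0, -0.5)), c(1, -1))
  mp <- multipole_expansion(dip, 2)
  expect_equal(mp$moments[1, 1, 1], 0, tolerance = 1e-14)  # monopole
  expect_equal(mp$moments[1, 1, 2], 1, tolerance = 1e-14)  # dipole q*d = 1
  expect_equal(mp$moments[2, 1, 1], 0, tolerance = 1e-14)
  mono <- charge_cloud(rbind(c(0, 0, 0)), 2.5)
  mp0 <- multipole_expansion(mono, 3)
  expect_equal(mp0$moments[1, 1, 1], 2.5)
  expect_true(all(abs(mp0$moments[-1]) < 1e-14))
  # dipole far potential ~ mu z / r^3
  r <- 25
  expect_equal(multipole_potential(mp, rbind(c(0, 0, r))), 1 / r^2,
               tolerance = 1e-6)
  expect_error(multipole_expansion(dip, 9),
               class = "mpaspec_validation_error")
})

test_that("order-4 far field is accurate to the expected multipole truncation", {
  cl <- make_charge_cloud(12, extent = 2, net_charge = 0.5, seed = 7)
  mp <- multipole_expansion(cl, 4)
  withr::with_seed(8, {
    pts <- as.matrix(random_env_shell(6, 10, 12)[, 1:3])
  })
  v_exact <- vapply(seq_len(nrow(pts)), function(j) {
    sum(cl$charges / sqrt(rowSums(sweep(cl$positions, 2, pts[j, ], `-`)^2)))
  }, numeric(1))
  v_mp <- multipole_potential(mp, pts)
  # cloud radius ~1.7 bohr at r >= 10: (a/r)^5 truncation ~ 1e-4
  expect_lt(max(abs(v_mp - v_exact) / abs(v_exact)), 1e-3)
})

test_that("neutral clouds have dipole-dominated far fields (log-log slope -2)", {
  cl <- make_charge_cloud(10, extent = 2, net_charge = 0, seed = 9)
  mp0 <- multipole_expansion(cl, 0)
  expect_equal(mp0$moments[1, 1, 1], 0, tolerance = 1e-13)
  expect_equal(multipole_potential(mp0, rbind(c(15, 0, 0))), 0,
               tolerance = 1e-14)
  rs <- c(20, 40, 80, 160)
  v <- vapply(rs, function(r) {
    abs(sum(cl$charges / sqrt(rowSums(sweep(cl$positions, 2, c(r, 3, 1),
                                            `-`)^2))))
  }, numeric(1))
  slope <- coef(lm(log(v) ~ log(rs)))[2]
  expect_lt(abs(slope - (-2)), 0.1)
})

test_that("ESP fitting recovers point sources and beats the monopole picture", {
  one <- charge_cloud(rbind(c(0.2, -0.1, 0.3)), 0.75)
  fit1 <- espf_fit(one)
  expect_equal(fit1$charges, 0.75, tolerance = 1e-10)
  dimer <- charge_cloud(rbind(c(0, 0, 1.2), c(0, 0, -1.2)), c(0.5, 0.5))
  fit2 <- espf_fit(dimer)
  expect_equal(fit2$charges[1], fit2$charges[2], tolerance = 1e-8)
  expect_equal(sum(fit2$charges), 1, tolerance = 1e-12)
  cl <- make_charge_cloud(10, extent = 3, net_charge = -0.3, seed = 11)
  fit <- espf_fit(cl)
  expect_equal(sum(fit$charges), -0.3, tolerance = 1e-10)
  # compare residual with a single-center monopole at the same grid points
  v_exact <- vapply(seq_len(nrow(fit$grid)), function(g) {
    sum(cl$charges / sqrt(rowSums(sweep(cl$positions, 2, fit$grid[g, ],
                                        `-`)^2)))
  }, numeric(1))
  mono <- multipole_expansion(cl, 0)
  v_mono <- multipole_potential(mono, fit$grid)
  rms_mono <- sqrt(mean((v_mono - v_exact)^2))
  expect_lt(fit$rms_residual, rms_mono)
})

test_that("hybrid evaluation reduces to the exact one at full-extent cutoff", {
  cl <- make_charge_cloud(10, extent = 3, seed = 13)
  env <- withr::with_seed(14, random_env_shell(12, 4, 15))
  ref <- exact_interaction(cl, env)
  for (scheme in c("single_center", "espf")) {
    h <- hybrid_interaction(cl, env, r_exact = 1e3, scheme = scheme)
    expect_equal(h$energy, ref$energy, tolerance = 1e-12)
    expect_equal(h$forces, ref$forces, tolerance = 1e-12)
    expect_true(all(h$assignment$method == "exact"))
  }
  # partition is a disjoint cover
  h2 <- hybrid_interaction(cl, env, r_exact = 8)
  expect_equal(sort(h2$assignment$point), seq_len(nrow(env)))
  expect_setequal(unique(h2$assignment$method), c("exact", "single_center"))
})

test_that("multipole order improves the far-field approximation", {
  cl <- make_charge_cloud(10, extent = 3, seed = 15)
  env <- withr::with_seed(16, random_env_shell(12, 6, 12))
  ref <- exact_interaction(cl, env)
  errs <- vapply(c(1, 3, 6), function(p) {
    h <- hybrid_interaction(cl, env, r_exact = 0, order = p)
    abs(h$energy - ref$energy)
  }, numeric(1))
  expect_true(errs[3] <= errs[1])
  expect_true(errs[3] <= errs[2])
})

test_that("convergence scans cover the grid and vanish at full extent", {
  cl <- make_charge_cloud(8, extent = 3, seed = 17)
  env <- withr::with_seed(18, random_env_shell(10, 5, 10))
  scan <- convergence_scan(cl, env, r_values = c(0, 6, 100),
                           p_values = c(0, 2, 4))
  expect_equal(nrow(scan), 9L)
  full <- scan[scan$r_exact == 100, ]
  expect_true(all(full$abs_dE < 1e-12))
  expect_true(all(full$abs_dFmax < 1e-12))
  expect_true(all(scan$abs_dE >= 0))
  expect_error(convergence_scan(cl, env, numeric(0), 1),
               class = "mpaspec_validation_error")
})

test_that("espf-based hybrid energies stay close to exact for point-charge clouds", {
  cl <- make_charge_cloud(8, extent = 3, seed = 19)
  env <- withr::with_seed(20, random_env_shell(10, 6, 10))
  ref <- exact_interaction(cl, env)
  h <- hybrid_interaction(cl, env, r_exact = 0, scheme = "espf")
  expect_equal(h$energy, ref$energy, tolerance = 1e-6)
})
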