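test_that("Devereux cube formula matches hand arithmetic", {
  m <- lvm_devereux(list(ivsd = 0.93, lvidd = 4.8, pwtd = 0.93))
  expect_equal(m$mass_g, 0.8 * 1.04 * ((0.93 + 4.8 + 0.93)^3 - 4.8^3) + 0.6,
               tolerance = 1e-12)
  expect_equal(m$mass_g, 154.4, tolerance = 5e-4)
  m2 <- lvm_devereux(list(ivsd = 1, lvidd = 5, pwtd = 1))
  expect_equal(m2$mass_g, 0.832 * (343 - 125) + 0.6, tolerance = 1e-12)
  expect_equal(m2$mass_g, 181.976, tolerance = 1e-12)
})

test_that("Devereux mass tends to the additive constant as walls vanish", {
  m <- lvm_devereux(list(ivsd = 1e-9, lvidd = 4.8, pwtd = 1e-9))
  expect_equal(m$mass_g, 0.6, tolerance = 1e-5)
  expect_error(lvm_devereux(list(ivsd = 0, lvidd = 4.8, pwtd = 1)),
               "positive")
})

test_that("Area-Length mass matches direct arithmetic and is linear in
           density", {
  m <- lvm_area_length(list(a1 = 4 * pi, a2 = pi), l = 6)
  expect_equal(m$mass_g, 1.05 * (5 / 6) * (4 * pi * 7 - pi * 6),
               tolerance = 1e-12)
  expect_equal(m$mass_g, 60.5, tolerance = 1e-3)
  expect_equal(m$intermediates$t_cm, 1, tolerance = 1e-12)
  # zero wall: A1 = A2
  expect_equal(lvm_area_length(list(a1 = pi, a2 = pi), l = 6)$mass_g, 0,
               tolerance = 1e-12)
  m2 <- lvm_area_length(list(a1 = 4 * pi, a2 = pi), l = 6,
                        cfg = method_config(density = 2.1))
  expect_equal(m2$mass_g, 2 * m$mass_g, tolerance = 1e-12)
  expect_error(lvm_area_length(list(a1 = 2, a2 = 3), l = 6), "inverted")
})

test_that("Truncated Ellipsoid mass matches the closed-form shell volume", {
  # hemi-spheroid shell: a = 4, b = 2.4, t = 0.97, d = 0
  m <- lvm_truncated_ellipsoid(list(a1 = pi * 3.37^2, a2 = pi * 2.4^2),
                               a = 4, d = 0)
  hand <- 1.05 * pi * (3.37^2 * (2 / 3) * 4.97 - 2.4^2 * (2 / 3) * 4)
  expect_equal(m$mass_g, hand, tolerance = 1e-12)
  expect_equal(m$mass_g, 73.4, tolerance = 2e-3)
  expect_equal(lvm_truncated_ellipsoid(list(a1 = pi, a2 = pi),
                                       a = 4, d = 1)$mass_g, 0,
               tolerance = 1e-12)
  expect_error(lvm_truncated_ellipsoid(list(a1 = 13, a2 = 12), a = 4, d = 5),
               "geometry error")
})

test_that("TE equals density x analytic shell volume for arbitrary shells", {
  set.seed(21)
  for (i in 1:20) {
    sh <- shell_spec(b_endo = stats::runif(1, 1.8, 3),
                     a_apex = stats::runif(1, 4, 9),
                     d_base = stats::runif(1, 0, 2),
                     t_wall = stats::runif(1, 0.5, 1.5))
    ti <- shell_te_inputs(sh)
    m <- lvm_truncated_ellipsoid(list(a1 = ti$a1, a2 = ti$a2), ti$a, ti$d)
    expect_equal(m$mass_g, shell_true_mass(sh), tolerance = 1e-12)
  }
})

test_that("biplane endo/epi tracing recovers the concentric hemisphere
           shell", {
  sh <- shell_spec(b_endo = 2.4, a_apex = 2.4, d_base = 0, t_wall = 0.8)
  tr <- biplane_tracing(render_contours(sh, "AP4CH", "endocardium", 513L),
                        render_contours(sh, "AP2CH", "endocardium", 513L),
                        render_contours(sh, "AP4CH", "epicardium", 513L),
                        render_contours(sh, "AP2CH", "epicardium", 513L))
  m <- lvm_biplane_endo_epi(tr)
  expect_equal(m$mass_g, 1.05 * (2 / 3) * pi * (3.2^3 - 2.4^3),
               tolerance = 0.01)
  expect_equal(m$mass_g,
               1.05 * (m$intermediates$edv_epi_ml -
                       m$intermediates$edv_endo_ml), tolerance = 1e-12)
})

test_that("biplane endo/epi requires all four contours and a real wall", {
  sh <- pig_shell()
  e4 <- render_contours(sh, "AP4CH", "endocardium")
  e2 <- render_contours(sh, "AP2CH", "endocardium")
  tr <- biplane_tracing(e4, e2)
  expect_error(lvm_biplane_endo_epi(tr), "missing")
  expect_error(biplane_tracing(e4, e2, e4, e2), "exceed")
})

test_that("wall-addition mass matches the analytic-chord oracle on the
           hemisphere", {
  sh <- shell_spec(b_endo = 2.4, a_apex = 2.4, d_base = 0, t_wall = 0.8)
  tr <- biplane_tracing(render_contours(sh, "AP4CH", "endocardium", 513L),
                        render_contours(sh, "AP2CH", "endocardium", 513L))
  ps <- psax_from_areas(pi * 3.2^2, pi * 2.4^2)
  m <- lvm_novel(tr, ps)
  oracle <- 1.05 * oracle_novel_volume(2.4, 2.4, 0.8, 0)
  expect_equal(m$mass_g, oracle, tolerance = 1e-3)
})

test_that("wall-addition mass vanishes at zero wall and grows with t", {
  sh <- pig_shell()
  tr <- biplane_tracing(render_contours(sh, "AP4CH", "endocardium"),
                        render_contours(sh, "AP2CH", "endocardium"))
  a2 <- pi * 2.4^2
  expect_equal(lvm_novel(tr, list(a1 = a2, a2 = a2))$mass_g, 0,
               tolerance = 1e-12)
  masses <- sapply(seq(0.2, 1.4, by = 0.2), function(t)
    lvm_novel(tr, psax_from_areas(pi * (2.4 + t)^2, a2))$mass_g)
  expect_true(all(diff(masses) > 0))
  expect_error(lvm_novel(tr, list(a1 = 10, a2 = 12)), "invalid PSAX|inverted")
})

test_that("stretch expansion equals the stack-level disk-expansion
           arithmetic", {
  # when the epicardial stack is built from the endocardial stack by the
  # same expansion rule, the wall-addition and endo/epi-subtraction routes
  # agree exactly
  sh <- pig_shell()
  e4 <- render_contours(sh, "AP4CH", "endocardium")
  e2 <- render_contours(sh, "AP2CH", "endocardium")
  tr <- biplane_tracing(e4, e2)
  t <- 0.97
  ps <- psax_from_areas(pi * (2.4 + t)^2, pi * 2.4^2)
  m <- lvm_novel(tr, ps, cfg = method_config(expansion = "stretch"))
  L <- max(long_axis(e4)$length, long_axis(e2)$length)
  c4 <- disk_diameters(e4, n_disks = 20L)
  c2 <- disk_diameters(e2, n_disks = 20L)
  v_endo <- biplane_disk_volume(disk_stack(c4, c2, L))
  v_epi <- biplane_disk_volume(disk_stack(c4 + 2 * t, c2 + 2 * t, L + t))
  expect_equal(m$mass_g, 1.05 * (v_epi - v_endo), tolerance = 1e-12)
})

test_that("quantify reports per-method feasibility", {
  st <- lv_study("lin-only",
                 linear = linear_measures(0.9, 4.8, 0.9))
  res <- lvm_quantify(st)
  expect_equal(sum(res$feasible), 1L)
  expect_equal(res$method[res$feasible], "devereux")
  full <- simulate_study(pig_shell(), noiseless(), seed = 1)
  res2 <- lvm_quantify(full)
  expect_true(all(res2$feasible))
  expect_equal(nrow(res2), 5L)
})

test_that("noiseless phantom quantification follows the method oracle
           ladder", {
  sh <- pig_shell()
  truth <- shell_true_mass(sh)
  res <- lvm_quantify(simulate_study(sh, noiseless(),
                                     n_points_apical = 257L,
                                     n_points_psax = 360L))
  m <- stats::setNames(res$mass_g, res$method)
  # TE is exact up to polygonisation, biplane within disk quadrature
  expect_equal(m[["truncated_ellipsoid"]], truth, tolerance = 1e-3)
  expect_equal(m[["biplane_endo_epi"]], truth, tolerance = 0.01)
  # wall-addition within its documented geometric band
  expect_equal(m[["novel"]], truth, tolerance = 0.055)
  # Devereux and Area-Length systematically overestimate on this geometry
  expect_gt(m[["devereux"]], truth * 1.1)
  expect_gt(m[["area_length"]], truth * 1.1)
})

test_that("all methods are homogeneous of degree 3 in length", {
  k <- 1.25
  sh <- pig_shell()
  sh_k <- shell_spec(b_endo = 2.4 * k, a_apex = 7 * k, d_base = 1.19 * k,
                     t_wall = 0.97 * k)
  r1 <- lvm_quantify(simulate_study(sh, noiseless()))
  r2 <- lvm_quantify(simulate_study(sh_k, noiseless()))
  m1 <- stats::setNames(r1$mass_g, r1$method)
  m2 <- stats::setNames(r2$mass_g, r2$method)
  for (meth in c("area_length", "truncated_ellipsoid", "biplane_endo_epi",
                 "novel"))
    expect_equal(m2[[meth]], k^3 * m1[[meth]], tolerance = 1e-9)
  expect_equal(m2[["devereux"]] - 0.6, k^3 * (m1[["devereux"]] - 0.6),
               tolerance = 1e-9)
})
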