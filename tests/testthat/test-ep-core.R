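test_that("uniform resting state is a fixed point of the stepper", {
  sh <- generate_sheet(10, 10, 1)
  sub <- new_substrate(sh, d_l = 0.2, d_t = 0.05)
  st <- resting_state(sub)
  st1 <- step_monodomain(sub, st, dt = 0.05)
  expect_lt(max(abs(st1$v - st$v)), 1e-9 / 110)   # 1e-9 mV
  expect_lt(max(abs(st1$h - st$h)), 1e-9)
})

test_that("zero conductivity decouples vertices into isolated cells", {
  sh <- generate_sheet(10, 10, 1)
  sub <- new_substrate(sh, d_l = 1e-12, d_t = 1e-12)
  centre <- which.min(rowSums(sweep(sh$vertices, 2, c(5, 5, 0))^2))
  mv <- simulate(sub, duration = 50,
                 stimuli = list(list(vertices = centre, start = 1,
                                     duration = 2, amplitude = 0.6)),
                 sample_interval = 5)
  thr <- activation_threshold(sub$cell_params)
  expect_gt(max(mv$vm[, centre]), thr)
  expect_lt(max(mv$vm[, -centre]), thr)
})

test_that("movie framing follows the sampling contract", {
  sh <- generate_sheet(8, 8, 2)
  sub <- new_substrate(sh, d_l = 0.1, d_t = 0.1)
  mv <- simulate(sub, duration = 2000, sample_interval = 10)
  expect_equal(nrow(mv$vm), 201)
  expect_equal(mv$times[c(1, 201)], c(0, 2000))
})

test_that("the explicit stepper enforces its stability bound", {
  sh <- generate_sheet(8, 8, 0.5)
  sub <- new_substrate(sh, d_l = 1, d_t = 1)
  expect_error(step_monodomain(sub, resting_state(sub), dt = 5),
               "stability")
})

test_that("calibration reaches the CV target and the sqrt-conductivity law holds", {
  cal <- calib_fx()   # target 0.5 mm/ms at h = 1
  expect_lt(abs(cal$achieved_cv - 0.5), 0.025)
  cv1 <- measure_cv_sheet(cal$d_l, cal$d_l, h = 1)
  cv2 <- measure_cv_sheet(2 * cal$d_l, 2 * cal$d_l, h = 1)
  expect_lt(abs(cv2 / cv1 - sqrt(2)), 0.08)
})

test_that("isotropic substrates conduct equally along and across fibers", {
  cal <- calib_fx()
  along <- measure_cv_sheet(cal$d_l, cal$d_l, h = 1, fiber_angle = 0)
  across <- measure_cv_sheet(cal$d_l, cal$d_l, h = 1, fiber_angle = pi / 2)
  expect_lt(abs(along / across - 1), 0.02)
})

test_that("halving dt in the converged regime changes planar CV by less than 1 percent", {
  cal <- calib_fx()
  cva <- measure_cv_sheet(cal$d_l, cal$d_l, h = 1, dt = 0.025)
  cvb <- measure_cv_sheet(cal$d_l, cal$d_l, h = 1, dt = 0.0125)
  expect_lt(abs(cva / cvb - 1), 0.01)
})

test_that("unattainable CV targets fail with the feasible range", {
  expect_error(calibrate_cv(50, resolution = 2), "unattainable")
  expect_error(calibrate_cv(-1), "target_cv")
})

test_that("the IIR-conductivity rule is piecewise linear with a floor", {
  expect_equal(iir_to_conductivity(c(0.9, 1.0, 1.22)), c(1, 1, 1))
  expect_equal(iir_to_conductivity(c(1.6, 1.9)), c(0.3, 0.3))
  mid <- iir_to_conductivity(1.41)
  expect_equal(mid, 1 - (1.41 - 1.22) / (1.6 - 1.22) * 0.7, tolerance = 1e-9)
  expect_error(iir_to_conductivity(1, rule = rbind(c(1, 0.5), c(2, 0.8))),
               "non-monotone")
  m <- la_mesh_fx()
  sc <- iir_to_conductivity(rep(1.0, n_vertices(m)), mesh = m)
  expect_length(sc, n_triangles(m))
  expect_true(all(sc == 1))
})

test_that("ERP measurement is monotone in APD scale and reports on the search grid", {
  sh <- generate_sheet(30, 10, 1)
  site <- which(sh$vertices[, 1] < 1)
  sub1 <- new_substrate(sh, d_l = 0.15, d_t = 0.15)
  erp1 <- measure_erp(sub1, site, s1_cl = 400, n_s1 = 4)
  sub2 <- new_substrate(sh, d_l = 0.15, d_t = 0.15, apd_scale = 1.2)
  erp2 <- measure_erp(sub2, site, s1_cl = 400, n_s1 = 4)
  expect_gt(erp2, erp1)
  expect_equal((erp1 - 2.5) %% 5, 0)
  sub0 <- new_substrate(sh, d_l = 0.15, d_t = 0.15,
                        excitability_scale = 1e-6)
  expect_error(measure_erp(sub0, site, s1_cl = 400, n_s1 = 2),
               "baseline capture failure")
})
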