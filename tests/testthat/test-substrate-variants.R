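test_that("the four fibrosis-type variants compose as specified", {
  m <- la_mesh_fx(); fb <- fibrosis_fx()
  cal <- list(d_l = 0.2, d_t = 0.05)
  s_none <- build_substrate(m, fb, "fiber_A", "none", seed = 2,
                            conductivity = cal)
  expect_true(is.null(s_none$decoupled_edges) ||
                nrow(s_none$decoupled_edges) == 0)
  expect_true(all(s_none$apd_scale == 1))
  expect_true(all(s_none$d_l == 0.2))

  s_comb <- build_substrate(m, fb, "fiber_A", "combination", seed = 2,
                            conductivity = cal)
  s_int <- build_substrate(m, fb, "fiber_A", "interstitial", seed = 2,
                           conductivity = cal)
  s_cond <- build_substrate(m, fb, "fiber_A", "conduction_only", seed = 2,
                            conductivity = cal)
  # identical decoupled edge sets (same seed), different conductivities
  expect_identical(s_comb$decoupled_edges, s_int$decoupled_edges)
  expect_true(all(s_int$d_l == 0.2))
  expect_lt(min(s_comb$d_l), 0.2)
  expect_identical(s_comb$d_l, s_cond$d_l)
  expect_true(is.null(s_cond$decoupled_edges) ||
                nrow(s_cond$decoupled_edges) == 0)
  # ionic remodeling only at fibrotic vertices
  expect_true(all(s_comb$apd_scale[fb$iir > IIR_THRESHOLD] == 0.85))
  expect_true(all(s_comb$apd_scale[fb$iir <= IIR_THRESHOLD] == 1))
})

test_that("zero burden makes interstitial identical to the healthy variant", {
  m <- la_mesh_fx()
  f0 <- generate_fibrosis(m, 1, burden = 0)
  cal <- list(d_l = 0.2, d_t = 0.05)
  s_int <- build_substrate(m, f0, "fiber_A", "interstitial", seed = 3,
                           conductivity = cal)
  s_non <- build_substrate(m, f0, "fiber_A", "none", seed = 3,
                           conductivity = cal)
  expect_equal(nrow(s_int$decoupled_edges) %||% 0, 0)
  expect_identical(s_int$d_l, s_non$d_l)
  expect_identical(s_int$apd_scale, s_non$apd_scale)
})

test_that("interstitial edge selection is deterministic, thresholded, and density-monotone", {
  m <- la_mesh_fx(); fb <- fibrosis_fx()
  e1 <- decouple_interstitial_edges(m, fb, seed = 4)
  e2 <- decouple_interstitial_edges(m, fb, seed = 4)
  expect_identical(e1, e2)
  f0 <- generate_fibrosis(m, 1, burden = 0)
  expect_equal(nrow(decouple_interstitial_edges(m, f0, seed = 4)), 0)
  # decoupled edges only where the mean endpoint iir is above threshold
  iir_e <- (fb$iir[e1[, 1]] + fb$iir[e1[, 2]]) / 2
  expect_true(all(iir_e > IIR_THRESHOLD))
  n_lo <- nrow(decouple_interstitial_edges(m, fb, seed = 4, p_max = 0.2))
  n_hi <- nrow(decouple_interstitial_edges(m, fb, seed = 4, p_max = 0.8))
  expect_gt(n_hi, n_lo)
  expect_error(decouple_interstitial_edges(m, fb, seed = 1,
                                           density_rule = function(x) 2),
               "density rule")
})

test_that("changing only the fiber variant leaves all other substrate fields unchanged", {
  m <- la_mesh_fx(); fb <- fibrosis_fx()
  cal <- list(d_l = 0.2, d_t = 0.05)
  sa <- build_substrate(m, fb, "fiber_A", "combination", seed = 5,
                        conductivity = cal)
  sb <- build_substrate(m, fb, "fiber_B", "combination", seed = 5,
                        conductivity = cal)
  expect_identical(sa$d_l, sb$d_l)
  expect_identical(sa$d_t, sb$d_t)
  expect_identical(sa$decoupled_edges, sb$decoupled_edges)
  expect_identical(sa$apd_scale, sb$apd_scale)
  expect_false(identical(sa$fibers$directions, sb$fibers$directions))
  expect_false(substrate_hash(sa) == substrate_hash(sb))
  expect_identical(substrate_hash(sa), substrate_hash(sa))
})

test_that("a fully decoupling-dense patch slows conduction", {
  sh <- generate_sheet(40, 10, 1)
  fibro <- structure(list(iir = rep(1.0, n_vertices(sh)), burden = 0,
                          correlation_length = 0, seed = 0),
                     class = "fibrosis_map")
  x <- sh$vertices[, 1]
  patch <- x > 15 & x < 25
  fibro$iir[patch] <- 1.8
  dec <- decouple_interstitial_edges(sh, fibro, seed = 6,
                                     density_rule = function(i)
                                       as.numeric(i > IIR_THRESHOLD))
  sub_h <- new_substrate(sh, d_l = 0.15, d_t = 0.15)
  sub_f <- new_substrate(sh, d_l = 0.15, d_t = 0.15,
                         decoupled_edges = dec)
  left <- which(x < 1)
  stim <- list(list(vertices = left, start = 1, duration = 2,
                    amplitude = 0.6))
  tmax <- 400
  mh <- simulate(sub_h, duration = tmax, stimuli = stim, sample_interval = 1)
  mf <- simulate(sub_f, duration = tmax, stimuli = stim, sample_interval = 1)
  probe <- which(x > 39)
  th <- mean(afstress:::activation_times(mh)[probe])
  tf <- mean(afstress:::activation_times(mf)[probe])
  expect_gt(tf, th)
})
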