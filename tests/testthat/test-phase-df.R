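test_that("Hilbert phase advances one cycle per oscillation period", {
  sh <- generate_sheet(6, 6, 2)
  n <- n_vertices(sh)
  times <- seq(0, 2000, by = 10)
  vm <- matrix(rep(sin(2 * pi * 6 * times / 1000) * 20 - 60,
                   n), ncol = n)
  vm[, 1] <- -80   # constant vertex
  movie <- structure(list(vm = vm, times = times, sample_interval = 10,
                          mesh = sh, ablated = integer(0),
                          cell_params = cell_model_params()),
                     class = "vm_movie")
  pm <- compute_phase(movie)
  expect_true(pm$undefined[1])
  expect_true(all(is.na(pm$phase[, 1])))
  # unwrapped phase of vertex 2 advances 2*pi per 1/6 s
  dphi <- wrap_pi(diff(pm$phase[, 2]))
  cycles <- sum(dphi) / (2 * pi)
  expect_lt(abs(cycles - 6 * 2) / 12, 0.06)
})

test_that("the PS detector agrees with the brute-force winding oracle", {
  sh <- generate_sheet(20, 20, 2)
  for (s in 1:20) {
    phi <- random_phase_field(sh, s)
    det <- detect_phase_singularities(phi, mesh = sh, dedupe = FALSE)
    orc <- oracle_ps(phi, sh)
    if (is.null(orc)) {
      expect_equal(nrow(det), 0, info = paste("seed", s))
    } else {
      expect_identical(det$vertex, orc$vertex, info = paste("seed", s))
      expect_identical(as.integer(det$charge), as.integer(orc$charge),
                       info = paste("seed", s))
    }
  }
})

test_that("constructed spirals and plane waves give the expected detections", {
  sh <- sheet_fx()
  phi <- atan2(sh$vertices[, 2] - 15.2, sh$vertices[, 1] - 15.2)
  ps <- detect_phase_singularities(phi, mesh = sh)
  expect_equal(nrow(ps), 1)
  expect_equal(ps$charge, 1L)
  ps_m <- detect_phase_singularities(-phi, mesh = sh)
  expect_equal(ps_m$charge, -1L)
  plane <- wrap_pi(0.7 * sh$vertices[, 1])
  expect_equal(nrow(detect_phase_singularities(plane, mesh = sh)), 0)
})

test_that("PS statistics aggregate counts and visited areas", {
  m <- la_mesh_fx()
  ft <- seq(0, 100, by = 10)
  none <- data.frame(time = numeric(0), vertex = integer(0),
                     charge = integer(0))
  st0 <- ps_statistics(none, m, frame_times = ft)
  expect_equal(unlist(st0), c(mean_count = 0, ps_area_cm2 = 0,
                              pv_ps_area_cm2 = 0))
  # one stationary PS at a body vertex
  v_body <- setdiff(as.vector(m$triangles[m$region == "body", ]),
                    as.vector(m$triangles[m$region != "body", ]))[1]
  obs <- data.frame(time = ft, vertex = v_body, charge = 1L)
  st1 <- ps_statistics(obs, m, frame_times = ft)
  expect_equal(st1$mean_count, 1)
  inc <- which(apply(m$triangles == v_body, 1, any))
  expect_equal(st1$ps_area_cm2,
               sum(afstress:::triangle_areas(m$vertices, m$triangles)[inc]) / 100)
  expect_equal(st1$pv_ps_area_cm2, 0)
  # PS confined to a pv region: pv area equals total area
  v_pv <- setdiff(as.vector(m$triangles[m$region == "pv1", ]),
                  as.vector(m$triangles[m$region != "pv1", ]))[1]
  obs2 <- data.frame(time = ft, vertex = v_pv, charge = 1L)
  st2 <- ps_statistics(obs2, m, frame_times = ft)
  expect_equal(st2$pv_ps_area_cm2, st2$ps_area_cm2)
  # windowing drops outside frames
  stw <- ps_statistics(obs, m, window = c(50, 100), frame_times = ft)
  expect_equal(stw$mean_count, 1)
})

test_that("dominant frequency recovers pure tones, silence, and the percentile rule", {
  sh <- generate_sheet(20, 20, 2)
  n <- n_vertices(sh)
  times <- seq(0, 2000, by = 10)
  mk <- function(vm) structure(list(vm = vm, times = times,
                                    sample_interval = 10, mesh = sh,
                                    ablated = integer(0),
                                    cell_params = cell_model_params()),
                               class = "vm_movie")
  tone <- matrix(rep(20 * sin(2 * pi * 6 * times / 1000) - 60, n), ncol = n)
  df <- dominant_frequency(mk(tone), details = TRUE)
  expect_lt(abs(df$df - 6), df$bin_width + 1e-9)
  quiet <- matrix(-80, length(times), n)
  expect_equal(dominant_frequency(mk(quiet)), 0)
  # 20% of vertices at 7 Hz, 80% quiescent
  mixed <- quiet
  k <- floor(0.2 * n)
  mixed[, seq_len(k)] <- rep(20 * sin(2 * pi * 7 * times / 1000) - 60, k)
  df2 <- dominant_frequency(mk(mixed), details = TRUE)
  expect_lt(abs(df2$df - 7), df2$bin_width + 1e-9)
  # adding a constant changes nothing
  expect_equal(dominant_frequency(mk(tone + 25)),
               dominant_frequency(mk(tone)))
  expect_error(dominant_frequency(mk(tone), epoch = c(0, 500)), "1 s")
})

test_that("the sustained-AF rule fires exactly at and above 4.7 Hz", {
  expect_true(classify_af_sustained(6))
  expect_false(classify_af_sustained(0))
  expect_true(classify_af_sustained(4.7))
  expect_false(classify_af_sustained(4.69))
  expect_error(classify_af_sustained(-1))
})

test_that("imaging metrics satisfy the area identities", {
  m <- la_mesh_fx()
  f0 <- generate_fibrosis(m, 1, burden = 0)
  im0 <- imaging_metrics(m, f0)
  expect_equal(im0$fibrosis_area, 0)
  expect_equal(im0$visual_code, 0)
  fb <- fibrosis_fx()
  im <- imaging_metrics(m, fb)
  expect_lt(im$pv_area, im$total_area)
  expect_lte(im$pv_fibrosis_area, min(im$pv_area, im$fibrosis_area))
  expect_equal(im$total_area, mesh_area(m, "cm2"))
  # pv + body + rim areas partition the total exactly
  areas <- afstress:::triangle_areas(m$vertices, m$triangles) / 100
  pv <- m$region %in% paste0("pv", 1:4)
  expect_equal(im$pv_area + sum(areas[!pv]), im$total_area)
  # all-fibrotic pv1-only map: pv fibrosis area equals pv1 area
  iir <- rep(1.0, n_vertices(m))
  pv1_verts <- unique(as.vector(m$triangles[m$region == "pv1", ]))
  iir[pv1_verts] <- 1.8
  f_pv1 <- structure(list(iir = iir, burden = mean(iir > 1.22),
                          correlation_length = 0, seed = 0),
                     class = "fibrosis_map")
  im_pv1 <- imaging_metrics(m, f_pv1)
  pv1_area <- sum(areas[m$region == "pv1"])
  expect_gte(im_pv1$pv_fibrosis_area, 0.95 * pv1_area)
})

test_that("a closed sphere-like mesh reproduces the closed-form area", {
  ico <- afstress:::icosphere(4)
  sph <- afstress:::new_la_mesh(ico$vertices * 10, ico$triangles,
                                factor(rep("body", nrow(ico$triangles)),
                                       levels = c("body", paste0("pv", 1:4),
                                                  "mitral_rim")),
                                list(), character(0),
                                rep(Inf, nrow(ico$vertices)), kind = "closed")
  expect_lt(abs(mesh_area(sph, "cm2") - 4 * pi), 0.15)
})
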