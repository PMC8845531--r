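test_that("phase seeding realises its seeds on a flat sheet", {
  sh <- sheet_fx()
  sub <- new_substrate(sh, d_l = 0.15, d_t = 0.15)
  centre <- which.min(rowSums(sweep(sh$vertices, 2, c(15, 15, 0))^2))
  map1 <- structure(list(seeds = data.frame(vertex = centre, chirality = 1L),
                         variant = "test", core_radius = 5),
                    class = "initiation_map")
  st <- seed_phase_distribution(sub, map1)
  phi <- attr(st, "phase")
  ps <- detect_phase_singularities(phi, mesh = sh)
  expect_equal(nrow(ps), 1)
  expect_lt(sqrt(sum((sh$vertices[ps$vertex, ] -
                        sh$vertices[centre, ])^2)), 2)
  # mirrored chirality flips the detected charge
  map2 <- map1; map2$seeds$chirality <- -1L
  st2 <- seed_phase_distribution(sub, map2)
  ps2 <- detect_phase_singularities(attr(st2, "phase"), mesh = sh)
  expect_equal(ps2$charge, -ps$charge)
  # state values come from the recorded limit cycle
  expect_true(all(st$v >= 0 & st$v <= 1))
  expect_true(all(st$h >= 0 & st$h <= 1))
})

test_that("seeding rejects empty maps and seeds inside ablated regions", {
  sh <- sheet_fx()
  sub <- new_substrate(sh, d_l = 0.15, d_t = 0.15)
  empty <- structure(list(seeds = data.frame(vertex = integer(0),
                                             chirality = integer(0)),
                          variant = "test", core_radius = 5),
                     class = "initiation_map")
  expect_error(seed_phase_distribution(sub, empty), "at least one seed")
  centre <- which.min(rowSums(sweep(sh$vertices, 2, c(15, 15, 0))^2))
  inc <- which(apply(sh$triangles == centre, 1, any))
  sub_abl <- apply_ablation(sub, inc)
  mp <- structure(list(seeds = data.frame(vertex = centre, chirality = 1L),
                       variant = "test", core_radius = 5),
                  class = "initiation_map")
  expect_error(seed_phase_distribution(sub_abl, mp), "ablated")
})

test_that("initiation map variants give distinct valid placements", {
  m <- la_mesh_fx()
  ma <- initiation_map(m, "map_A")
  mb <- initiation_map(m, "map_B")
  mc <- initiation_map(m, "map_C")
  expect_equal(nrow(ma$seeds), 4)
  expect_false(identical(ma$seeds$vertex, mb$seeds$vertex))
  expect_false(identical(mb$seeds$vertex, mc$seeds$vertex))
  expect_setequal(unique(abs(ma$seeds$chirality)), 1)
  # seeds keep away from every boundary loop
  bl <- unlist(m$boundary_loops)
  d <- afstress:::geodesic_from(m, bl)
  expect_true(all(d[ma$seeds$vertex] > 1.5 * m$resolution))
})

test_that("PVI lesions form closed encircling bands", {
  m <- la_mesh_fx()
  les <- build_pvi_lesion(m, d = 5)
  expect_true(isTRUE(afstress:::check_isolation(m, les)))
  cd <- (m$dist_pv[m$triangles[, 1]] + m$dist_pv[m$triangles[, 2]] +
           m$dist_pv[m$triangles[, 3]]) / 3
  expect_true(all(cd[les$triangles] >= les$d - 1e-9))
  expect_true(all(cd[les$triangles] <= les$d + les$width + 1e-9))
  expect_error(build_pvi_lesion(m, d = 5, width = 1), "2 x edge length")
  expect_error(build_pvi_lesion(m, d = 0), "d must be")
  # gap injection breaks the encirclement at graph level
  gap <- inject_lesion_gap(les, m)
  expect_false(isTRUE(afstress:::check_isolation(m, gap)))
})

test_that("ablation is non-mutating and composable", {
  m <- la_mesh_fx(); fb <- fibrosis_fx()
  sub <- build_substrate(m, fb, "fiber_A", "none", seed = 1,
                         conductivity = list(d_l = 0.2, d_t = 0.05))
  les <- build_pvi_lesion(m, d = 5)
  sub2 <- apply_ablation(sub, les)
  expect_length(sub$ablated, 0)
  expect_identical(sort(sub2$ablated), sort(as.integer(les$triangles)))
  expect_identical(sub2$d_l, sub$d_l)
  sub3 <- apply_ablation(sub, integer(0))
  expect_identical(sub3$ablated, sub$ablated)
  expect_error(apply_ablation(sub, c(-1L)), "invalid triangles")
})

test_that("a full-mesh lesion suppresses all propagation", {
  sh <- generate_sheet(10, 10, 1)
  sub <- new_substrate(sh, d_l = 0.15, d_t = 0.15)
  sub_all <- apply_ablation(sub, seq_len(n_triangles(sh)))
  mv <- simulate(sub_all, duration = 50,
                 stimuli = list(list(vertices = 1:5, start = 1,
                                     duration = 2, amplitude = 0.6)),
                 sample_interval = 10)
  expect_true(all(mv$vm <= sub$cell_params$v_rest + 1e-6))
})
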