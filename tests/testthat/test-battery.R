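test_that("the battery enumerates exactly 11 setups varying one field each", {
  setups <- enumerate_setups()
  expect_equal(nrow(setups), 11)
  fields <- c("fibrosis_type", "fiber_variant", "lesion_size",
              "initiation_map", "erp_variant")
  base <- setups[1, fields]
  ndiff <- vapply(2:11, function(r)
    sum(setups[r, fields] != base), numeric(1))
  expect_true(all(ndiff == 1))
  # the varied field follows the documented order
  varied <- vapply(2:11, function(r)
    fields[which(setups[r, fields] != base)], character(1))
  expect_equal(varied, c(rep("fibrosis_type", 3), rep("fiber_variant", 2),
                         "lesion_size", rep("initiation_map", 2),
                         rep("erp_variant", 2)))
  expect_equal(setups$fibrosis_type[4], "none")
  expect_equal(setups$lesion_size[7], "variant")
})

test_that("incomplete configs are rejected with the missing field named", {
  cfg <- battery_config()
  cfg$initiation_maps <- NULL
  expect_error(enumerate_setups(cfg), "initiation_maps")
  cfg2 <- battery_config()
  cfg2$erp_scales <- c(baseline = 1)
  expect_error(enumerate_setups(cfg2), "erp_scales")
})

test_that("signature schema has pre-ablation metrics iff setup <= 4 and DF everywhere", {
  sc <- signature_schema()
  for (i in 1:11) {
    has_pre <- any(grepl(paste0("^s", i, "_ps_count$"), sc$sim))
    expect_equal(has_pre, i <= 4, info = paste("setup", i))
    expect_true(paste0("s", i, "_df") %in% sc$sim)
    expect_true(paste0("s", i, "_sustained") %in% sc$sim)
  }
  expect_identical(sc$all, c(sc$sim, sc$imaging, sc$history))
  # feature sets nest
  cols <- sc$all
  fh <- feature_columns("history", cols, sc)
  fi <- feature_columns("imaging_history", cols, sc)
  fs <- feature_columns("sim_imaging_history", cols, sc)
  expect_true(all(fh %in% fi))
  expect_true(all(fi %in% fs))
})

test_that("run_patient fills the signature and reuses pre-ablation states per policy", {
  m <- coarse_mesh_fx()
  fb <- generate_fibrosis(m, 2, burden = 0.3)
  cfg <- battery_config("desk", pre_duration = 2000, ps_window = 1000,
                        target_cv = 0.5)
  setups <- enumerate_setups(cfg)
  # setups 1 (baseline) and 7 (lesion size) share pre-ablation dynamics;
  # setup 10 (ERP) does not
  sel <- setups[setups$setup %in% c(1, 7, 10), ]
  sig <- run_patient(list(mesh = m, fibrosis = fb, record = NULL),
                     sel, cfg, seed = 21)
  expect_equal(attr(sig, "n_pre_sims"), 2L)
  expect_true(isTRUE(attr(sig, "complete")))
  expect_false(anyNA(sig[c("s1_ps_count", "s1_ps_area", "s1_pv_ps_area",
                           "s1_df", "s7_df", "s10_df",
                           "total_area", "fibrosis_area")]))
  expect_true(is.na(sig["age"]))   # no record supplied
  # determinism
  sig2 <- run_patient(list(mesh = m, fibrosis = fb, record = NULL),
                      sel, cfg, seed = 21)
  expect_identical(as.numeric(sig), as.numeric(sig2))
})

test_that("run_cohort produces one row per patient and resumes from cache", {
  co <- generate_cohort(2, seed = 31, resolution = 4)
  cfg <- battery_config("desk", pre_duration = 2000, ps_window = 1000)
  setups <- enumerate_setups(cfg)[1, ]
  cache <- file.path(tempdir(), "afstress-cache-test")
  unlink(cache, recursive = TRUE)
  tab <- run_cohort(co, setups, cfg, cache_dir = cache)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("id", "recurrence", "s1_df", "total_area", "age")
                  %in% names(tab)))
  expect_false(anyNA(tab$s1_df))
  # resumability: second run must reuse the cached rows bit-for-bit
  tab2 <- run_cohort(co, setups, cfg, cache_dir = cache)
  expect_equal(tab, tab2, ignore_attr = TRUE)
  expect_error(run_cohort(co, setups, cfg, patients = integer(0)),
               "empty cohort")
  unlink(cache, recursive = TRUE)
})
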