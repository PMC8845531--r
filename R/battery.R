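# The 11-setup model-variant stress battery and patient signatures.
#
# Setup 1 is the all-baseline model (combination fibrotic remodeling,
# baseline fiber map, baseline PVI size, baseline initiation map, baseline
# ERP); setups 2-11 each vary exactly one model feature, in the order:
# fibrosis type (2-4), fiber map (5-6), PVI lesion size (7), initiation
# map (8-9), ERP (10-11).  Pre-ablation arrhythmia simulations are analysed
# for setups 1-4 (phase-singularity statistics); post-ablation simulations
# are analysed for all 11 (dominant frequency + sustained-AF flag).

#' Battery configuration
#'
#' @param profile `"desk"` (4 s pre-ablation / 2 s post-ablation epochs,
#'   suited to coarse meshes on one CPU) or `"paper"` (15 s / 2 s).
#' @param ... overrides for any config entry.
#' @return named list of battery parameters.
#' @export
battery_config <- function(profile = c("desk", "paper"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    pre_duration = if (profile == "desk") 4000 else 15000,
    post_duration = 2000,
    ps_window = if (profile == "desk") 3000 else 10000, # final part analysed
    sample_interval = 10,
    target_cv = 0.5,
    anisotropy_ratio = 2,
    fibrosis_types = c("combination", "conduction_only", "interstitial",
                       "none"),
    fiber_variants = c("fiber_A", "fiber_B", "fiber_C"),
    lesion_d = c(baseline = 5, variant = 10),
    initiation_maps = c("map_A", "map_B", "map_C"),
    erp_scales = c(baseline = 1, short = 0.8, long = 1.2))
  utils::modifyList(cfg, list(...))
}

#' Enumerate the 11 stress-test setups
#'
#' @param config from [battery_config()].
#' @return data.frame with 11 rows: `setup`, `fibrosis_type`,
#'   `fiber_variant`, `lesion_size`, `initiation_map`, `erp_variant`.
#' @export
enumerate_setups <- function(config = battery_config()) {
  need <- c("fibrosis_types", "fiber_variants", "lesion_d",
            "initiation_maps", "erp_scales")
  for (nm in need) {
    if (is.null(config[[nm]]))
      stop("config is missing variant values: ", nm)
  }
  if (length(config$fibrosis_types) < 4)
    stop("config is missing variant values: fibrosis_types needs 4 entries")
  if (length(config$fiber_variants) < 3)
    stop("config is missing variant values: fiber_variants needs 3 entries")
  if (length(config$lesion_d) < 2)
    stop("config is missing variant values: lesion_d needs 2 entries")
  if (length(config$initiation_maps) < 3)
    stop("config is missing variant values: initiation_maps needs 3 entries")
  if (length(config$erp_scales) < 3)
    stop("config is missing variant values: erp_scales needs 3 entries")
  base <- data.frame(
    setup = 1L,
    fibrosis_type = config$fibrosis_types[1],
    fiber_variant = config$fiber_variants[1],
    lesion_size = names(config$lesion_d)[1],
    initiation_map = config$initiation_maps[1],
    erp_variant = names(config$erp_scales)[1],
    stringsAsFactors = FALSE)
  rows <- base[rep(1, 11), ]
  rows$setup <- 1:11
  rows$fibrosis_type[2:4] <- config$fibrosis_types[2:4]
  rows$fiber_variant[5:6] <- config$fiber_variants[2:3]
  rows$lesion_size[7] <- names(config$lesion_d)[2]
  rows$initiation_map[8:9] <- config$initiation_maps[2:3]
  rows$erp_variant[10:11] <- names(config$erp_scales)[2:3]
  rownames(rows) <- NULL
  rows
}

#' Column layout of a patient signature
#'
#' @param setups setup table from [enumerate_setups()] (possibly a subset).
#' @return list with character vectors `sim`, `imaging`, `history` and the
#'   concatenated `all` (fixed, documented order).
#' @export
signature_schema <- function(setups = enumerate_setups()) {
  pre <- setups$setup[setups$setup <= 4]
  sim <- c(
    as.vector(t(outer(paste0("s", pre),
                      c("_ps_count", "_ps_area", "_pv_ps_area"), paste0))),
    paste0("s", setups$setup, "_df"),
    paste0("s", setups$setup, "_sustained"))
  imaging <- c("total_area", "pv_area", "fibrosis_area", "pv_fibrosis_area",
               "visual_code")
  history <- c("age", "sex_male", "hypertension", "diabetes", "la_dilated",
               "af_persistent", "af_longstanding")
  list(sim = sim, imaging = imaging, history = history,
       all = c(sim, imaging, history))
}

#' Run the stress battery for one patient
#'
#' For every setup: build the substrate variant, initiate AF by phase
#' seeding, run the pre-ablation epoch (re-used across setups whose varied
#' field does not alter pre-ablation dynamics, i.e. lesion size), apply the
#' setup's PVI lesion, run the post-ablation epoch, and extract metrics.
#' Pre-ablation phase-singularity statistics are recorded for setups 1-4
#' only; post-ablation DF and the sustained flag for every setup run.
#'
#' @param geometry list(mesh, fibrosis, record) from [patient_geometry()],
#'   or an equivalent hand-built list (record may be NULL).
#' @param setups setup table (subset allowed).
#' @param config battery configuration.
#' @param seed integer seed for substrate construction.
#' @return named numeric signature row (see [signature_schema()]);
#'   attributes: `complete` (logical), `n_pre_sims` (cache audit),
#'   `provenance`.
#' @export
run_patient <- function(geometry, setups = enumerate_setups(config),
                        config = battery_config(), seed = 1) {
  mesh <- geometry$mesh
  fibrosis <- geometry$fibrosis
  record <- geometry$record
  schema <- signature_schema(setups)
  sig <- setNames(rep(NA_real_, length(schema$all)), schema$all)
  complete <- TRUE

  conductivity <- calibrate_cv(config$target_cv, config$anisotropy_ratio,
                               resolution = mesh$resolution %||% 2)
  pre_cache <- new.env(parent = emptyenv())
  n_pre <- 0L

  get_pre <- function(row) {
    key <- paste(row$fibrosis_type, row$fiber_variant, row$initiation_map,
                 row$erp_variant, sep = "|")
    hit <- pre_cache[[key]]
    if (!is.null(hit)) return(hit)
    sub <- build_substrate(mesh, fibrosis, row$fiber_variant,
                           row$fibrosis_type, seed = seed,
                           conductivity = conductivity,
                           erp_scale = config$erp_scales[[row$erp_variant]])
    imap <- initiation_map(mesh, row$initiation_map)
    st0 <- seed_phase_distribution(sub, imap)
    movie <- simulate(sub, initial_state = st0,
                      duration = config$pre_duration,
                      sample_interval = config$sample_interval)
    out <- list(substrate = sub, movie = movie)
    pre_cache[[key]] <- out
    n_pre <<- n_pre + 1L
    out
  }

  for (r in seq_len(nrow(setups))) {
    row <- setups[r, ]
    res <- tryCatch({
      pre <- get_pre(row)
      if (row$setup <= 4) {
        ph <- compute_phase(pre$movie)
        win <- c(config$pre_duration - config$ps_window,
                 config$pre_duration)
        obs <- track_phase_singularities(
          ph, ph$times[ph$times >= win[1] & ph$times <= win[2]])
        st <- ps_statistics(obs, mesh, window = win,
                            frame_times = ph$times)
        sig[paste0("s", row$setup, "_ps_count")] <- st$mean_count
        sig[paste0("s", row$setup, "_ps_area")] <- st$ps_area_cm2
        sig[paste0("s", row$setup, "_pv_ps_area")] <- st$pv_ps_area_cm2
      }
      lesion <- build_pvi_lesion(mesh,
                                 d = config$lesion_d[[row$lesion_size]])
      post_sub <- apply_ablation(pre$substrate, lesion)
      post <- simulate(post_sub, initial_state = pre$movie$final_state,
                       duration = config$post_duration,
                       sample_interval = config$sample_interval)
      df <- dominant_frequency(post)
      sig[paste0("s", row$setup, "_df")] <- df
      sig[paste0("s", row$setup, "_sustained")] <-
        as.numeric(classify_af_sustained(df))
      TRUE
    }, error = function(e) {
      warning(sprintf("setup %d failed: %s", row$setup,
                      conditionMessage(e)))
      FALSE
    })
    if (!res) complete <- FALSE
  }

  im <- imaging_metrics(mesh, fibrosis)
  sig["total_area"] <- im$total_area
  sig["pv_area"] <- im$pv_area
  sig["fibrosis_area"] <- im$fibrosis_area
  sig["pv_fibrosis_area"] <- im$pv_fibrosis_area
  sig["visual_code"] <- im$visual_code
  if (!is.null(record)) {
    sig["age"] <- record$age
    sig["sex_male"] <- record$sex_male
    sig["hypertension"] <- record$hypertension
    sig["diabetes"] <- record$diabetes
    sig["la_dilated"] <- record$la_dilated
    sig["af_persistent"] <- as.numeric(record$af_type == "persistent")
    sig["af_longstanding"] <- as.numeric(record$af_type == "long_standing")
  }
  attr(sig, "complete") <- complete
  attr(sig, "n_pre_sims") <- n_pre
  attr(sig, "provenance") <- list(seed = seed, profile = config$profile,
                                  pre_duration = config$pre_duration,
                                  post_duration = config$post_duration,
                                  setups = setups$setup)
  sig
}

#' Run the battery over a cohort
#'
#' @param cohort an `af_cohort`.
#' @param setups setup table (subset allowed).
#' @param config battery configuration.
#' @param cache_dir optional directory of per-patient CSV rows; present
#'   rows are reused, making interrupted runs resumable.
#' @param patients optional patient row indices (default all).
#' @param verbose print per-patient progress.
#' @return data.frame: `id`, `recurrence`, then signature columns; rows
#'   with failed cells carry NA and are flagged in attribute `incomplete`.
#' @export
run_cohort <- function(cohort, setups = enumerate_setups(config),
                       config = battery_config(), cache_dir = NULL,
                       patients = NULL, verbose = FALSE) {
  stopifnot(inherits(cohort, "af_cohort"))
  patients <- patients %||% seq_len(nrow(cohort$patients))
  if (length(patients) < 1) stop("empty cohort")
  schema <- signature_schema(setups)
  rows <- vector("list", length(patients))
  incomplete <- character(0)
  for (k in seq_along(patients)) {
    i <- patients[k]
    id <- cohort$patients$id[i]
    cf <- if (!is.null(cache_dir)) file.path(cache_dir,
                                             paste0(id, ".csv")) else NULL
    if (!is.null(cf) && file.exists(cf)) {
      rows[[k]] <- read.csv(cf)[1, ]
      next
    }
    t0 <- Sys.time()
    geo <- patient_geometry(cohort, i)
    sig <- run_patient(geo, setups, config,
                       seed = cohort$patients$seed[i])
    if (!isTRUE(attr(sig, "complete"))) incomplete <- c(incomplete, id)
    row <- data.frame(id = id,
                      recurrence = cohort$patients$recurrence[i],
                      t(sig))
    if (!is.null(cf)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      write.csv(row, cf, row.names = FALSE)
    }
    rows[[k]] <- row
    if (verbose)
      message(sprintf("%s done in %.1f s", id,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "incomplete") <- incomplete
  attr(out, "schema") <- schema
  out
}
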