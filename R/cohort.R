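# Virtual patient cohort generation.
#
# Each patient couples: shape parameters for a synthetic LA mesh, a target
# fibrosis burden, an AF-type label, history covariates, and a binary
# one-year recurrence outcome drawn from a logistic model on substrate
# summaries with caller-supplied (planted) log-odds coefficients.  Setting
# all coefficients to zero makes labels independent of every feature.
# Geometry is generated lazily per patient so statistical tests on large n
# stay cheap.

#' Default planted effect (log-odds coefficients)
#'
#' Linear predictor: `qlogis(base_rate) + burden * (burden - 0.21) +
#' area * (area_cm2 - 150) / 30 + af_persistent * I(persistent) +
#' af_longstanding * I(long-standing persistent)`.
#' @return named numeric vector
#' @export
cohort_effect <- function(burden = 0, area = 0, af_persistent = 0,
                          af_longstanding = 0) {
  c(burden = burden, area = area, af_persistent = af_persistent,
    af_longstanding = af_longstanding)
}

#' Generate a virtual patient cohort
#'
#' @param n number of patients (>= 2).
#' @param seed master seed; all randomness is derived from it by a tagged
#'   splitting scheme, so a cohort is byte-identical given `(n, seed, ...)`.
#' @param effect named coefficients from [cohort_effect()].
#' @param base_rate marginal recurrence probability when `effect` is zero.
#' @param af_mix proportions of paroxysmal / persistent / long-standing
#'   persistent AF.
#' @param exact_quota use deterministic largest-remainder quotas for the
#'   AF-type split (e.g. 43/41/16 at n = 100 with the default mix) instead
#'   of multinomial sampling.
#' @param resolution mesh target edge length (mm) for lazily built
#'   geometries.
#' @param burden_shape Beta distribution parameters for the fibrosis
#'   burden.
#' @param correlation_length fibrosis patch scale (mm).
#' @return object of class `af_cohort`: data.frame `patients` plus the
#'   generator configuration.  Use [patient_geometry()] to realise a
#'   patient's mesh and fibrosis map.
#' @export
generate_cohort <- function(n, seed, effect = cohort_effect(),
                            base_rate = 0.34,
                            af_mix = c(paroxysmal = 0.43, persistent = 0.41,
                                       long_standing = 0.16),
                            exact_quota = FALSE, resolution = 2,
                            burden_shape = c(1.6, 6),
                            correlation_length = 8) {
  if (n < 2) stop("n must be >= 2")
  eff <- cohort_effect()
  if (!all(names(effect) %in% names(eff)))
    stop("unknown effect coefficient: ",
         paste(setdiff(names(effect), names(eff)), collapse = ", "))
  eff[names(effect)] <- effect
  with_seed(child_seed(seed, "cohort"), {
    af_levels <- c("paroxysmal", "persistent", "long_standing")
    if (exact_quota) {
      q <- floor(af_mix / sum(af_mix) * n)
      rem <- n - sum(q)
      if (rem > 0) {
        frac <- af_mix / sum(af_mix) * n - q
        q[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
          q[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
      }
      af_type <- rep(af_levels, times = q)
    } else {
      af_type <- sample(af_levels, n, replace = TRUE,
                        prob = af_mix / sum(af_mix))
    }
    af_type <- factor(af_type, levels = af_levels)

    burden <- rbeta(n, burden_shape[1], burden_shape[2])
    radius_scale <- 1 + runif(n, -0.06, 0.06)
    # analytic (Thomsen) ellipsoid area minus the ostial holes, cm^2
    base_radii <- c(42, 35, 29)
    p <- 1.6075
    ell_area <- function(r) {
      4 * pi * ((r[1]^p * r[2]^p + r[1]^p * r[3]^p + r[2]^p * r[3]^p) / 3)^(1 / p)
    }
    area_cm2 <- vapply(radius_scale, function(s)
      (ell_area(base_radii * s) * 0.92) / 100, numeric(1))

    age <- round(rnorm(n, 61, 10))
    sex_male <- rbinom(n, 1, 0.7)
    hypertension <- rbinom(n, 1, 0.4)
    diabetes <- rbinom(n, 1, 0.12)
    la_dilated <- as.integer(area_cm2 > 150)

    eta <- qlogis(base_rate) +
      eff["burden"] * (burden - 0.21) +
      eff["area"] * (area_cm2 - 150) / 30 +
      eff["af_persistent"] * (af_type == "persistent") +
      eff["af_longstanding"] * (af_type == "long_standing")
    recurrence <- rbinom(n, 1, plogis(eta))
    rt <- rnorm(n, 189, 95)
    rt <- pmin(455, pmax(90.5, rt))
    recurrence_time <- ifelse(recurrence == 1, round(rt), NA_real_)

    visual_code <- findInterval(burden, stats::qbeta(c(0.25, 0.5, 0.75),
                                                     burden_shape[1],
                                                     burden_shape[2]))
    patients <- data.frame(
      id = sprintf("vp%03d", seq_len(n)),
      seed = vapply(seq_len(n), function(i)
        child_seed(seed, paste0("patient", i)), integer(1)),
      af_type = af_type,
      age = age, sex_male = sex_male, hypertension = hypertension,
      diabetes = diabetes, la_dilated = la_dilated,
      burden = burden, radius_scale = radius_scale,
      area_cm2 = area_cm2, visual_code = visual_code,
      recurrence = recurrence, recurrence_time = recurrence_time,
      stringsAsFactors = FALSE)
    structure(list(patients = patients, seed = seed, effect = eff,
                   base_rate = base_rate, resolution = resolution,
                   burden_shape = burden_shape,
                   correlation_length = correlation_length),
              class = "af_cohort")
  })
}

#' @export
print.af_cohort <- function(x, ...) {
  cat(sprintf("<af_cohort> %d patients (seed %s), recurrence rate %.2f\n",
              nrow(x$patients), format(x$seed),
              mean(x$patients$recurrence)))
  invisible(x)
}

#' Realise the geometry of one cohort patient
#'
#' Deterministically rebuilds the patient's mesh and fibrosis map from the
#' per-patient seed stored in the cohort table.
#'
#' @param cohort an `af_cohort`.
#' @param i patient row index.
#' @return list with `mesh`, `fibrosis`, and the patient `record` row.
#' @export
patient_geometry <- function(cohort, i) {
  rec <- cohort$patients[i, ]
  mesh <- generate_mesh(rec$seed, resolution = cohort$resolution,
                        shape_params = list(
                          radii = c(42, 35, 29) * rec$radius_scale,
                          radius_jitter = 0))
  fibrosis <- generate_fibrosis(mesh, rec$seed, burden = rec$burden,
                                correlation_length =
                                  cohort$correlation_length)
  list(mesh = mesh, fibrosis = fibrosis, record = rec)
}

#' Write the cohort table as CSV
#' @param cohort an `af_cohort`
#' @param path output file
#' @return invisibly, the path
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort$patients, path, row.names = FALSE)
  invisible(path)
}
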