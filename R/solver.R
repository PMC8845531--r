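# Monodomain solver front end: operator assembly, time stepping, CV
# calibration, and the S1-S2 effective refractory period protocol.
#
# Space: P1 finite elements on the triangulated surface with mass lumping,
# anisotropic diffusion tensor D = d_t (I - n n') + (d_l - d_t) f f' per
# triangle.  Decoupled (interstitial) edges have their stiffness coupling
# zeroed with diagonal compensation, i.e. carry no flux.  Ablated triangles
# contribute neither stiffness nor mass; vertices with zero lumped mass are
# clamped at rest and skipped by the reaction update.
#
# Time: explicit operator splitting (forward Euler on diffusion + reaction).
# The step is bounded by both the reaction scale (0.05 ms default) and the
# diffusion stability limit dt < 1/max_i |A_ii| (Gershgorin bound on the
# lumped explicit operator); `simulate()` enforces the bound.

# assemble A = -M^{-1} K and the active-vertex mask
assemble_operator <- function(substrate) {
  mesh <- substrate$mesh
  tri <- mesh$triangles
  keep <- setdiff(seq_len(nrow(tri)), substrate$ablated)
  tri <- tri[keep, , drop = FALSE]
  f <- substrate$fibers$directions[keep, , drop = FALSE]
  d_l <- substrate$d_l[keep]; d_t <- substrate$d_t[keep]
  V <- mesh$vertices
  n <- nrow(V)

  p1 <- V[tri[, 1], , drop = FALSE]
  p2 <- V[tri[, 2], , drop = FALSE]
  p3 <- V[tri[, 3], , drop = FALSE]
  e1 <- p3 - p2; e2 <- p1 - p3; e3 <- p2 - p1   # edge opposite vertex i
  nr <- cross3(e3, -e2)
  a2 <- vec_norm(nr)                             # 2 * area
  area <- a2 / 2
  nh <- nr / a2
  g1 <- cross3(nh, e1) / a2
  g2 <- cross3(nh, e2) / a2
  g3 <- cross3(nh, e3) / a2
  gf1 <- rowSums(g1 * f); gf2 <- rowSums(g2 * f); gf3 <- rowSums(g3 * f)
  dd <- d_l - d_t
  kij <- function(gi, gj, gfi, gfj)
    area * (d_t * rowSums(gi * gj) + dd * gfi * gfj)

  glist <- list(g1, g2, g3); gflist <- list(gf1, gf2, gf3)
  ii <- jj <- xx <- vector("list", 6)
  q <- 1
  for (a in 1:2) for (b in (a + 1):3) {
    val <- kij(glist[[a]], glist[[b]], gflist[[a]], gflist[[b]])
    ii[[q]] <- tri[, a]; jj[[q]] <- tri[, b]; xx[[q]] <- val
    ii[[q + 1]] <- tri[, b]; jj[[q + 1]] <- tri[, a]; xx[[q + 1]] <- val
    q <- q + 2
  }
  i <- unlist(ii); j <- unlist(jj); x <- unlist(xx)

  if (!is.null(substrate$decoupled_edges) &&
      nrow(substrate$decoupled_edges) > 0) {
    dk <- paste(substrate$decoupled_edges[, 1], substrate$decoupled_edges[, 2])
    ek <- paste(pmin(i, j), pmax(i, j))
    drop <- ek %in% dk
    i <- i[!drop]; j <- j[!drop]; x <- x[!drop]
  }
  Koff <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  rs <- Matrix::rowSums(Koff)
  K <- Koff + Matrix::Diagonal(n, -rs)

  M <- numeric(n)
  w <- area / 3
  for (a in 1:3) {
    tm <- tapply(w, tri[, a], sum)
    M[as.integer(names(tm))] <- M[as.integer(names(tm))] + tm
  }
  active <- M > 0
  invM <- ifelse(active, 1 / M, 0)
  A <- Matrix::Diagonal(n, -invM) %*% K
  A <- methods::as(A, "CsparseMatrix")
  list(A = A, active = active, M = M,
       dt_max = 1 / max(abs(Matrix::diag(A)), 1e-12))
}

# turn user-level stimulus descriptors into (start, dur, amp) windows +
# vertex lists; a descriptor may describe a train via `interval` and `count`
expand_stimuli <- function(stimuli) {
  wins <- NULL; verts <- list()
  for (s in stimuli) {
    count <- s$count %||% 1
    interval <- s$interval %||% 0
    dur <- s$duration %||% 2
    amp <- s$amplitude %||% 0.6
    for (k in seq_len(count)) {
      wins <- rbind(wins, c(s$start + (k - 1) * interval, dur, amp))
      verts[[length(verts) + 1]] <- as.integer(s$vertices)
    }
  }
  if (is.null(wins)) wins <- matrix(0, 0, 3)
  list(windows = wins, verts = verts)
}

#' Default resting state for a substrate
#' @param substrate a `substrate`
#' @return list with normalized `v` and gate `h`
#' @export
resting_state <- function(substrate) {
  n <- n_vertices(substrate$mesh)
  list(v = numeric(n), h = rep(1, n))
}

#' Advance the monodomain system by a number of explicit steps
#'
#' Low-level stepping entry point; [simulate()] is the usual interface.
#'
#' @param substrate a `substrate`.
#' @param state list with `v` (normalized) and `h`; see [resting_state()].
#' @param dt time step (ms); must satisfy the stability bound.
#' @param n_steps number of steps.
#' @param stimuli list of stimulus descriptors (`vertices`, `start`,
#'   `duration`, `amplitude`, optional `interval`/`count`), times relative
#'   to the start of this call.
#' @param operator optional pre-assembled operator (from an earlier call's
#'   attribute) to skip re-assembly.
#' @return updated state; attribute `"operator"` carries the assembly.
#' @export
step_monodomain <- function(substrate, state, dt, n_steps = 1,
                            stimuli = list(), operator = NULL) {
  op <- operator %||% assemble_operator(substrate)
  if (dt > op$dt_max * (1 + 1e-9))
    stop(sprintf("dt = %g ms exceeds stability bound %g ms", dt, op$dt_max))
  st <- expand_stimuli(stimuli)
  cp <- substrate$cell_params
  res <- monodomain_run(op$A@p, op$A@i, op$A@x, state$v, state$h,
                        op$active,
                        substrate$excitability_scale / cp$tau_in,
                        1 / cp$tau_out, 1 / cp$tau_open,
                        1 / (cp$tau_close * substrate$apd_scale),
                        cp$v_gate, dt, n_steps, n_steps,
                        st$windows, st$verts)
  if (isTRUE(res$error))
    stop(sprintf("non-finite state at t = %.3f ms, vertex %d",
                 res$time, res$vertex))
  out <- list(v = res$v, h = res$h)
  attr(out, "operator") <- op
  out
}

#' Run a monodomain simulation and record a transmembrane-potential movie
#'
#' @param substrate a `substrate`.
#' @param initial_state list(v, h) or NULL for rest.
#' @param duration simulated time (ms); rounded up to a multiple of
#'   `sample_interval`.
#' @param stimuli stimulus descriptor list (see [step_monodomain()]).
#' @param sample_interval movie sampling interval (ms).
#' @param dt requested step (ms); reduced automatically to meet the
#'   stability bound and to divide `sample_interval` evenly.
#' @param seed unused (the solver is deterministic); kept for interface
#'   symmetry with the generators.
#' @return object of class `vm_movie`: `vm` (frames x vertices, mV),
#'   `times` (ms), `sample_interval`, `stimuli`, `final_state`, `mesh`,
#'   `ablated`.
#' @export
simulate <- function(substrate, initial_state = NULL, duration = 2000,
                     stimuli = list(), sample_interval = 10, dt = 0.1,
                     seed = NULL) {
  if (duration <= 0) stop("duration must be > 0")
  op <- assemble_operator(substrate)
  dt <- min(dt, 0.9 * op$dt_max)
  steps_per_sample <- ceiling(sample_interval / dt)
  dt <- sample_interval / steps_per_sample
  duration <- ceiling(duration / sample_interval) * sample_interval
  n_steps <- round(duration / sample_interval) * steps_per_sample

  state <- initial_state %||% resting_state(substrate)
  st <- expand_stimuli(stimuli)
  cp <- substrate$cell_params
  res <- monodomain_run(op$A@p, op$A@i, op$A@x, state$v, state$h,
                        op$active,
                        substrate$excitability_scale / cp$tau_in,
                        1 / cp$tau_out, 1 / cp$tau_open,
                        1 / (cp$tau_close * substrate$apd_scale),
                        cp$v_gate, dt, n_steps, steps_per_sample,
                        st$windows, st$verts)
  if (isTRUE(res$error))
    stop(sprintf("non-finite state at t = %.3f ms, vertex %d",
                 res$time, res$vertex))
  vm <- cp$v_rest + cp$v_amp * res$vm
  times <- seq(0, duration, by = sample_interval)
  structure(list(vm = vm, times = times, sample_interval = sample_interval,
                 stimuli = st$windows, dt = dt,
                 final_state = list(v = res$v, h = res$h),
                 mesh = substrate$mesh, ablated = substrate$ablated,
                 cell_params = cp),
            class = "vm_movie")
}

#' @export
print.vm_movie <- function(x, ...) {
  cat(sprintf("<vm_movie> %d frames x %d vertices, %.0f ms at %.0f ms sampling\n",
              nrow(x$vm), ncol(x$vm), max(x$times), x$sample_interval))
  invisible(x)
}

# --- conduction velocity -----------------------------------------------

# threshold-crossing activation times (ms) per vertex from a movie
activation_times <- function(movie, threshold = NULL) {
  thr <- threshold %||% activation_threshold(movie$cell_params)
  vm <- movie$vm
  up <- vm[-1, , drop = FALSE] > thr & vm[-nrow(vm), , drop = FALSE] <= thr
  first <- apply(up, 2, function(z) which(z)[1])
  t0 <- movie$times[first]
  # linear interpolation within the sampling interval
  ok <- !is.na(first)
  fi <- first[ok]
  v0 <- vm[cbind(fi, which(ok))]
  v1 <- vm[cbind(fi + 1, which(ok))]
  t0[ok] <- t0[ok] + movie$sample_interval * (thr - v0) / (v1 - v0)
  t0
}

# planar-wave CV (mm/ms) along x on a calibration sheet
measure_cv_sheet <- function(d_l, d_t = d_l, h = 0.5, lx = 40, ly = 12,
                             cell_params = cell_model_params(),
                             fiber_angle = 0, dt = 0.1) {
  sheet <- generate_sheet(lx, ly, h)
  m <- n_triangles(sheet)
  dirs <- matrix(rep(c(cos(fiber_angle), sin(fiber_angle), 0), each = m),
                 m, 3)
  fib <- structure(list(directions = dirs, variant = "calibration"),
                   class = "fiber_field")
  sub <- new_substrate(sheet, fib, d_l = d_l, d_t = d_t,
                       cell_params = cell_params)
  left <- which(sheet$vertices[, 1] < h / 2)
  movie <- simulate(sub, duration = ceiling(lx / 0.1 / 10) * 10 + 100,
                    stimuli = list(list(vertices = left, start = 1,
                                        duration = 2, amplitude = 0.6)),
                    sample_interval = 1, dt = dt)
  at <- activation_times(movie)
  x <- sheet$vertices[, 1]
  mid <- abs(sheet$vertices[, 2] - ly / 2) < h
  p1 <- which(mid & abs(x - 0.3 * lx) < h / 1.9)
  p2 <- which(mid & abs(x - 0.8 * lx) < h / 1.9)
  t1 <- mean(at[p1]); t2 <- mean(at[p2])
  if (!is.finite(t1) || !is.finite(t2) || t2 <= t1) return(NA_real_)
  (mean(x[p2]) - mean(x[p1])) / (t2 - t1)
}

.afstress_cache <- new.env(parent = emptyenv())

#' Calibrate conductivity to a target conduction velocity
#'
#' Bisection on the longitudinal diffusion coefficient using planar-wave CV
#' measured on a flat calibration sheet at the requested resolution; the
#' transverse coefficient is set from the (velocity) anisotropy ratio as
#' `d_t = d_l / ratio^2`.  Results are memoized per parameter set.
#'
#' @param target_cv longitudinal conduction velocity target (mm/ms).
#' @param anisotropy_ratio CV_longitudinal / CV_transverse.
#' @param resolution sheet edge length (mm), matched to the tissue mesh.
#' @param cell_params `cell_model_params`.
#' @param tol relative CV tolerance (default 2%, comfortably within the 5%
#'   contract).
#' @return list with `d_l`, `d_t` (mm^2/ms), `achieved_cv`, `target_cv`,
#'   `resolution`.
#' @export
calibrate_cv <- function(target_cv, anisotropy_ratio = 2, resolution = 0.5,
                         cell_params = cell_model_params(), tol = 0.02) {
  if (target_cv <= 0) stop("target_cv must be > 0")
  key <- digest::digest(list(target_cv, anisotropy_ratio, resolution,
                             unclass(cell_params), tol))
  hit <- .afstress_cache[[key]]
  if (!is.null(hit)) return(hit)

  f <- function(d) measure_cv_sheet(d, d, h = resolution,
                                    cell_params = cell_params)
  lo <- 0.01; hi <- 0.2
  cv_lo <- f(lo); cv_hi <- f(hi)
  while ((is.na(cv_hi) || cv_hi < target_cv) && hi < 20) {
    hi <- hi * 2; cv_hi <- f(hi)
  }
  while (!is.na(cv_lo) && cv_lo > target_cv && lo > 1e-4) {
    lo <- lo / 2; cv_lo <- f(lo)
  }
  if (is.na(cv_hi) || cv_hi < target_cv || (!is.na(cv_lo) && cv_lo > target_cv))
    stop(sprintf("target CV %.3f mm/ms unattainable at resolution %.2f mm (feasible approx [%.3f, %.3f])",
                 target_cv, resolution,
                 ifelse(is.na(cv_lo), 0, cv_lo), ifelse(is.na(cv_hi), 0, cv_hi)))
  d <- NA; cv <- NA
  for (it in 1:40) {
    d <- sqrt(lo * hi)
    cv <- f(d)
    if (is.na(cv)) { lo <- d; next }
    if (abs(cv - target_cv) / target_cv < tol) break
    if (cv < target_cv) lo <- d else hi <- d
  }
  out <- list(d_l = d, d_t = d / anisotropy_ratio^2, achieved_cv = cv,
              target_cv = target_cv, resolution = resolution)
  .afstress_cache[[key]] <- out
  out
}

# --- effective refractory period ---------------------------------------

#' Measure the effective refractory period by an S1-S2 protocol
#'
#' Eight S1 beats at `s1_cl`, then a binary search on the S2 coupling
#' interval (grid of `resolution` ms).  Capture means a propagated response
#' at a probe vertex remote from the pacing site.  The returned ERP is the
#' longest non-capturing interval plus `resolution / 2`.
#'
#' @param substrate a `substrate`.
#' @param site integer vector of pacing vertices.
#' @param s1_cl S1 cycle length (ms).
#' @param resolution search grid (ms).
#' @param n_s1 number of conditioning beats.
#' @param probe optional probe vertex; default: the active vertex farthest
#'   from the site (graph distance).
#' @return ERP in ms.
#' @export
measure_erp <- function(substrate, site, s1_cl = 600, resolution = 5,
                        n_s1 = 8, probe = NULL) {
  stopifnot(length(site) >= 1)
  op <- assemble_operator(substrate)
  if (is.null(probe)) {
    d <- geodesic_from(substrate$mesh, site)
    d[!op$active] <- -1
    probe <- which.max(d)
  }
  thr <- activation_threshold(substrate$cell_params)
  # conditioning train; save state `offset` ms after the last S1 onset
  offset <- 10
  t_last <- 1 + (n_s1 - 1) * s1_cl
  train <- list(list(vertices = site, start = 1, duration = 2,
                     amplitude = 0.6, interval = s1_cl, count = n_s1))
  base <- simulate(substrate, duration = t_last + offset, stimuli = train,
                   sample_interval = 5)
  if (!any(base$vm[, probe] > thr))
    stop("baseline capture failure: S1 train did not propagate to probe")
  state0 <- base$final_state

  upcrossings <- function(movie, from, to) {
    pv <- movie$vm[movie$times >= from & movie$times <= to, probe]
    if (length(pv) < 2) return(0L)
    sum(diff(pv > thr) == 1) + as.integer(pv[1] > thr)
  }
  # control continuation without S2 (the tail of the last S1 wave)
  ctrl <- simulate(substrate, initial_state = state0,
                   duration = s1_cl + 300, sample_interval = 5)
  captures <- function(ci) {
    t2 <- ci - offset + 1     # S2 onset relative to state0
    if (t2 < 0) return(FALSE)
    mv <- simulate(substrate, initial_state = state0,
                   duration = t2 + 300,
                   stimuli = list(list(vertices = site, start = t2,
                                       duration = 2, amplitude = 0.6)),
                   sample_interval = 5)
    upcrossings(mv, t2 + 5, t2 + 300) > upcrossings(ctrl, t2 + 5, t2 + 300)
  }
  lo <- resolution            # assumed refractory
  hi <- s1_cl                 # assumed excitable
  if (!captures(hi)) stop("baseline capture failure: S2 at S1 cycle length did not capture")
  while (hi - lo > resolution) {
    mid <- round((lo + hi) / 2 / resolution) * resolution
    if (mid <= lo) mid <- lo + resolution
    if (mid >= hi) mid <- hi - resolution
    if (captures(mid)) hi <- mid else lo <- mid
  }
  lo + resolution / 2
}
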