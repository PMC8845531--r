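# Shared fixtures (built once per session) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  hit <- .fixtures[[name]]
  if (!is.null(hit)) return(hit)
  val <- builder()
  .fixtures[[name]] <- val
  val
}

la_mesh_fx <- function() fixture("la1", function() generate_mesh(1))
fibrosis_fx <- function() fixture("fib1", function()
  generate_fibrosis(la_mesh_fx(), 3, burden = 0.3))
sheet_fx <- function() fixture("sheet1", function() generate_sheet(30, 30, 1))
coarse_mesh_fx <- function() fixture("la4", function()
  generate_mesh(2, resolution = 4))

# conductivity used by solver unit tests (memoized by the package too)
calib_fx <- function() fixture("cal_h1", function()
  calibrate_cv(0.5, anisotropy_ratio = 2, resolution = 1))

# --- independent oracles -------------------------------------------------

# brute-force winding-number oracle: chains each interior vertex's one-ring
# into an ordered cycle and accumulates wrapped phase differences
oracle_ps <- function(phi, mesh) {
  tri <- mesh$triangles
  bound <- unique(unlist(afstress:::trace_boundary_loops(tri)))
  out <- NULL
  for (v in setdiff(seq_len(nrow(mesh$vertices)), bound)) {
    inc <- which(tri[, 1] == v | tri[, 2] == v | tri[, 3] == v)
    nxt <- list()
    for (ti in inc) {
      tr <- tri[ti, ]
      k <- which(tr == v)
      a <- tr[(k %% 3) + 1]; b <- tr[((k + 1) %% 3) + 1]
      nxt[[as.character(a)]] <- b
    }
    start <- as.integer(names(nxt)[1])
    ring <- start
    repeat {
      nb <- nxt[[as.character(ring[length(ring)])]]
      if (is.null(nb) || nb == start) break
      ring <- c(ring, nb)
    }
    if (length(ring) < 3) next
    cyc <- c(ring, ring[1])
    w <- sum(wrap_pi(diff(phi[cyc]))) / (2 * pi)
    if (!is.na(w) && abs(round(w)) >= 1)
      out <- rbind(out, data.frame(vertex = v, charge = sign(round(w))))
  }
  out
}

# exhaustive pair-counting AUC oracle (ties count half)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# smooth random phase field on a mesh: few random plane/radial harmonics
random_phase_field <- function(mesh, seed) {
  set.seed(seed)
  v <- mesh$vertices
  f <- rnorm(3, 0, 0.15)
  ctr <- colMeans(v) + rnorm(3, 0, 5)
  chg <- sample(-2:2, 1)   # integer so the spiral term is smooth mod 2*pi
  wrap_pi(v %*% f + rnorm(1, 0, pi) +
            chg * atan2(v[, 2] - ctr[2], v[, 1] - ctr[1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
with_seed <- afstress:::with_seed
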