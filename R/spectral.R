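# Dominant frequency (DF) and the sustained-AF rule.
#
# DF summarises the post-ablation 2 s epoch: per-vertex Welch power spectra
# of mean-subtracted Vm in the 1-20 Hz band, per-vertex peak frequency, and
# a robust spatial aggregate (90th percentile over non-ablated body
# vertices).  A simulation is called sustained AF when DF >= 4.7 Hz
# (threshold inclusive).

#' Dominant frequency threshold (Hz) defining sustained AF
#' @export
AF_DF_THRESHOLD <- 4.7

#' Dominant frequency of a transmembrane-potential movie
#'
#' @param movie a `vm_movie`.
#' @param epoch length-2 analysis window (ms); default the whole movie.
#'   Must span at least 1 s.
#' @param band frequency band searched (Hz).
#' @param max_bin maximal frequency resolution (Hz); spectra are
#'   zero-padded until the bin width is at most this.
#' @param quiescent_range vertices whose Vm peak-to-peak range over the
#'   epoch is below this (mV) are treated as quiescent (DF 0).
#' @param percentile spatial aggregation quantile over per-vertex DFs.
#' @param details return per-vertex DFs and the frequency grid too.
#' @return DF in Hz (0 for a quiescent movie), or a list when
#'   `details = TRUE`.
#' @export
dominant_frequency <- function(movie, epoch = NULL, band = c(1, 20),
                               max_bin = 0.25, quiescent_range = 1,
                               percentile = 0.9, details = FALSE) {
  stopifnot(inherits(movie, "vm_movie"))
  epoch <- epoch %||% range(movie$times)
  if (diff(epoch) < 1000) stop("epoch must span at least 1 s")
  sel <- movie$times >= epoch[1] & movie$times <= epoch[2]
  x <- movie$vm[sel, , drop = FALSE]
  fs <- 1000 / movie$sample_interval
  n <- nrow(x)

  # candidate vertices: non-ablated body tissue
  mesh <- movie$mesh
  keep_tri <- setdiff(seq_len(n_triangles(mesh)), movie$ablated)
  body_tri <- keep_tri[mesh$region[keep_tri] == "body" |
                         mesh$kind != "la"]
  verts <- sort(unique(as.vector(mesh$triangles[body_tri, ])))

  xc <- sweep(x[, verts, drop = FALSE], 2,
              colMeans(x[, verts, drop = FALSE]))
  rng <- apply(x[, verts, drop = FALSE], 2, function(v) diff(range(v)))
  quiescent <- rng < quiescent_range

  seg <- min(n, max(16, round(fs)))      # ~1 s segments
  step <- max(1, floor(seg / 2))
  starts <- seq(1, n - seg + 1, by = step)
  nfft <- 2^ceiling(log2(max(seg, fs / max_bin)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))
  pow <- matrix(0, nfft, length(verts))
  for (s0 in starts) {
    segx <- xc[s0:(s0 + seg - 1), , drop = FALSE] * win
    padded <- rbind(segx, matrix(0, nfft - seg, ncol(segx)))
    pow <- pow + Mod(mvfft(padded))^2
  }
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  inband <- which(freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2)
  peak <- inband[apply(pow[inband, , drop = FALSE], 2, which.max)]
  df_v <- freqs[peak]
  df_v[quiescent] <- 0
  df <- if (all(quiescent)) 0 else
    as.numeric(quantile(df_v, percentile, names = FALSE))
  if (details)
    list(df = df, per_vertex = setNames(df_v, verts),
         bin_width = fs / nfft, vertices = verts)
  else df
}

#' Sustained-AF classification from dominant frequency
#'
#' @param df dominant frequency (Hz), non-negative.
#' @return logical: TRUE when `df >= 4.7` (sustained AF); the acute-success
#'   flag of a post-ablation simulation is the negation.
#' @export
classify_af_sustained <- function(df) {
  stopifnot(all(df >= 0))
  df >= AF_DF_THRESHOLD
}
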