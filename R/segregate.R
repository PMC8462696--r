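#' Spatial segregation by binaural cue matching
#'
#' Implements the midbrain-style assignment of time-frequency tiles to
#' spatial channels: the scene is cut into short frames per frequency
#' channel; in low-frequency channels the interaural time difference is
#' estimated from the cross-correlation lag of the band fine structure, in
#' high-frequency channels the interaural level difference from the
#' envelope energy ratio; each tile is then assigned (winner-take-all) to
#' the spatial channel whose preferred azimuth predicts the nearest cue
#' under the same parametric cue model used for spatialisation. Mask mass
#' per tile never exceeds 1; tiles with negligible energy stay unassigned.
#'
#' @param left,right `aim_tf` decompositions of the two ears (matching
#'   banks).
#' @param azimuths preferred azimuths of the spatial channels (degrees).
#' @param frame_ms tile length (ms).
#' @param split_freq channels below this frequency (Hz) use ITD, the
#'   rest ILD. The default is the highest frequency whose period exceeds
#'   twice the spherical-head maximum delay (~656 us), above which a
#'   per-channel fine-structure cross-correlation is phase-ambiguous and
#'   would alias large ITDs onto small ones.
#' @param energy_floor tiles whose energy is below this fraction of the
#'   loudest tile in their channel row are left unassigned.
#' @param match_frac cue-match tolerance as a fraction of the predicted
#'   cue separation between the winning channel and its nearest
#'   neighbour: a tile is encoded only if its observed cue lies within
#'   this distance of the winning channel's preferred cue. Tiles dominated by a single source match their
#'   channel; tiles where concurrent sources mix into a composite cue
#'   match no channel and are dropped, which is what produces spatial
#'   release from masking as sources separate. `Inf` disables the gate
#'   (pure winner-take-all).
#' @return list with `mask` (array frames x frequency x spatial, entries
#'   0/1), `frame_ms`, `azimuths`.
#' @export
spatial_segregate <- function(left, right, azimuths, frame_ms = 20,
                              split_freq = 750, energy_floor = 1e-4,
                              match_frac = 0.5) {
  stopifnot(inherits(left, "aim_tf"), inherits(right, "aim_tf"),
            length(left$cf) == length(right$cf))
  fs <- left$rate
  n <- nrow(left$bm)
  nf <- length(left$cf)
  flen <- max(1L, round(frame_ms * fs / 1000))
  n_frames <- ceiling(n / flen)
  n_sp <- length(azimuths)
  itd_pred <- itd_s(azimuths)
  max_lag <- ceiling(max(abs(itd_pred)) * fs) + 2L
  # per-channel tolerance: half the cue distance to the nearest other
  # channel (never below the lag-quantisation step for ITD)
  local_tol <- function(pred, floor_val = 0) {
    if (n_sp == 1) return(rep(Inf, 1))
    vapply(seq_along(pred), function(i)
      max(match_frac * min(abs(pred[-i] - pred[i])), floor_val),
      numeric(1))
  }
  itd_tol <- local_tol(itd_pred, 1.5 / fs)
  mask <- array(0, dim = c(n_frames, nf, n_sp))
  for (k in seq_len(nf)) {
    lk <- left$bm[, k]
    rk <- right$bm[, k]
    e_fr <- numeric(n_frames)
    for (fr in seq_len(n_frames)) {
      i0 <- (fr - 1) * flen + 1
      i1 <- min(fr * flen, n)
      e_fr[fr] <- sum(lk[i0:i1]^2) + sum(rk[i0:i1]^2)
    }
    thr <- energy_floor * max(e_fr)
    use_itd <- left$cf[k] < split_freq
    ild_pred <- ild_db(azimuths, left$cf[k])
    ild_tol <- local_tol(ild_pred)
    for (fr in seq_len(n_frames)) {
      if (e_fr[fr] <= thr || e_fr[fr] == 0) next
      i0 <- (fr - 1) * flen + 1
      i1 <- min(fr * flen, n)
      if (use_itd) {
        obs <- itd_lag(lk[i0:i1], rk[i0:i1], max_lag) / fs
        win <- which.min(abs(itd_pred - obs))
        if (abs(itd_pred[win] - obs) > itd_tol[win]) next
      } else {
        el <- sum(left$env[i0:i1, k]^2)
        er <- sum(right$env[i0:i1, k]^2)
        if (el == 0 || er == 0) next
        obs <- 10 * log10(er / el)
        win <- which.min(abs(ild_pred - obs))
        if (abs(ild_pred[win] - obs) > ild_tol[win]) next
      }
      mask[fr, k, win] <- 1
    }
  }
  list(mask = mask, frame_ms = frame_ms, azimuths = azimuths)
}

# lag (samples) maximising sum(l[t] * r[t + lag]); positive lag = right
# leads (right-ear waveform is earlier in time)
itd_lag <- function(l, r, max_lag) {
  n <- length(l)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(lag) {
    if (lag >= 0) {
      m <- n - lag
      if (m < 2) return(-Inf)
      sum(l[(1 + lag):n] * r[1:m])
    } else {
      m <- n + lag
      if (m < 2) return(-Inf)
      sum(l[1:m] * r[(1 - lag):n])
    }
  }, numeric(1))
  lags[which.max(cc)]
}

#' Encode masked time-frequency energy as IC spike trains
#'
#' Inhomogeneous Poisson encoding of the segregated scene: for every
#' (spatial channel, frequency channel) pair the instantaneous rate is
#' proportional to the binaural envelope power falling in tiles assigned to
#' that spatial channel, clipped at `max_rate`. Each IC unit is an ensemble
#' rate proxy for the corresponding subcortical channel. With
#' `masks = NULL` the scene is treated as dichotic: segregation is bypassed
#' and all energy feeds a single spatial channel.
#'
#' @param left an `aim_tf` (left ear, or the sole decomposition for
#'   dichotic input).
#' @param right optional `aim_tf` of the right ear.
#' @param masks output of [spatial_segregate()], or `NULL` for dichotic.
#' @param azimuths spatial-channel azimuths; taken from `masks` when
#'   present.
#' @param rate_scale firing rate (spikes/s) at the envelope reference
#'   level.
#' @param max_rate rate ceiling (spikes/s).
#' @param env_ref envelope reference level; default the scene's peak
#'   envelope, making `rate_scale` the rate at the loudest tile.
#' @param compress exponent of the envelope-to-rate mapping
#'   (`rate = rate_scale (env/env_ref)^compress`); values below 1 model
#'   the compressive rate-level behaviour of the auditory periphery and
#'   keep weaker spectral regions (e.g. the fundamental of a voiced
#'   token) represented in the drive.
#' @param onset_ms spike times are shifted by this amount (settle time
#'   before the stimulus).
#' @param bin_ms Poisson discretisation (ms).
#' @param seed integer seed.
#' @return an `aim_ic_input`: `spikes` (data frame `spatial`, `freq`,
#'   `time`), `n_spatial`, `n_freq`, `azimuths`, `freqs`, `duration` (ms,
#'   includes the onset shift).
#' @export
encode_ic <- function(left, right = NULL, masks = NULL, azimuths = 0,
                      rate_scale = 400, max_rate = rate_scale,
                      env_ref = NULL, compress = 1, onset_ms = 0,
                      bin_ms = 1, seed = NULL) {
  stopifnot(rate_scale > 0, inherits(left, "aim_tf"))
  if (!is.null(seed)) set.seed(seed)
  env <- if (is.null(right)) left$env else
    sqrt((left$env^2 + right$env^2) / 2)
  fs <- left$rate
  n <- nrow(env)
  nf <- ncol(env)
  if (!is.null(masks)) azimuths <- masks$azimuths
  n_sp <- length(azimuths)
  env_ref <- env_ref %||% max(env)
  if (env_ref <= 0) env_ref <- 1
  bl <- max(1L, round(bin_ms * fs / 1000))
  n_bins <- ceiling(n / bl)
  bin_of <- rep(seq_len(n_bins), each = bl)[seq_len(n)]
  # mean envelope per (bin, channel)
  env_b <- rowsum(env, bin_of) / as.numeric(table(bin_of))
  rate_b <- pmin(rate_scale * (env_b / env_ref)^compress,
                 max_rate)                                # spikes/s
  out <- vector("list", n_sp * nf)
  ptr <- 0
  for (s in seq_len(n_sp)) {
    for (k in seq_len(nf)) {
      lam <- rate_b[, k]
      if (!is.null(masks)) {
        fr_of_bin <- pmin(ceiling(seq_len(n_bins) * bl / fs * 1000 /
                                    masks$frame_ms), dim(masks$mask)[1])
        lam <- lam * masks$mask[fr_of_bin, k, s]
      }
      lam_cnt <- lam * bl / fs               # expected count per bin
      nz <- which(lam_cnt > 0)
      if (length(nz) == 0) next
      cnt <- stats::rpois(length(nz), lam_cnt[nz])
      tot <- sum(cnt)
      if (tot == 0) next
      bidx <- rep(nz, cnt)
      times <- (bidx - 1 + stats::runif(tot)) * bl / fs * 1000 + onset_ms
      ptr <- ptr + 1
      out[[ptr]] <- data.frame(spatial = s, freq = k, time = times)
    }
  }
  spikes <- if (ptr > 0) do.call(rbind, out[seq_len(ptr)]) else
    data.frame(spatial = integer(0), freq = integer(0), time = numeric(0))
  structure(list(spikes = spikes, n_spatial = n_sp, n_freq = nf,
                 azimuths = azimuths, freqs = left$cf,
                 duration = 1000 * n / fs + onset_ms),
            class = "aim_ic_input")
}

#' @export
print.aim_ic_input <- function(x, ...) {
  cat("IC input:", nrow(x$spikes), "spikes,", x$n_spatial, "spatial x",
      x$n_freq, "frequency channels,", round(x$duration, 1), "ms\n")
  invisible(x)
}

#' Total IC spike counts by spatial channel
#' @param ic an `aim_ic_input`.
#' @return integer vector of length `n_spatial`.
#' @export
ic_counts_by_spatial <- function(ic) {
  as.integer(table(factor(ic$spikes$spatial, levels = seq_len(ic$n_spatial))))
}
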