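#' Audio waveform container
#'
#' @param samples numeric vector of pressure samples (arbitrary units).
#' @param rate sample rate (Hz), >= 16000.
#' @param label optional label.
#' @return an `aim_wave` object.
#' @export
waveform <- function(samples, rate = 40000, label = NULL) {
  stopifnot(all(is.finite(samples)), rate >= 16000)
  structure(list(samples = as.numeric(samples), rate = rate,
                 duration = 1000 * length(samples) / rate, label = label),
            class = "aim_wave")
}

#' Generate a stimulus
#'
#' Three stimulus families cover all protocols: seeded white Gaussian noise
#' (spatial tuning probes), unit-amplitude pure tones (spectral probes) and
#' harmonic-complex speech surrogates. A surrogate token is a harmonic
#' series at a fundamental `f0` whose harmonic amplitudes are shaped by
#' three formant-like resonances (500, 1500, 2500 Hz), modulated at full
#' depth by a syllabic envelope (rate drawn from 3--5 Hz so concurrent
#' talkers alternate rather than co-modulate), with random harmonic
#' phases and 5 ms onset/offset ramps; it reproduces the properties the
#' segregation analyses rely on -- a well-defined f0 and a sparse,
#' speech-like envelope -- without lexical content.
#'
#' @param kind `"noise"`, `"tone"` or `"token"`.
#' @param duration_ms duration (ms), > 0.
#' @param frequency tone frequency (Hz); a warning is issued outside
#'   200--8000 Hz (the filterbank span).
#' @param f0 token fundamental (Hz); conventional defaults are 115
#'   ("male") and 220 ("female").
#' @param formants,formant_bw formant centre frequencies and bandwidths
#'   (Hz) of the token's vocal-tract envelope; concurrent talkers should
#'   use different sets, as different voices and utterances do.
#' @param rate sample rate (Hz).
#' @param seed integer seed for noise samples / token phases.
#' @return an `aim_wave`.
#' @examples
#' gen_stimulus("noise", 80, seed = 1)
#' gen_stimulus("token", 300, f0 = 115, seed = 2)
#' @export
gen_stimulus <- function(kind = c("noise", "tone", "token"),
                         duration_ms, frequency = 1000, f0 = 115,
                         formants = c(500, 1500, 2500),
                         formant_bw = c(80, 120, 200),
                         rate = 40000, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(duration_ms > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_ms * rate / 1000)
  t <- (seq_len(n) - 1) / rate
  x <- switch(kind,
    noise = stats::rnorm(n, 0, 0.3),
    tone = {
      if (frequency < 200 - 1e-6 || frequency > 8000 + 1e-6)
        warning("tone frequency ", frequency,
                " Hz outside the 200-8000 Hz filterbank span")
      sin(2 * pi * frequency * t)
    },
    token = {
      harm <- seq(f0, min(8000, rate / 2 - 1000), by = f0)
      # glottal-source rolloff (~ -6 dB/oct) keeps the fundamental region
      # strong, as in voiced speech; formant resonances shape the rest
      amp <- (0.2 + formant_envelope(harm, formants, formant_bw)) /
        seq_along(harm)^0.9
      ph <- stats::runif(length(harm), 0, 2 * pi)
      x <- drop(cos(outer(2 * pi * t, harm) + rep(ph, each = n)) %*% amp)
      am_ph <- stats::runif(1, 0, 2 * pi)
      am_f <- stats::runif(1, 3, 5)
      # squared raised sine: syllable-like bursts separated by near
      # silence, so concurrent talkers alternate instead of overlapping
      am <- ((1 + sin(2 * pi * am_f * t + am_ph)) / 2)^2
      x <- x * am
      x / stats::sd(x) * 0.3
    })
  x <- apply_ramps(x, rate, ramp_ms = 5)
  waveform(x, rate, label = paste0(kind, if (kind == "token")
    paste0("_f0=", f0) else ""))
}

formant_envelope <- function(f, formants = c(500, 1500, 2500),
                             bw = c(80, 120, 200)) {
  rowSums(vapply(seq_along(formants), function(k)
    1 / (1 + ((f - formants[k]) / bw[k])^2), numeric(length(f))))
}

apply_ramps <- function(x, rate, ramp_ms = 5) {
  nr <- min(round(ramp_ms * rate / 1000), floor(length(x) / 2))
  if (nr > 1) {
    r <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
    x[seq_len(nr)] <- x[seq_len(nr)] * r
    x[length(x) - seq_len(nr) + 1] <- x[length(x) - seq_len(nr) + 1] * r
  }
  x
}

#' Interaural time difference of a spherical head
#'
#' Woodworth's formula `ITD = (r/c) (theta + sin theta)` with head radius
#' r = 8.75 cm and c = 343 m/s. Positive azimuths (right of midline) give
#' positive ITDs, meaning the right ear leads; `itd_s(-a) = -itd_s(a)`.
#'
#' @param azimuth azimuth in degrees, |azimuth| <= 90.
#' @param r head radius (m).
#' @param c_sound speed of sound (m/s).
#' @return ITD in seconds (vectorised).
#' @export
itd_s <- function(azimuth, r = 0.0875, c_sound = 343) {
  th <- azimuth * pi / 180
  (r / c_sound) * (th + sin(th))
}

#' Interaural level difference model
#'
#' Parametric frequency-dependent ILD, linear in azimuth:
#' `ild_db = 5 sqrt(f / 1000) * az / 90` dB, i.e. ~2 dB at 200 Hz rising
#' to ~14 dB at 8 kHz at lateral azimuths, matching the qualitative
#' head-shadow pattern the midbrain stage consumes. Linearity in azimuth
#' keeps the cue resolvable near the poles, where a sin-law ILD would
#' compress neighbouring directions onto almost identical levels.
#'
#' @param azimuth degrees.
#' @param freq frequency (Hz).
#' @return ILD in dB (positive = right ear louder).
#' @export
ild_db <- function(azimuth, freq) {
  5 * sqrt(freq / 1000) * azimuth / 90
}

#' Spatialise a waveform with parametric binaural cues
#'
#' Imparts directionality with a spherical-head interaural time difference
#' ([itd_s()]) and a frequency-dependent interaural level difference
#' ([ild_db()]), applied in the frequency domain (exact fractional delay,
#' zero-phase level shelf split symmetrically across the ears). Azimuth 0
#' yields identical channels. Measured HRTF impulse responses can be
#' supplied instead as a two-column matrix (left, right) to convolve with.
#'
#' @param w an `aim_wave`.
#' @param azimuth degrees, |azimuth| <= 90.
#' @param hrtf optional matrix of HRTF impulse responses (column 1 left,
#'   column 2 right) at the waveform's sample rate; overrides the
#'   parametric model.
#' @return an `aim_binaural` object with equal-length `left` and `right`.
#' @export
spatialize <- function(w, azimuth, hrtf = NULL) {
  stopifnot(inherits(w, "aim_wave"), abs(azimuth) <= 90)
  if (!is.null(hrtf)) {
    stopifnot(is.matrix(hrtf), ncol(hrtf) == 2)
    l <- stats::convolve(w$samples, rev(hrtf[, 1]), type = "open")
    r <- stats::convolve(w$samples, rev(hrtf[, 2]), type = "open")
    n <- max(length(l), length(r))
    return(binaural(c(l, numeric(n - length(l))),
                    c(r, numeric(n - length(r))), w$rate, azimuth))
  }
  fs <- w$rate
  itd <- itd_s(azimuth)
  pad <- 256
  n <- length(w$samples) + pad
  X <- stats::fft(c(w$samples, numeric(pad)))
  f <- (seq_len(n) - 1) / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs          # signed frequencies
  gain <- 10^(ild_db(azimuth, abs(f)) / 40)    # half the ILD per ear
  # right ear leads for positive azimuth: delay left by itd/2, advance right
  dl <- exp(-2i * pi * f * (+itd / 2))
  dr <- exp(-2i * pi * f * (-itd / 2))
  l <- Re(stats::fft(X / gain * dl, inverse = TRUE)) / n
  r <- Re(stats::fft(X * gain * dr, inverse = TRUE)) / n
  binaural(l, r, fs, azimuth)
}

#' @rdname spatialize
#' @param left,right equal-length sample vectors.
#' @param rate sample rate (Hz).
#' @export
binaural <- function(left, right, rate, azimuth = NA_real_) {
  stopifnot(length(left) == length(right))
  structure(list(left = as.numeric(left), right = as.numeric(right),
                 rate = rate, azimuth = azimuth,
                 duration = 1000 * length(left) / rate),
            class = "aim_binaural")
}

#' Mix binaural signals
#'
#' Simultaneous presentation sums sample-wise per ear (zero-padding to the
#' longest signal); sequential presentation concatenates the signals with
#' silent gaps.
#'
#' @param signals list of `aim_binaural` objects with equal sample rates.
#' @param mode `"sum"` or `"concat"`.
#' @param gap_ms silent gap between concatenated signals (ms).
#' @return an `aim_binaural`.
#' @export
mix <- function(signals, mode = c("sum", "concat"), gap_ms = 100) {
  mode <- match.arg(mode)
  stopifnot(length(signals) >= 1)
  rates <- vapply(signals, `[[`, numeric(1), "rate")
  if (length(unique(rates)) != 1) stop("sample-rate mismatch")
  fs <- rates[1]
  if (mode == "sum") {
    n <- max(vapply(signals, function(s) length(s$left), integer(1)))
    l <- r <- numeric(n)
    for (s in signals) {
      l[seq_along(s$left)] <- l[seq_along(s$left)] + s$left
      r[seq_along(s$right)] <- r[seq_along(s$right)] + s$right
    }
  } else {
    gap <- numeric(round(gap_ms * fs / 1000))
    l <- unlist(lapply(signals, function(s) c(s$left, gap)))
    r <- unlist(lapply(signals, function(s) c(s$right, gap)))
    l <- l[seq_len(length(l) - length(gap))]
    r <- r[seq_len(length(r) - length(gap))]
  }
  binaural(l, r, fs)
}

#' Read and write WAV files
#'
#' Minimal RIFF/WAVE support: PCM 16-bit and IEEE float 32-bit, mono or
#' stereo, used for stimuli and user-supplied HRTF pairs.
#'
#' @param x an `aim_wave` (written mono) or `aim_binaural` (stereo).
#' @param path file path.
#' @param bits 16 (PCM) or 32 (float).
#' @return `write_wav` returns `path` invisibly; `read_wav` returns an
#'   `aim_wave` (mono) or `aim_binaural` (stereo).
#' @export
write_wav <- function(x, path, bits = 16) {
  stopifnot(bits %in% c(16, 32))
  if (inherits(x, "aim_wave")) {
    dat <- matrix(x$samples, ncol = 1)
    fs <- x$rate
  } else if (inherits(x, "aim_binaural")) {
    dat <- cbind(x$left, x$right)
    fs <- x$rate
  } else stop("unsupported object")
  n_ch <- ncol(dat)
  inter <- as.numeric(t(dat))
  bytes <- bits / 8
  data_size <- length(inter) * bytes
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(if (bits == 16) 1 else 3); w16(n_ch); w32(fs)
  w32(fs * n_ch * bytes); w16(n_ch * bytes); w16(bits)
  writeChar("data", con, eos = NULL); w32(data_size)
  if (bits == 16) {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(inter * 32767)))),
             con, size = 2, endian = "little")
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  r32()
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; fs <- NULL; n_ch <- NULL; bits <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- r32()
    if (id == "fmt ") {
      fmt <- r16(); n_ch <- r16(); fs <- r32(); r32(); r16()
      bits <- r16()
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      n_samp <- size / (bits / 8)
      dat <- if (bits == 16)
        readBin(con, "integer", n_samp, size = 2, endian = "little") / 32767
      else
        readBin(con, "numeric", n_samp, size = 4, endian = "little")
      break
    } else readBin(con, "raw", size)
  }
  if (is.null(dat)) stop("no data chunk found")
  if (n_ch == 1) return(waveform(dat, fs))
  m <- matrix(dat, nrow = n_ch)
  binaural(m[1, ], m[2, ], fs)
}
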