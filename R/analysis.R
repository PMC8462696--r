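#' Moving-window firing rate
#'
#' Firing rate as spike count in a sliding window divided by the window
#' length, evaluated on a regular step grid (window right-aligned: the rate
#' at time t counts spikes in (t - window, t]).
#'
#' @param spike_times spike times (ms).
#' @param duration evaluation extent (ms).
#' @param window window length (ms), default the 5 ms PSTH window.
#' @param step evaluation step (ms).
#' @return list with `time` (ms) and `rate` (spikes/s).
#' @export
moving_rate <- function(spike_times, duration, window = 5, step = 1) {
  stopifnot(window > 0, step > 0)
  at <- seq(0, duration, by = step)
  cnt <- if (length(spike_times) == 0) numeric(length(at)) else {
    st <- sort(spike_times)
    findInterval(at, st, left.open = FALSE) -
      findInterval(at - window, st, left.open = FALSE)
  }
  list(time = at, rate = cnt / (window / 1000))
}

#' Tuning surface (probe value x time firing-rate matrix)
#'
#' Stacks the moving-window rate of a readout population across a set of
#' probe stimuli (azimuths or frequencies) into the model's approximation
#' of a spectrotemporal / spatial receptive field.
#'
#' @param sims list of `aim_sim` objects, one per probe value.
#' @param probe_values numeric probe values (same length as `sims`).
#' @param pop population to read out (default `"C"`).
#' @param neuron neuron index within the population, or `NULL` for all.
#' @param window,step PSTH window and step (ms).
#' @param from,to time range (ms) over which to evaluate (e.g. excluding a
#'   settling period).
#' @return an `aim_surface`: `rate` (probes x time bins, spikes/s),
#'   `probe_values`, `time`, `window`, `axis`.
#' @export
tuning_surface <- function(sims, probe_values, pop = "C", neuron = NULL,
                           window = 5, step = 1, from = 0, to = NULL) {
  stopifnot(length(sims) == length(probe_values))
  durs <- vapply(sims, `[[`, numeric(1), "duration")
  if (length(unique(durs)) != 1) stop("ragged simulation durations")
  to <- to %||% durs[1]
  rows <- lapply(sims, function(s) {
    sp <- s$spikes[[pop]]
    if (!is.null(neuron)) sp <- sp[sp$neuron %in% neuron, ]
    mr <- moving_rate(sp$time, durs[1], window, step)
    keep <- mr$time >= from & mr$time <= to
    list(rate = mr$rate[keep], time = mr$time[keep])
  })
  structure(list(rate = do.call(rbind, lapply(rows, `[[`, "rate")),
                 probe_values = probe_values, time = rows[[1]]$time,
                 window = window,
                 axis = sims[[1]]$grid$axis),
            class = "aim_surface")
}

#' @export
print.aim_surface <- function(x, ...) {
  cat("Tuning surface:", length(x$probe_values), "probes (", x$axis,
      ") x", length(x$time), "time bins; peak rate",
      round(max(x$rate), 1), "spikes/s\n")
  invisible(x)
}

#' Probe-axis marginal of a tuning surface
#'
#' Total spiking activity per probe across the evaluated epoch (mean rate
#' times epoch length, in spikes).
#' @param surface an `aim_surface`.
#' @return numeric vector over probes.
#' @export
probe_marginal <- function(surface) {
  span_s <- (max(surface$time) - min(surface$time)) / 1000
  rowMeans(surface$rate) * span_s
}

#' Collapse an IC input over the frequency dimension
#'
#' Replaces the spike trains of every spatial channel by a single Poisson
#' train whose rate profile is the summed firing rate across all frequency
#' channels of that spatial channel, so that the expected collapsed count
#' equals the total input count.
#'
#' @param ic an `aim_ic_input` with more than one frequency channel.
#' @param bin_ms rate-profile resolution (ms).
#' @param seed integer seed.
#' @return an `aim_ic_input` with one frequency channel per spatial
#'   channel.
#' @export
collapse_frequency_poisson <- function(ic, bin_ms = 1, seed = NULL) {
  stopifnot(inherits(ic, "aim_ic_input"))
  if (!is.null(seed)) set.seed(seed)
  n_bins <- max(1L, ceiling(ic$duration / bin_ms))
  out <- vector("list", ic$n_spatial)
  for (s in seq_len(ic$n_spatial)) {
    ts <- ic$spikes$time[ic$spikes$spatial == s]
    if (length(ts) == 0) next
    bins <- pmin(pmax(ceiling(ts / bin_ms), 1L), n_bins)
    lam <- tabulate(bins, nbins = n_bins)
    cnt <- stats::rpois(n_bins, lam)
    tot <- sum(cnt)
    if (tot == 0) next
    bidx <- rep(seq_len(n_bins), cnt)
    out[[s]] <- data.frame(spatial = s, freq = 1L,
                           time = (bidx - 1 + stats::runif(tot)) * bin_ms)
  }
  spikes <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(spikes))
    spikes <- data.frame(spatial = integer(0), freq = integer(0),
                         time = numeric(0))
  structure(list(spikes = spikes, n_spatial = ic$n_spatial, n_freq = 1L,
                 azimuths = ic$azimuths, freqs = NA_real_,
                 duration = ic$duration),
            class = "aim_ic_input")
}

#' Two-dimensional correlation coefficient
#'
#' Pearson correlation over all entries of two rate matrices after mean
#' removal; invariant to affine rescaling of either argument. If the time
#' axes differ in length, the shorter matrix is linearly interpolated onto
#' the longer one's column grid.
#'
#' @param A,B numeric matrices (e.g. frequency channel x time firing
#'   rates). Equal row counts required.
#' @return correlation coefficient in `[-1, 1]`, or `NA` (with a warning)
#'   for zero-variance input.
#' @export
corr2d <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("row-count mismatch")
  if (ncol(A) != ncol(B)) {
    if (ncol(A) < ncol(B)) { tmp <- A; A <- B; B <- tmp }
    B <- t(apply(B, 1, function(row)
      stats::approx(seq(0, 1, length.out = length(row)), row,
                    seq(0, 1, length.out = ncol(A)))$y))
  }
  if (stats::sd(A) == 0 || stats::sd(B) == 0) {
    warning("zero-variance input; correlation undefined")
    return(NA_real_)
  }
  stats::cor(as.numeric(A), as.numeric(B))
}

#' Half-maximum tuning width
#'
#' Full width at half maximum of the probe-axis marginal of a tuning
#' surface, with linear interpolation of the half-maximum crossings. When
#' the marginal does not fall below half maximum before the grid edge the
#' edge itself bounds the width.
#'
#' @param surface an `aim_surface`, or a list with elements `marginal` and
#'   `probe_values`.
#' @return width in the probe units (degrees or Hz).
#' @export
tuning_width <- function(surface) {
  if (inherits(surface, "aim_surface")) {
    m <- probe_marginal(surface)
    x <- surface$probe_values
  } else {
    m <- surface$marginal
    x <- surface$probe_values
  }
  if (all(m == 0)) stop("all-zero marginal: no tuning width")
  half <- max(m) / 2
  imax <- which.max(m)
  cross <- function(idx_seq) {
    prev <- imax
    for (i in idx_seq) {
      if (m[i] < half) {
        # linear interpolation between probes i and prev
        return(x[i] + (x[prev] - x[i]) * (half - m[i]) / (m[prev] - m[i]))
      }
      prev <- i
    }
    x[idx_seq[length(idx_seq)]]          # never fell below half: grid edge
  }
  left <- if (imax == 1) x[1] else cross((imax - 1):1)
  right <- if (imax == length(m)) x[length(m)] else cross((imax + 1):length(m))
  right - left
}

#' Autocorrelation pitch estimate
#'
#' Median fundamental-frequency estimate over voiced frames. Each 40 ms
#' frame is declared voiced when the normalised autocorrelation peak in the
#' 50--500 Hz lag range exceeds a clarity threshold; the frame estimate is
#' the reciprocal of the peak lag.
#'
#' @param w an `aim_wave` (or numeric vector with `rate`).
#' @param rate sample rate for bare vectors.
#' @param f_min,f_max pitch search range (Hz).
#' @param frame_ms frame length (ms).
#' @param clarity voicing threshold on the normalised autocorrelation peak.
#' @return f0 estimate in Hz, or `NA` when no voiced frame is found.
#' @export
estimate_f0 <- function(w, rate = NULL, f_min = 50, f_max = 500,
                        frame_ms = 40, clarity = 0.5) {
  if (inherits(w, "aim_wave")) {
    x <- w$samples; rate <- w$rate
  } else x <- as.numeric(w)
  flen <- round(frame_ms * rate / 1000)
  lag_min <- max(2L, floor(rate / f_max))
  lag_max <- min(flen - 1L, ceiling(rate / f_min))
  n_frames <- floor(length(x) / flen)
  if (n_frames < 1 || lag_max <= lag_min) return(NA_real_)
  f0s <- numeric(0)
  for (fr in seq_len(n_frames)) {
    seg <- x[((fr - 1) * flen + 1):(fr * flen)]
    seg <- seg - mean(seg)
    r0 <- sum(seg^2)
    if (r0 == 0) next
    ac <- vapply(lag_min:lag_max, function(l)
      sum(seg[1:(flen - l)] * seg[(1 + l):flen]), numeric(1))
    best <- which.max(ac)
    if (ac[best] / r0 < clarity) next
    lag <- (lag_min:lag_max)[best]
    # parabolic refinement around the peak
    if (best > 1 && best < length(ac)) {
      y1 <- ac[best - 1]; y2 <- ac[best]; y3 <- ac[best + 1]
      denom <- y1 - 2 * y2 + y3
      if (denom != 0) lag <- lag + 0.5 * (y1 - y3) / denom
    }
    f0s <- c(f0s, rate / lag)
  }
  if (length(f0s) == 0) NA_real_ else stats::median(f0s)
}

#' Percent spike-count change between two runs
#'
#' `100 * (count_attend - count_passive) / count_passive` for the readout
#' neurons of the stated channel.
#'
#' @param attend,passive `aim_sim` objects on matching grids.
#' @param channel channel index.
#' @param pop population (default `"C"`).
#' @param from,to counting interval (ms).
#' @return percent change.
#' @export
spike_count_change <- function(attend, passive, channel, pop = "C",
                               from = 0, to = attend$duration) {
  cnt <- function(sim) {
    ids <- which(sim$channel_map[[pop]] == channel)
    sp <- sim$spikes[[pop]]
    sum(sp$neuron %in% ids & sp$time > from & sp$time <= to)
  }
  cp <- cnt(passive)
  if (cp == 0) stop("zero passive spike count in channel ", channel)
  100 * (cnt(attend) - cp) / cp
}

#' Per-channel firing-rate matrix of a readout population
#'
#' Rate matrix (channels x time) of a population with one neuron per
#' channel (e.g. the per-lane cortical readouts), used as the input to
#' [corr2d()].
#'
#' @param sim an `aim_sim`.
#' @param pop population name.
#' @param window,step PSTH window and step (ms).
#' @param from,to time range (ms).
#' @return matrix with one row per neuron/channel.
#' @export
rate_matrix <- function(sim, pop = "C", window = 5, step = 1, from = 0,
                        to = sim$duration) {
  at <- seq(0, sim$duration, by = step)
  keep <- at >= from & at <= to
  n <- length(sim$channel_map[[pop]])
  sp <- sim$spikes[[pop]]
  out <- matrix(0, n, sum(keep))
  for (i in seq_len(n)) {
    mr <- moving_rate(sp$time[sp$neuron == i], sim$duration, window, step)
    out[i, ] <- mr$rate[keep]
  }
  out
}

#' Write a rate matrix as delimited text
#'
#' Probe/channel values as header row, time (ms) as first column.
#' @param rate matrix (probes x time).
#' @param time time axis (ms).
#' @param probe_values row labels.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rate_matrix <- function(rate, time, probe_values, path) {
  df <- data.frame(time_ms = time, t(rate), check.names = FALSE)
  names(df)[-1] <- as.character(probe_values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_matrix
#' @export
read_rate_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  list(time = df$time_ms,
       probe_values = as.numeric(names(df)[-1]),
       rate = t(as.matrix(df[, -1, drop = FALSE])))
}

#' Plot a tuning surface
#'
#' Firing rate as colour over probe value (y) and time (x), the layout
#' used for azimuth- and frequency-dependent PSTHs.
#' @param x an `aim_surface`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.aim_surface <- function(x, ...) {
  graphics::image(x$time, x$probe_values, t(x$rate),
                  xlab = "time (ms)",
                  ylab = if (x$axis == "azimuth") "azimuth (deg)" else
                    "frequency (Hz)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  ...)
  invisible(x)
}
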