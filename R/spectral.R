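#' Boxcar-tapered power spectra per participant and condition
#'
#' Extracts the requested analysis window from every trial (baseline:
#' `t < 0`; tagging: `t >= 0`), applies a single rectangular (boxcar) taper
#' over the full window, evaluates the discrete Fourier transform on the
#' requested frequency grid, converts to one-sided power, and averages the
#' single-trial power within condition per participant. Averaging power
#' (not the complex spectrum) lets components with weak cross-trial phase
#' coherence survive, as expected for intermodulation responses.
#'
#' Power convention: a unit-amplitude sinusoid at an on-grid frequency has
#' bin power `amplitude^2 / 4 = 0.25` (one-sided, no doubling). With a 1 s
#' window the native resolution is 1 Hz, so the default 1-80 Hz grid at
#' 1 Hz steps falls exactly on DFT bins and an on-grid sinusoid leaks into
#' no other bin.
#'
#' @param x a `rift_epochs` (one participant) or `rift_dataset`.
#' @param window `"tagging"` or `"baseline"`.
#' @param f_lo,f_hi frequency grid limits in Hz (defaults 1 and 80).
#' @param step grid step in Hz (default 1); must divide `f_hi - f_lo`.
#' @return an object of class `rift_spectra`: list with `power`
#'   (participant x condition x channel x frequency array, microvolts
#'   squared), `freqs`, `window`, `n_trials` (participant x condition) and
#'   `montage`.
#' @export
windowed_power <- function(x, window = c("tagging", "baseline"),
                           f_lo = 1, f_hi = 80, step = 1) {
  window <- match.arg(window)
  sets <- if (inherits(x, "rift_epochs")) list(x) else {
    stopifnot(inherits(x, "rift_dataset"))
    x
  }
  if (step <= 0) stopf("step must be positive")
  if (f_lo <= 0 || f_hi < f_lo) stopf("need 0 < f_lo <= f_hi")
  if (abs((f_hi - f_lo) / step - round((f_hi - f_lo) / step)) > 1e-9) {
    stopf("step (%g Hz) does not divide the grid [%g, %g] Hz", step, f_lo, f_hi)
  }
  freqs <- seq(f_lo, f_hi, by = step)
  montage <- sets[[1L]]$montage
  conditions <- c("related", "unrelated")
  nch <- length(montage$channels)
  pw <- array(NA_real_,
              dim = c(length(sets), length(conditions), nch, length(freqs)),
              dimnames = list(vapply(sets, `[[`, "", "participant_id"),
                              conditions, montage$channels, freqs))
  n_trials <- matrix(0L, length(sets), length(conditions),
                     dimnames = list(dimnames(pw)[[1L]], conditions))
  E <- NULL
  for (p in seq_along(sets)) {
    ep <- sets[[p]]
    fs <- ep$sample_rate
    idx <- if (window == "baseline") which(ep$time < 0) else which(ep$time >= 0)
    if (length(idx) == 0L) stopf("%s window lies outside the epoch", window)
    n_win <- length(idx)
    if (any(freqs >= fs / 2)) {
      stopf("frequency grid reaches the Nyquist rate (%g Hz)", fs / 2)
    }
    if (is.null(E) || nrow(E) != n_win) {
      t_win <- (seq_len(n_win) - 1) / fs
      E <- exp(-2i * pi * outer(t_win, freqs))
    }
    dat <- ep$data[, , idx, drop = FALSE]
    ntr <- dim(dat)[1L]
    m <- matrix(dat, nrow = ntr * nch)          # (trial, channel) x sample
    p_trial <- array((Mod(m %*% E) / n_win)^2,   # trial x channel x frequency
                     dim = c(ntr, nch, length(freqs)))
    for (ci in seq_along(conditions)) {
      rows <- which(ep$condition == conditions[ci])
      if (length(rows) == 0L) next
      n_trials[p, ci] <- length(rows)
      pw[p, ci, , ] <- colMeans(p_trial[rows, , , drop = FALSE])
    }
  }
  structure(list(power = pw, freqs = freqs, window = window,
                 n_trials = n_trials, montage = montage),
            class = "rift_spectra")
}

#' @export
print.rift_spectra <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<rift_spectra> %s window: %d participants x %d conditions x %d channels x %d freqs (%g-%g Hz)\n",
              x$window, d[1L], d[2L], d[3L], d[4L], min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Percentage power change between tagging window and baseline
#'
#' Element-wise `((power_tagging - power_baseline) / power_baseline) * 100`,
#' computed per participant, condition, channel and frequency. Values are
#' unbounded above and bounded below by -100 (total suppression); a zero
#' baseline power cell is a division error and is reported by location.
#'
#' @param tagging a `rift_spectra` for the tagging window.
#' @param baseline a `rift_spectra` for the baseline window, with identical
#'   participants, conditions, channels and frequency grid.
#' @return an object of class `rift_pc`: list with `pc` (same 4-D shape,
#'   percent), `freqs` and `montage`.
#' @export
percent_change <- function(tagging, baseline) {
  stopifnot(inherits(tagging, "rift_spectra"), inherits(baseline, "rift_spectra"))
  if (!identical(dimnames(tagging$power), dimnames(baseline$power)) ||
      !identical(tagging$freqs, baseline$freqs)) {
    stopf("tagging and baseline spectra must share participants, conditions, channels and frequency grid")
  }
  zero <- which(baseline$power == 0, arr.ind = TRUE)
  if (nrow(zero) > 0L) {
    dn <- dimnames(baseline$power)
    i <- zero[1L, ]
    stopf("zero baseline power at participant %s, condition %s, channel %s, %s Hz: percent change undefined",
          dn[[1L]][i[1L]], dn[[2L]][i[2L]], dn[[3L]][i[3L]], dn[[4L]][i[4L]])
  }
  pc <- (tagging$power - baseline$power) / baseline$power * 100
  structure(list(pc = pc, freqs = tagging$freqs, montage = tagging$montage),
            class = "rift_pc")
}

#' @export
print.rift_pc <- function(x, ...) {
  d <- dim(x$pc)
  cat(sprintf("<rift_pc> percent power change: %d participants x %d conditions x %d channels x %d freqs\n",
              d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

#' Intermodulation frequencies of two tags
#'
#' A nonlinear interaction of two periodic drives at `f1 < f2` produces
#' spectral components at the difference and sum frequencies `f2 - f1` and
#' `f2 + f1`.
#'
#' @param f1 lower tag frequency in Hz (> 0).
#' @param f2 upper tag frequency in Hz (> f1).
#' @return list with elements `difference` and `sum`, in Hz.
#' @export
intermodulation_freqs <- function(f1, f2) {
  stopifnot(is.numeric(f1), is.numeric(f2), length(f1) == 1L, length(f2) == 1L)
  if (!(f2 > f1 && f1 > 0)) stopf("need f2 > f1 > 0")
  list(difference = f2 - f1, sum = f2 + f1)
}

spectra_long <- function(arr, freqs, window, value_name) {
  dn <- dimnames(arr)
  g <- expand.grid(participant = dn[[1L]], condition = dn[[2L]],
                   channel = dn[[3L]], frequency_hz = freqs,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$window <- window
  g[[value_name]] <- as.vector(arr)
  g[, c("participant", "condition", "window", "channel", "frequency_hz",
        value_name)]
}

#' Export spectra or percent-change maps as long-format TSV
#'
#' Columns: participant, condition, window, channel, frequency_hz, value.
#'
#' @param x a `rift_spectra` or `rift_pc`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_spectra_tsv <- function(x, path) {
  tab <- if (inherits(x, "rift_spectra")) {
    spectra_long(x$power, x$freqs, x$window, "power_uv2")
  } else if (inherits(x, "rift_pc")) {
    spectra_long(x$pc, x$freqs, "percent_change", "percent_change")
  } else {
    stopf("x must be a rift_spectra or rift_pc")
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
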