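#' Spectral features from an EEG-like signal
#'
#' Splits a sampled signal into fixed-length epochs (trailing partial
#' epoch dropped) and computes, per epoch, periodogram-based features
#' commonly used for depth-of-anesthesia regression:
#' band powers in the delta (0.5-4 Hz), theta (4-8), alpha (8-13),
#' beta (13-30) and gamma (30-Nyquist) bands, total power (0.5-Nyquist),
#' the 95% spectral edge frequency (frequency below which 95% of total
#' power lies) and the normalized spectral entropy
#' \eqn{-\sum p_k \log p_k / \log K} of the power distribution
#' (0 for an all-zero epoch, by convention).
#'
#' The periodogram is the squared modulus of the FFT scaled by
#' \eqn{1/(n f_s)} (one-sided), computed without tapering so a pure tone
#' at a Fourier frequency lands in a single bin.
#'
#' @param signal numeric vector, the sampled signal (uV).
#' @param fs sampling frequency in Hz (> 0).
#' @param epoch_s epoch length in seconds; `fs * epoch_s` must be a whole
#'   number of samples and the signal must contain at least one epoch.
#'
#' @return A data.frame with one row per epoch and columns `delta`,
#'   `theta`, `alpha`, `beta`, `gamma`, `total_power`, `sef95`,
#'   `spectral_entropy`.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1/128))
#' eeg_features(x, fs = 128, epoch_s = 2)
#' @export
eeg_features <- function(signal, fs, epoch_s = 2) {
  stopifnot(is.numeric(signal), fs > 0, epoch_s > 0)
  n_ep <- round(fs * epoch_s)
  if (abs(n_ep - fs * epoch_s) > 1e-8)
    stop("fs * epoch_s must be a whole number of samples", call. = FALSE)
  if (length(signal) < n_ep)
    stop("signal shorter than one epoch (", n_ep, " samples)",
         call. = FALSE)
  n_epochs <- length(signal) %/% n_ep

  freq <- (seq_len(n_ep %/% 2)) * fs / n_ep   # positive Fourier freqs
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
                beta = c(13, 30), gamma = c(30, fs / 2))

  rows <- lapply(seq_len(n_epochs), function(e) {
    seg <- signal[((e - 1L) * n_ep + 1L):(e * n_ep)]
    sp <- Mod(stats::fft(seg)[seq_len(n_ep %/% 2) + 1L])^2 / (n_ep * fs)
    sp <- 2 * sp                       # one-sided
    keep <- freq >= 0.5 & freq <= fs / 2
    total <- sum(sp[keep])
    bp <- vapply(bands, function(b)
      sum(sp[freq > b[1] & freq <= b[2]]), numeric(1L))
    bp["delta"] <- sum(sp[freq >= 0.5 & freq <= 4])  # lower edge inclusive
    if (total > 0) {
      cum <- cumsum(sp[keep]) / total
      sef <- freq[keep][which(cum >= 0.95)[1L]]
      p <- sp[keep] / total
      p <- p[p > 0]
      ent <- -sum(p * log(p)) / log(sum(keep))
    } else {
      sef <- 0; ent <- 0
    }
    c(bp, total_power = total, sef95 = sef, spectral_entropy = ent)
  })
  as.data.frame(do.call(rbind, rows))
}
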