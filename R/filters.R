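#' Design a cascaded-biquad Butterworth band-pass
#'
#' A Butterworth band-pass of order `2 * n_sections` realized as serially
#' cascaded second-order (biquad) IIR sections. The transfer function is
#' designed with [signal::butter()] and factored into biquads by
#' conjugate-pole pairing; the band-pass zeros (`n_sections`-fold zeros at
#' z = 1 and z = -1) give each section the numerator (1, 0, -1), and the
#' overall gain is split evenly across sections for numerical headroom.
#'
#' @param low,high Band edges in Hz.
#' @param rate Sampling rate in Hz; must exceed `2 * high`.
#' @param n_sections Number of biquad sections (default 2).
#' @return An object of class `biquad_cascade`: list of sections, each with
#'   numerator `b` and denominator `a` (length-3 each).
#' @export
design_biquad_cascade <- function(low, high, rate, n_sections = 2) {
  stopifnot(low > 0, high > low, n_sections >= 1)
  if (rate <= 2 * high) stop("sampling rate too low for this band: aliasing")
  flt <- signal::butter(n_sections, c(low, high) / (rate / 2), type = "pass")
  b <- flt$b
  a <- flt$a
  # poles: roots of the denominator polynomial; pair complex conjugates
  poles <- polyroot(rev(a))
  pos <- poles[Im(poles) >= 0]
  pos <- pos[order(Mod(pos))]
  stopifnot(length(pos) == n_sections)
  g <- b[1]^(1 / n_sections)
  sections <- lapply(seq_along(pos), function(i) {
    p <- pos[i]
    list(b = g * c(1, 0, -1),
         a = c(1, -2 * Re(p), Mod(p)^2))
  })
  structure(list(sections = sections, low = low, high = high, rate = rate),
            class = "biquad_cascade")
}

#' Apply a biquad cascade to a signal
#'
#' @param cascade A [design_biquad_cascade()] object.
#' @param x Numeric vector.
#' @param zero_phase Apply forward-backward (zero-phase) filtering instead
#'   of the default causal forward pass. Causal filtering matches a
#'   real-time monitor; zero-phase is useful offline.
#' @return Filtered vector, same length as `x`.
#' @export
apply_biquad_cascade <- function(cascade, x, zero_phase = FALSE) {
  stopifnot(inherits(cascade, "biquad_cascade"))
  y <- as.numeric(x)
  for (s in cascade$sections) {
    y <- if (zero_phase)
      as.numeric(signal::filtfilt(signal::Arma(b = s$b, a = s$a), y))
    else
      as.numeric(signal::filter(signal::Arma(b = s$b, a = s$a), y))
  }
  y
}

# Magnitude response of the cascade at frequencies f (Hz).
biquad_cascade_gain <- function(cascade, f) {
  w <- 2 * pi * f / cascade$rate
  z <- exp(1i * w)
  g <- rep(1 + 0i, length(z))
  for (s in cascade$sections) {
    num <- s$b[1] + s$b[2] / z + s$b[3] / z^2
    den <- s$a[1] + s$a[2] / z + s$a[3] / z^2
    g <- g * num / den
  }
  Mod(g)
}
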