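#' Pitch-class arithmetic on the Shepard circle
#'
#' Shepard tones live on a circular pitch-class space of one octave,
#' 0--12 semitones, anchored so that the tone built on 440 Hz has pitch
#' class 0. All arithmetic is modulo 12; pitch class 12 is identical to 0.
#'
#' @param x numeric vector of pitch classes in semitones.
#' @return `pitch_class()` returns values wrapped into `[0, 12)`.
#' @examples
#' pitch_class(12)    # 0
#' pitch_class(-1.5)  # 10.5
#' @export
pitch_class <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  x %% 12
}

#' Signed minimal circular step between two pitch classes
#'
#' Returns the signed step from `pc_from` to `pc_to` along the shorter arc
#' of the pitch circle, in semitones within `(-6, 6]`. Steps of less than
#' 6 st are unambiguous (e.g. 0 -> 3 is ascending +3, 0 -> 9 is descending
#' -3); the half-octave step returns +6 by convention (the ambiguity
#' boundary -- downstream percept labels never depend on this sign, only
#' on the side of the bias).
#'
#' @param pc_from,pc_to pitch classes in semitones (any real; wrapped mod 12).
#' @return signed semitones in `(-6, 6]`, vectorised.
#' @examples
#' circular_step(0, 3)  # +3
#' circular_step(0, 9)  # -3
#' circular_step(0, 6)  # +6 (ambiguous boundary)
#' @export
circular_step <- function(pc_from, pc_to) {
  d <- (pc_to - pc_from) %% 12
  ifelse(d > 6, d - 12, d)
}

#' Absolute circular distance between pitch classes
#'
#' @param a,b pitch classes in semitones.
#' @return distance in `[0, 6]` semitones.
#' @export
circular_distance <- function(a, b) {
  abs(circular_step(a, b))
}

#' Circular mean of pitch classes
#'
#' Resultant-vector mean on the 12-semitone circle; weights optional.
#'
#' @param pc pitch classes in semitones.
#' @param w optional nonnegative weights.
#' @return mean pitch class in `[0, 12)`, or `NA` if the resultant
#'   magnitude is numerically zero (uniform input).
#' @export
circular_mean_pc <- function(pc, w = NULL) {
  if (is.null(w)) w <- rep(1, length(pc))
  stopifnot(length(w) == length(pc), all(w >= 0))
  th <- 2 * pi * pc / 12
  z <- sum(w * exp(1i * th))
  if (Mod(z) < 1e-12 * max(sum(w), 1)) return(NA_real_)
  r <- (Arg(z) * 12 / (2 * pi)) %% 12
  if (r >= 12) r <- 0   # guard the floating-point wrap at exactly 12
  r
}

# Circular (Fisher-Lee) correlation between two circular variables given in
# semitone pitch-class units. Used to score how faithfully a decoded pitch
# tracks the true pitch around the circle.
#' Circular correlation of two pitch-class vectors
#'
#' Fisher--Lee circular correlation coefficient, with both variables
#' expressed on the 12-semitone circle. Values near +/-1 indicate a tight
#' (possibly reflected) circular relationship.
#'
#' @param a,b pitch-class vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
circular_cor_pc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  x <- 2 * pi * a / 12
  y <- 2 * pi * b / 12
  num <- 0; dx <- 0; dy <- 0
  n <- length(x)
  # O(n^2) pair sum is fine at the problem sizes used here (<= a few hundred)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    sx <- sin(x[i] - x[j]); sy <- sin(y[i] - y[j])
    num <- num + sum(sx * sy)
    dx <- dx + sum(sx^2); dy <- dy + sum(sy^2)
  }
  if (dx == 0 || dy == 0) return(NA_real_)
  num / sqrt(dx * dy)
}
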