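#' Bending energy of a closed loop
#'
#' Total bending energy of a circular loop of `L` bending sites (base pairs
#' for DNA), for which the closure constraint fixes the average bend angle to
#' \eqn{\bar\theta = 2\pi/L}.
#'
#' For the worm-like chain (WLC) the energy is \eqn{2\pi^2 L_p / L} (kT) for
#' all `L > 0`.  For the ECH model the WLC form holds while
#' \eqn{\bar\theta \le \theta_a} (i.e. \eqn{L \ge 2\pi/\theta_a}); shorter
#' loops fall on the hull line and cost
#' \eqn{L_p \theta_a (2\pi - L\theta_a/2)} kT, which approaches a constant
#' rather than diverging as \eqn{L \to 0}.  Loops with
#' \eqn{L \le 2\pi/\theta_b} (about 10 bp for DNA) are beyond the model's
#' validity and rejected.
#'
#' @param L loop length(s) in bending sites (bp); vectorised.
#' @param model `"wlc"` or `"ech"`.
#' @param Lp persistence length, bending sites (default 150 bp, dsDNA).
#' @param theta_a hull onset angle in radians (required for `"ech"`).
#' @param theta_b optional upper hull angle, radians; when supplied, ECH
#'   requests with `L <= 2*pi/theta_b` are rejected as out of regime.
#' @return total loop bending energy, kT.
#' @examples
#' loop_energy(150, "wlc")                               # 2*pi^2 ~ 19.74 kT
#' loop_energy(50, "ech", theta_a = 2.2 * pi / 180)      # ~ 30.7 kT
#' @export
loop_energy <- function(L, model = c("wlc", "ech"), Lp = 150,
                        theta_a = NULL, theta_b = NULL) {
  model <- match.arg(model)
  stopifnot(all(L > 0), Lp > 0)
  wlc <- 2 * pi^2 * Lp / L
  if (model == "wlc") return(wlc)
  if (is.null(theta_a) || !is.finite(theta_a) || theta_a <= 0)
    stop("ECH loop energy requires a positive theta_a (radians)", call. = FALSE)
  if (!is.null(theta_b) && any(L <= 2 * pi / theta_b))
    stop("loop shorter than 2*pi/theta_b: outside the ECH model's validity",
         call. = FALSE)
  ifelse(L >= 2 * pi / theta_a,
         wlc,
         Lp * theta_a * (2 * pi - 0.5 * L * theta_a))
}

torsional_factor <- function(L, h, floor = 1e-3) {
  pmax((1 + cos(2 * pi * L / h)) / 2, floor)
}

#' Shimada-Yamakawa cyclization j-factor
#'
#' Closed-form loop-closure probability factor
#' \deqn{j(L) = k\, L_p^{-3} (L_p/L)^5 \exp(-E_{loop}/k_BT + L/(4L_p)),}
#' where the power-law/exponential prefactor is the entropic contribution of
#' the looping geometries and \eqn{E_{loop}} is the bending cost from
#' [loop_energy()].  The prefactor `k` subsumes the loop-closure geometry and
#' experimental details; `j` is in relative units unless `k` has been
#' calibrated against measured j-factors with [fit_k()].
#'
#' To compare with cyclization experiments at non-integer numbers of helical
#' repeats, the torsionally independent curve can be modulated by the helical
#' phase factor \eqn{(1+\cos(2\pi L/h))/2} (clamped below at
#' `modulation_floor` so `j` stays positive); `modulation = "none"` gives the
#' envelope.  Ratios at equal helical phase are unaffected by any
#' multiplicative modulation.
#'
#' @inheritParams loop_energy
#' @param k positive prefactor (1 for relative units).
#' @param modulation `"none"` (envelope) or `"cosine"`.
#' @param h helical repeat, bp per turn (default 10).
#' @param modulation_floor lower clamp for the cosine factor.
#' @return j-factor value(s), relative units (times `k`).
#' @export
jfactor <- function(L, model = c("wlc", "ech"), Lp = 150, theta_a = NULL,
                    theta_b = NULL, k = 1,
                    modulation = c("none", "cosine"), h = 10,
                    modulation_floor = 1e-3) {
  modulation <- match.arg(modulation)
  stopifnot(k > 0, Lp > 0)
  E <- loop_energy(L, model, Lp = Lp, theta_a = theta_a, theta_b = theta_b)
  j <- k * Lp^(-3) * (Lp / L)^5 * exp(-E + L / (4 * Lp))
  if (modulation == "cosine") j <- j * torsional_factor(L, h, modulation_floor)
  j
}

#' j-factor ratio between two loop lengths
#'
#' \eqn{j(L_1)/j(L_2)} computed without the prefactor `k`, which cancels by
#' construction.  At integer numbers of helical repeats (or any two lengths
#' of equal helical phase) the torsional modulation cancels as well, so the
#' unmodulated closed form predicts the ratio directly.
#'
#' @param L1,L2 loop lengths, bp.
#' @inheritParams jfactor
#' @return the dimensionless ratio.
#' @examples
#' jfactor_ratio(40, 50, "ech", theta_a = 2.2 * pi / 180)   # ~ 0.993
#' jfactor_ratio(40, 50, "wlc")                             # ~ 1.12e-6
#' @export
jfactor_ratio <- function(L1, L2, model = c("wlc", "ech"), Lp = 150,
                          theta_a = NULL, theta_b = NULL,
                          modulation = c("none", "cosine"), h = 10,
                          modulation_floor = 1e-3) {
  modulation <- match.arg(modulation)
  jfactor(L1, model, Lp, theta_a, theta_b, k = 1, modulation = modulation,
          h = h, modulation_floor = modulation_floor) /
    jfactor(L2, model, Lp, theta_a, theta_b, k = 1, modulation = modulation,
            h = h, modulation_floor = modulation_floor)
}

#' Loop length minimising the ECH j-factor envelope
#'
#' The ECH envelope (unmodulated j-factor with the linear-branch loop
#' energy) has a stationary minimum at
#' \deqn{L^* = \frac{5}{\,1/(4L_p) + L_p\theta_a^2/2\,},}
#' the balance point between the decreasing entropic penalty and the nearly
#' constant ECH bending cost of small loops.  No such minimum exists for the
#' WLC, whose j-factor falls steeply as \eqn{L \to 0}.
#'
#' @param Lp persistence length, bp.
#' @param theta_a hull onset angle, radians.
#' @return the real-valued minimising loop length, bp.
#' @examples
#' envelope_minimum(150, 2.2 * pi / 180)   # ~ 44.5 bp -> about 45 bp
#' @export
envelope_minimum <- function(Lp, theta_a) {
  stopifnot(is.finite(Lp), Lp > 0, is.finite(theta_a), theta_a >= 0)
  5 / (1 / (4 * Lp) + Lp * theta_a^2 / 2)
}

#' Calibrate the j-factor prefactor against measured data
#'
#' Least-squares fit of `log j` with `k` the only free parameter, which has
#' the closed form: `k` is the geometric mean of the observed over the
#' `k = 1` predicted j-factors.
#'
#' @param L loop lengths of the measurements, bp.
#' @param j measured j-factors (positive).
#' @inheritParams jfactor
#' @return the fitted prefactor `k`.
#' @export
fit_k <- function(L, j, model = c("wlc", "ech"), Lp = 150, theta_a = NULL,
                  theta_b = NULL, modulation = c("none", "cosine"), h = 10,
                  modulation_floor = 1e-3) {
  if (length(L) == 0L) stop("no calibration points supplied", call. = FALSE)
  if (length(L) != length(j))
    stop("L and j must have equal length", call. = FALSE)
  if (any(!is.finite(j)) || any(j <= 0))
    stop("measured j-factors must be positive", call. = FALSE)
  pred <- jfactor(L, model, Lp, theta_a, theta_b, k = 1,
                  modulation = match.arg(modulation), h = h,
                  modulation_floor = modulation_floor)
  exp(mean(log(j) - log(pred)))
}

#' j-factor curve over a range of loop lengths
#'
#' Convenience wrapper evaluating the modulated j-factor and its envelope on
#' a grid of loop lengths.
#'
#' @param L numeric vector of loop lengths, bp.
#' @inheritParams jfactor
#' @return a `data.frame` with columns `L`, `j`, `envelope`.
#' @export
jfactor_curve <- function(L, model = c("wlc", "ech"), Lp = 150,
                          theta_a = NULL, theta_b = NULL, k = 1,
                          modulation = c("cosine", "none"), h = 10,
                          modulation_floor = 1e-3) {
  modulation <- match.arg(modulation)
  env <- jfactor(L, model, Lp, theta_a, theta_b, k = k, modulation = "none")
  j <- if (modulation == "cosine")
    env * torsional_factor(L, h, modulation_floor) else env
  data.frame(L = L, j = j, envelope = env)
}
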