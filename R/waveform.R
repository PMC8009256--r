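## Saccade waveform synthesis.
##
## Velocity profile family v(t) = Vp * sin(pi t / D)^k on t in [0, D]:
## k = 2 is the raised cosine (sin^2 = (1 - cos 2pi s) / 2).  Peak velocity
## follows the main sequence Vp = Vmax * (1 - exp(-A / C)) and duration the
## literature rule D = 2.2 * A + 21 ms; the exponent k is solved so that the
## displacement integral equals the amplitude exactly, which keeps all three
## constraints simultaneously satisfiable (a fixed k cannot).  With the
## default main-sequence constants k stays in ~[1.9, 2.9].

## mean of sin(pi s)^k over s in [0, 1]
zg_profile_mean <- function(k) {
  exp(lgamma((k + 1) / 2) - lgamma(k / 2 + 1)) / sqrt(pi)
}

zg_solve_exponent <- function(m) {
  if (m <= 0.02 || m >= 0.98) {
    stop("main-sequence configuration implies an unattainable velocity ",
         "profile (mean/peak ratio ", signif(m, 3), ")")
  }
  uniroot(function(k) zg_profile_mean(k) - m,
          interval = c(1e-4, 400), tol = 1e-10)$root
}

## amplitude -> (Vp, D, k); the scalar kinematics of one saccade
zg_saccade_kinematics <- function(amplitude, config) {
  vp <- config$main_sequence_vmax * (1 - exp(-amplitude / config$main_sequence_c))
  d_ms <- 2.2 * amplitude + 21
  if (amplitude <= 0) {
    return(list(vp = 0, d_ms = d_ms, k = 2))
  }
  m <- amplitude / (vp * d_ms / 1000)
  list(vp = vp, d_ms = d_ms, k = zg_solve_exponent(m))
}

#' Synthesize a saccade waveform
#'
#' Generates the position samples of a single ballistic movement of the given
#' amplitude and direction at the simulator's sampling rate.  Peak velocity
#' obeys the main sequence `Vmax * (1 - exp(-A / C))`, duration the rule
#' `D = 2.2 * A + 21` ms, and the sampled displacement is rescaled to match
#' the amplitude to machine precision.
#'
#' @param amplitude Movement amplitude in degrees (`>= 0`).
#' @param direction Polar angle of the movement in degrees (counterclockwise
#'   from rightward).
#' @param config A [sim_config()] object (supplies sampling rate and
#'   main-sequence constants).
#' @return A numeric matrix with columns `x`, `y`: position per sample
#'   relative to the movement start.  Attributes: `duration_ms`,
#'   `peak_velocity` (model value, deg/s), `speed` (sampled speed, deg/s),
#'   and `crossing_ms`, the times at which the noise-free speed crosses
#'   20 deg/s (a standard operational saccade-onset criterion, used for the ground-truth logs).
#' @export
#' @examples
#' w <- synthesize_saccade(4, 0, sim_config())
#' attr(w, "peak_velocity")
synthesize_saccade <- function(amplitude, direction, config) {
  if (amplitude < 0) stop("amplitude must be non-negative")
  dt <- 1000 / config$sampling_rate
  kin <- zg_saccade_kinematics(amplitude, config)
  n <- max(2L, as.integer(round(kin$d_ms / dt)))
  if (amplitude == 0) {
    out <- matrix(0, n, 2, dimnames = list(NULL, c("x", "y")))
    attr(out, "duration_ms") <- kin$d_ms
    attr(out, "peak_velocity") <- 0
    attr(out, "speed") <- rep(0, n)
    attr(out, "crossing_ms") <- c(0, kin$d_ms)
    return(out)
  }
  ## midpoint-sampled velocity, integrated and rescaled to the exact amplitude
  tm <- (seq_len(n) - 0.5) * kin$d_ms / n
  v <- kin$vp * sin(pi * tm / kin$d_ms)^kin$k
  disp <- cumsum(v) * kin$d_ms / n / 1000
  scale <- amplitude / disp[n]
  disp <- disp * scale
  th <- direction * pi / 180
  out <- cbind(x = disp * cos(th), y = disp * sin(th))
  ## 20 deg/s crossings of the analytic profile (operational onset/offset)
  vfloor <- 20
  if (kin$vp <= vfloor) {
    crossing <- c(0, kin$d_ms)
  } else {
    s0 <- asin((vfloor / kin$vp)^(1 / kin$k)) / pi
    crossing <- c(s0, 1 - s0) * kin$d_ms
  }
  attr(out, "duration_ms") <- kin$d_ms
  attr(out, "peak_velocity") <- kin$vp
  attr(out, "speed") <- v * scale
  attr(out, "crossing_ms") <- crossing
  out
}

#' Sample a target position
#'
#' Draws the next target center under one of the task's placement schemes.
#' `"full_screen"` draws uniformly over the screen such that the whole
#' `target_window` square remains on-screen.  `"step4deg"` places the target
#' at exactly `step_eccentricity` degrees from `previous_center` at a polar
#' angle uniform over `allowed_polar_sectors`, resampling until the window is
#' fully on-screen.
#'
#' @param previous_center Previous target center, `c(x, y)` degrees.
#' @param scheme `"full_screen"` or `"step4deg"`; defaults to the scheme in
#'   `config`.
#' @param config A [sim_config()] object.
#' @param max_attempts Resampling cap for the step scheme before erroring.
#' @return Numeric `c(x, y)` in degrees.
#' @export
sample_target_position <- function(previous_center, scheme = NULL, config,
                                   max_attempts = 1000) {
  if (is.null(scheme)) scheme <- config$placement_scheme
  half <- config$target_window / 2
  lim <- config$screen_deg / 2 - half
  if (any(lim <= 0)) stop("configuration error: target window larger than screen")
  if (scheme == "full_screen") {
    return(c(runif(1, -lim[1], lim[1]), runif(1, -lim[2], lim[2])))
  }
  sec <- config$allowed_polar_sectors
  widths <- sec[, 2] - sec[, 1]
  for (i in seq_len(max_attempts)) {
    u <- runif(1, 0, sum(widths))
    cum <- cumsum(widths)
    j <- which(u <= cum)[1]
    ang <- sec[j, 1] + (u - c(0, cum)[j])
    th <- ang * pi / 180
    p <- previous_center + config$step_eccentricity * c(cos(th), sin(th))
    if (abs(p[1]) <= lim[1] && abs(p[2]) <= lim[2]) return(p)
  }
  stop("configuration error: could not place target on-screen after ",
       max_attempts, " attempts")
}
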