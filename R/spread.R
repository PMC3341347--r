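#' Expected lifetime reproduction
#'
#' `R0 = seeds_per_year x reproductive_years x survival`: the expected
#' number of offspring reaching adulthood per individual, combining
#' annual fecundity once mature, reproductive lifespan, and survival
#' from seed dispersal to adulthood.
#'
#' @param seeds_per_year Mean annual seed production once mature.
#' @param reproductive_years Length of the reproductive life, years.
#' @param survival Probability of surviving from seed to adulthood,
#'   in `[0, 1]`.
#' @return `R0`, dimensionless.
#' @examples
#' lifetime_R0(800, 80, 0.001)  # 64
#' @export
lifetime_R0 <- function(seeds_per_year, reproductive_years, survival) {
  stopifnot(seeds_per_year >= 0, reproductive_years > 0)
  if (any(survival < 0 | survival > 1))
    stop("survival must lie in [0, 1]", call. = FALSE)
  seeds_per_year * reproductive_years * survival
}

#' Asymptotic migration wave speed under the 2D-t kernel
#'
#' When spread proceeds by jumps from the furthest-forward individual
#' and dispersal follows the fat-tailed 2D-t kernel, the asymptotic
#' front velocity is
#' \deqn{V = \frac{\sqrt{(\pi/2)\, u\, R_0}}{T},}
#' with `T` the generation time (yr), `u` the dispersal parameter (m^2)
#' and `R0` the expected lifetime reproduction. Speeds from large source
#' populations early in an invasion are faster; this is the asymptotic
#' (minimum) rate.
#'
#' @param T_gen Generation time, years.
#' @param u Dispersal parameter, m^2.
#' @param R0 Expected lifetime reproduction (see [lifetime_R0()]).
#' @return Wave speed in metres per year.
#' @examples
#' wave_speed(20, 92, lifetime_R0(800, 80, 0.001))   # ~4.8 m/yr
#' wave_speed(20, 6300, lifetime_R0(800, 80, 0.001)) # ~39.8 m/yr
#' @export
wave_speed <- function(T_gen, u, R0) {
  check_u(u)
  stopifnot(T_gen > 0, R0 > 0)
  sqrt((pi / 2) * u * R0) / T_gen
}

#' Ratio of asymptotic spread rates of two populations
#'
#' For two populations sharing demography (`T`, `R0`) but differing in
#' dispersal parameter, the wave-speed ratio reduces to
#' `sqrt(u1 / u2)`.
#'
#' @param u1,u2 Dispersal parameters, m^2.
#' @return Dimensionless speed ratio.
#' @examples
#' speed_ratio(92, 34.9)   # ~1.6
#' speed_ratio(6300, 92)   # ~8.3
#' @export
speed_ratio <- function(u1, u2) {
  check_u(u1); check_u(u2)
  sqrt(u1 / u2)
}
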