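#' Lighting regimes
#'
#' The four housing regimes supported by the package: standard light-dark
#' (`LD12_12`), long photoperiod (`LD16_8`), constant darkness (`DD`) and
#' constant light (`LL`).
#'
#' @export
LIGHT_REGIMES <- c("LD12_12", "LD16_8", "DD", "LL")

#' Construct a light schedule
#'
#' A light schedule describes the lighting regime an animal is housed under and
#' the clock anchors needed to convert clock time into Zeitgeber time (ZT,
#' light-driven regimes) or circadian time (CT, constant regimes). All animals
#' are first habituated under LD 12:12, so the lights-on clock time of that
#' acclimation phase is always carried along: under DD/LL it anchors CT0 (the
#' former lights-on) and thereby the subjective day (CT0-CT12).
#'
#' @param regime One of `"LD12_12"`, `"LD16_8"`, `"DD"`, `"LL"`.
#' @param lights_on_clock Clock hour-of-day (0-24) at which lights turn on;
#'   used for light-driven regimes. Ignored (set to `NA`) under DD/LL.
#' @param acclimation_lights_on Clock hour-of-day of lights-on during the
#'   LD 12:12 acclimation phase; defaults to `lights_on_clock`.
#' @return An object of class `light_schedule` with fields `regime`,
#'   `cycle_length` (24 h), `lights_on_clock`, `photoperiod` (hours of light
#'   per cycle: 12, 16, 0 or 24) and `acclimation_lights_on`.
#' @examples
#' light_schedule("LD12_12", lights_on_clock = 8)
#' light_schedule("DD", acclimation_lights_on = 8)
#' @export
light_schedule <- function(regime = LIGHT_REGIMES, lights_on_clock = 8,
                           acclimation_lights_on = lights_on_clock) {
  regime <- match.arg(regime)
  stopifnot_scalar(lights_on_clock, "lights_on_clock", 0, 24)
  stopifnot_scalar(acclimation_lights_on, "acclimation_lights_on", 0, 24)
  photoperiod <- switch(regime, LD12_12 = 12, LD16_8 = 16, DD = 0, LL = 24)
  driven <- photoperiod > 0 && photoperiod < 24
  structure(
    list(regime = regime,
         cycle_length = 24,
         lights_on_clock = if (driven) lights_on_clock %% 24 else NA_real_,
         photoperiod = photoperiod,
         acclimation_lights_on = acclimation_lights_on %% 24),
    class = "light_schedule")
}

is_driven <- function(schedule) {
  schedule$photoperiod > 0 && schedule$photoperiod < schedule$cycle_length
}

#' Clock hour of lights-off under a light-driven regime
#' @param schedule A [light_schedule()].
#' @return Hour-of-day of lights-off, or `NA` under constant regimes.
#' @export
lights_off_clock <- function(schedule) {
  if (!is_driven(schedule)) return(NA_real_)
  (schedule$lights_on_clock + schedule$photoperiod) %% 24
}

# Clock anchor of (subjective) day start: lights-on for driven regimes,
# acclimation lights-on for constant regimes.
day_anchor_clock <- function(schedule) {
  if (is_driven(schedule)) schedule$lights_on_clock else schedule$acclimation_lights_on
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule: %s (%g h light / %g h cycle)\n",
              x$regime, x$photoperiod, x$cycle_length))
  if (is_driven(x))
    cat(sprintf("  lights on %05.2f h, off %05.2f h\n",
                x$lights_on_clock, lights_off_clock(x)))
  cat(sprintf("  acclimation lights-on anchor: %05.2f h\n", x$acclimation_lights_on))
  invisible(x)
}
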