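#' MTY probe model
#'
#' Forward model of Mito Thermo Yellow fluorescence. The dye's emission
#' falls approximately linearly with temperature; the rendered signal is
#'
#' `F(t) = quench_factor * gain * (1 - relative_slope * (T - T_ref)
#'         - quad_coeff * (T - T_ref)^2) * exp(-bleach_rate * t)
#'         + autofluorescence + noise`
#'
#' The optional quadratic term models the mild deviation from linearity
#' seen at high temperature; it defaults to 0 (pure linear response).
#'
#' @param gain Fluorescence at the reference temperature, arbitrary units
#'   (AU, > 0).
#' @param relative_slope Fractional fluorescence loss per degC (0 < s < 0.1).
#' @param reference_temperature Temperature at which fluorescence equals
#'   `gain`, degC.
#' @param autofluorescence Additive temperature-independent background, AU.
#' @param bleach_rate Photobleaching rate, per second (>= 0).
#' @param leakage If `TRUE`, adds an unbounded slowly rising component after
#'   the drug event (dye leakage/redistribution artifact that defeats
#'   plateau detection).
#' @param quench_factor Multiplicative drug-quenching factor (default 1;
#'   e.g. bongkrekic acid quenches MTY even cell-free).
#' @param quad_coeff Optional mild quadratic temperature coefficient
#'   (per degC^2, default 0).
#' @param leak_rate Leakage rise rate as a fraction of `gain` per second
#'   (used only when `leakage = TRUE`).
#' @return An object of class `mty_probe`.
#' @export
mty_probe <- function(gain = 1000, relative_slope = 0.025,
                      reference_temperature = 37, autofluorescence = 50,
                      bleach_rate = 0, leakage = FALSE, quench_factor = 1,
                      quad_coeff = 0, leak_rate = 5e-5) {
  if (!is_number(gain) || gain <= 0) abort_validation("gain must be > 0")
  if (!is_number(relative_slope) || relative_slope <= 0 || relative_slope >= 0.1) {
    abort_validation("relative_slope must satisfy 0 < s < 0.1 per degC")
  }
  stopifnot_number(reference_temperature, "reference_temperature", 0, 60)
  stopifnot_number(autofluorescence, "autofluorescence", 0)
  stopifnot_number(bleach_rate, "bleach_rate", 0)
  if (!is_number(quench_factor) || quench_factor <= 0) {
    abort_validation("quench_factor must be > 0")
  }
  structure(
    list(gain = gain, relative_slope = relative_slope,
         reference_temperature = reference_temperature,
         autofluorescence = autofluorescence, bleach_rate = bleach_rate,
         leakage = isTRUE(leakage), quench_factor = quench_factor,
         quad_coeff = quad_coeff, leak_rate = leak_rate),
    class = "mty_probe"
  )
}

#' mito-gTEMP probe model
#'
#' Forward model of the ratiometric reporter pair: temperature-insensitive
#' mT-Sapphire and temperature-sensitive Sirius, co-expressed at a common
#' per-trial level. Channels are rendered as
#'
#' `F_sap(t) = expression * sapphire_gain + A_sap + noise`
#' `F_sir(t) = expression / (1 + sirius_slope * (T - T_ref)) + A_sir + noise`
#'
#' Sirius is strictly decreasing in temperature (and close to linear for
#' small slopes); the reciprocal-affine form makes the Sapphire/Sirius
#' ratio exactly affine in temperature with zero backgrounds:
#' `R(T) = sapphire_gain * (1 + sirius_slope * (T - T_ref))`, so the linear
#' ratio calibration is the exact inverse of the rendering model. With zero
#' backgrounds the ratio is independent of the expression level.
#'
#' @param expression Per-trial expression level, AU (> 0).
#' @param sirius_slope Fractional Sirius sensitivity per degC (0 < s < 0.1).
#' @param sapphire_gain Temperature-insensitive Sapphire gain relative to
#'   expression (dimensionless, > 0).
#' @param reference_temperature Reference temperature, degC.
#' @param channel_backgrounds Length-2 numeric `(sapphire, sirius)` additive
#'   backgrounds, AU (>= 0).
#' @param drug_background_shift Length-2 numeric `(sapphire, sirius)` shift
#'   applied to cell-free blanks when a drug is present (models e.g. the
#'   antimycin background artifact).
#' @return An object of class `gtemp_probe`.
#' @export
gtemp_probe <- function(expression = 1000, sirius_slope = 0.025,
                        sapphire_gain = 1, reference_temperature = 37,
                        channel_backgrounds = c(sapphire = 0, sirius = 0),
                        drug_background_shift = c(sapphire = 0, sirius = 0)) {
  if (!is_number(expression) || expression <= 0) {
    abort_validation("expression must be > 0")
  }
  if (!is_number(sirius_slope) || sirius_slope <= 0 || sirius_slope >= 0.1) {
    abort_validation("sirius_slope must satisfy 0 < s < 0.1 per degC")
  }
  if (!is_number(sapphire_gain) || sapphire_gain <= 0) {
    abort_validation("sapphire_gain must be > 0")
  }
  stopifnot_number(reference_temperature, "reference_temperature", 0, 60)
  if (length(channel_backgrounds) != 2L || any(channel_backgrounds < 0)) {
    abort_validation("channel_backgrounds must be two non-negative numbers")
  }
  if (length(drug_background_shift) != 2L) {
    abort_validation("drug_background_shift must have length 2")
  }
  structure(
    list(expression = expression, sirius_slope = sirius_slope,
         sapphire_gain = sapphire_gain,
         reference_temperature = reference_temperature,
         channel_backgrounds = stats::setNames(as.numeric(channel_backgrounds),
                                               c("sapphire", "sirius")),
         drug_background_shift = stats::setNames(as.numeric(drug_background_shift),
                                                 c("sapphire", "sirius"))),
    class = "gtemp_probe"
  )
}

#' Closed-form ratio calibration implied by a gTEMP probe model
#'
#' With zero channel backgrounds the rendered Sapphire/Sirius ratio is
#' exactly `c0 + c1 * T` with `c1 = sapphire_gain * sirius_slope` and
#' `c0 = sapphire_gain * (1 - sirius_slope * reference_temperature)`.
#' Useful as the "matching calibration" in zero-noise round-trip checks.
#'
#' @param probe A [gtemp_probe()].
#' @param calibrated_range Temperature range recorded on the calibration,
#'   degC.
#' @return A `ratio_calibration` object (see [fit_ratio_calibration()]).
#' @export
ratio_calibration_from_probe <- function(probe, calibrated_range = c(30, 42)) {
  if (!inherits(probe, "gtemp_probe")) abort_validation("probe must be a gtemp_probe")
  ratio_calibration(
    c0 = probe$sapphire_gain * (1 - probe$sirius_slope * probe$reference_temperature),
    c1 = probe$sapphire_gain * probe$sirius_slope,
    calibrated_range = calibrated_range, r_squared = 1, n_replicates = 0
  )
}
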