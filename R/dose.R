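#' Injection dose parameters
#'
#' Parameters of the tracer-dose mixing model: an enriched H2-17O saline
#' solution is injected into a blood volume of
#' `subject_weight_kg * blood_volume_ml_per_kg` mL that already carries
#' the natural abundance of H2-17O, to reach a target intravascular
#' concentration.
#'
#' @param subject_weight_kg Subject weight (kg), > 0.
#' @param blood_volume_ml_per_kg Blood volume per body weight (mL/kg);
#'   default 65, the rat value.
#' @param enrichment_percent Mole-percent H2-17O of the injectate;
#'   default 70.
#' @param target_concentration_percent Target intravascular
#'   concentration (%); default 4.6.
#' @param natural_abundance_percent Background H2-17O mole-percent of
#'   ordinary water; default 0.037.
#' @return An object of class `dose_params`.
#' @export
dose_params <- function(subject_weight_kg,
                        blood_volume_ml_per_kg = 65,
                        enrichment_percent = 70,
                        target_concentration_percent = 4.6,
                        natural_abundance_percent = 0.037) {
  if (subject_weight_kg <= 0) abort_validation("weight must be positive")
  if (blood_volume_ml_per_kg <= 0)
    abort_validation("blood volume per kg must be positive")
  if (!(target_concentration_percent < enrichment_percent &&
        enrichment_percent <= 100))
    abort_validation("need target < enrichment <= 100 (%)")
  if (target_concentration_percent <= 0)
    abort_validation("target concentration must be positive")
  structure(list(subject_weight_kg = subject_weight_kg,
                 blood_volume_ml_per_kg = blood_volume_ml_per_kg,
                 enrichment_percent = enrichment_percent,
                 target_concentration_percent = target_concentration_percent,
                 natural_abundance_percent = natural_abundance_percent),
            class = "dose_params")
}

blood_volume_ml <- function(params)
  params$subject_weight_kg * params$blood_volume_ml_per_kg

#' Injection volume for a target intravascular concentration
#'
#' Solves the mixing model
#' `(V * E + BV * c_nat) / (V + BV) = C_target` for the injectate
#' volume: `V = BV * (C_target - c_nat) / (E - C_target)` with
#' `BV = weight * blood_volume_per_kg`. Setting
#' `include_background = FALSE` drops the natural-abundance term
#' (`V = BV * C_target / (E - C_target)`) for comparison.
#'
#' @param params A [dose_params()].
#' @param include_background Include the natural-abundance background of
#'   blood water in the mixing balance (default `TRUE`).
#' @return Injection volume (mL).
#' @export
dose_volume <- function(params, include_background = TRUE) {
  stopifnot(inherits(params, "dose_params"))
  c_nat <- if (include_background) params$natural_abundance_percent else 0
  if (params$target_concentration_percent <= c_nat)
    abort_validation(
      "target concentration does not exceed the background; nothing to inject")
  bv <- blood_volume_ml(params)
  bv * (params$target_concentration_percent - c_nat) /
    (params$enrichment_percent - params$target_concentration_percent)
}

#' Intravascular concentration after injecting a given volume
#'
#' The forward mixing model `(V * E + BV * c_nat) / (V + BV)`; the exact
#' inverse of [dose_volume()].
#'
#' @param volume_ml Injected volume (mL), >= 0.
#' @param params A [dose_params()].
#' @param include_background As in [dose_volume()].
#' @return Intravascular H2-17O concentration (%).
#' @export
intravascular_concentration <- function(volume_ml, params,
                                        include_background = TRUE) {
  stopifnot(inherits(params, "dose_params"))
  if (any(volume_ml < 0)) abort_validation("volume must be >= 0")
  c_nat <- if (include_background) params$natural_abundance_percent else 0
  bv <- blood_volume_ml(params)
  (volume_ml * params$enrichment_percent + bv * c_nat) / (volume_ml + bv)
}

#' Molality of H2-17O at a given mole-percent abundance
#'
#' Converts a mole-percent abundance of H2-17O among water molecules
#' into micromoles of H2-17O per gram of water: with a water molar mass
#' of 18.0 g/mol, natural abundance (0.037%) corresponds to 20.56
#' umol/g.
#'
#' @param abundance_percent Mole-percent of H2-17O; default the 0.037%
#'   natural abundance.
#' @param water_molar_mass_g Molar mass of water (g/mol), default 18.0.
#' @return Micromoles of H2-17O per gram of water.
#' @export
natural_abundance_molality <- function(abundance_percent = 0.037,
                                       water_molar_mass_g = 18.0) {
  if (abundance_percent < 0) abort_validation("abundance must be >= 0")
  abundance_percent / 100 / water_molar_mass_g * 1e6
}
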