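#' Bile flow from a timed gallbladder-cannulation collection
#'
#' Collected bile is weighed; flow = mass / duration at an assumed density
#' (1.0 g/mL by default, so mg/min equals uL/min).
#'
#' @param bile_mass_mg Collected bile mass, mg, >= 0.
#' @param duration_min Collection duration, minutes, > 0 (20 by default).
#' @param density_g_ml Bile density, g/mL.
#' @return Flow in uL/min.
#' @export
bile_flow <- function(bile_mass_mg, duration_min = 20, density_g_ml = 1.0) {
  stopifnot(duration_min > 0, density_g_ml > 0, all(bile_mass_mg >= 0))
  bile_mass_mg / density_g_ml / duration_min
}

#' Biliary secretion rate normalized to 100 g body weight
#'
#' Secretion = bile flow x biliary concentration; with flow in uL/min and
#' concentration in mM (nmol/uL) the product is nmol/min, normalized here
#' per 100 g body weight (the field's convention; the normalization basis
#' is a choice, not a measurement).
#'
#' @param flow_ul_min Bile flow, uL/min.
#' @param conc_mM Biliary concentration of the species (bile acid,
#'   cholesterol or phospholipid), mM.
#' @param body_weight_g Body weight, g, > 0.
#' @return Secretion rate, nmol/min per 100 g body weight.
#' @export
biliary_secretion_rate <- function(flow_ul_min, conc_mM, body_weight_g) {
  stopifnot(all(flow_ul_min >= 0), all(conc_mM >= 0), all(body_weight_g > 0))
  flow_ul_min * conc_mM * 100 / body_weight_g
}

#' Fecal sterol excretion rate normalized to 100 g body weight
#'
#' Excretion = daily feces production x sterol content of the feces,
#' normalized per 100 g body weight. Applies equally to neutral sterols
#' and bile acids.
#'
#' @param feces_g_day Feces produced per day, g/day, >= 0.
#' @param content_umol_g Sterol content, umol per g feces, >= 0.
#' @param body_weight_g Body weight, g, > 0.
#' @return Excretion rate, umol/day per 100 g body weight.
#' @export
fecal_excretion_rate <- function(feces_g_day, content_umol_g, body_weight_g) {
  stopifnot(all(feces_g_day >= 0), all(content_umol_g >= 0),
            all(body_weight_g > 0))
  feces_g_day * content_umol_g * 100 / body_weight_g
}
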