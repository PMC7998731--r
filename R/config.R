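#' Study configuration for a pharmacokinetic characterization
#'
#' Bundles the compound-level physicochemical and binding parameters together
#' with the dosing design. All downstream stages (molar conversions, the
#' well-stirred liver model, Rodgers-Rowland partition prediction, the PBPK
#' simulator) draw their compound inputs from this object.
#'
#' @param compound Compound name (free text).
#' @param molecular_weight Molecular weight, g/mol (> 0).
#' @param logP Octanol:water log partition coefficient.
#' @param pKa Acid dissociation constant of the ionizable group.
#' @param compound_type One of `"monoprotic acid"`, `"monoprotic base"`,
#'   `"neutral"`; governs the ionization terms in partition prediction.
#' @param fu_plasma Unbound fraction in plasma, in (0, 1].
#' @param fu_mic Unbound fraction in the microsomal incubation, in (0, 1].
#' @param blood_plasma_ratio Blood-to-plasma concentration ratio R (> 0).
#' @param dose Dose in mg/kg (>= 0).
#' @param route Administration route, `"iv"` or `"po"`.
#' @param body_weight_ref Reference body weight in kg (default 0.25, rat).
#' @param seed Non-negative integer seed for any downstream simulation.
#' @return A validated object of class `study_config`.
#' @examples
#' cfg <- study_config(
#'   compound = "supinoxin", molecular_weight = 441.465, logP = 2.7,
#'   pKa = 1.5, compound_type = "monoprotic acid", fu_plasma = 0.0363,
#'   fu_mic = 0.623, dose = 5, route = "po"
#' )
#' @export
study_config <- function(compound,
                         molecular_weight,
                         logP,
                         pKa,
                         compound_type = c("neutral", "monoprotic acid", "monoprotic base"),
                         fu_plasma,
                         fu_mic = 1,
                         blood_plasma_ratio = 1,
                         dose = 0,
                         route = c("iv", "po"),
                         body_weight_ref = 0.25,
                         seed = 0L) {
  compound_type <- match.arg(compound_type)
  route <- match.arg(route)
  stopifnot(is.character(compound), length(compound) == 1L, nzchar(compound))
  assert_scalar(molecular_weight, "molecular_weight", lo = 0, lo_open = TRUE)
  assert_scalar(logP, "logP")
  assert_scalar(pKa, "pKa")
  assert_scalar(fu_plasma, "fu_plasma", lo = 0, hi = 1, lo_open = TRUE)
  assert_scalar(fu_mic, "fu_mic", lo = 0, hi = 1, lo_open = TRUE)
  assert_scalar(blood_plasma_ratio, "blood_plasma_ratio", lo = 0, lo_open = TRUE)
  assert_scalar(dose, "dose", lo = 0)
  assert_scalar(body_weight_ref, "body_weight_ref", lo = 0, lo_open = TRUE)
  assert_scalar(seed, "seed", lo = 0)
  structure(
    list(
      compound = compound,
      molecular_weight = molecular_weight,
      logP = logP,
      pKa = pKa,
      compound_type = compound_type,
      fu_plasma = fu_plasma,
      fu_mic = fu_mic,
      blood_plasma_ratio = blood_plasma_ratio,
      dose = dose,
      route = route,
      body_weight_ref = body_weight_ref,
      seed = as.integer(seed)
    ),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>", x$compound, "\n")
  cat(sprintf("  MW %.3f g/mol | logP %.2f | pKa %.2f | %s\n",
              x$molecular_weight, x$logP, x$pKa, x$compound_type))
  cat(sprintf("  fu,p %.4f | fu,mic %.3f | B/P %.2f\n",
              x$fu_plasma, x$fu_mic, x$blood_plasma_ratio))
  cat(sprintf("  dose %g mg/kg %s | ref BW %g kg | seed %d\n",
              x$dose, x$route, x$body_weight_ref, x$seed))
  invisible(x)
}

#' Read a study configuration from a YAML file
#'
#' Mandatory keys: `compound`, `molecular_weight`, `logP`, `pKa`,
#' `compound_type`, `fu_plasma`. Optional keys default to `fu_mic = 1`,
#' `blood_plasma_ratio = 1`, `dose = 0`, `route = "iv"`,
#' `body_weight_ref = 0.25`, `seed = 0`.
#'
#' @param path Path to a YAML file.
#' @return A validated `study_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  mandatory <- c("compound", "molecular_weight", "logP", "pKa",
                 "compound_type", "fu_plasma")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing)) {
    stop("config is missing mandatory key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(fu_mic = 1, blood_plasma_ratio = 1, dose = 0, route = "iv",
                   body_weight_ref = 0.25, seed = 0L)
  for (key in names(defaults)) {
    if (is.null(raw[[key]])) raw[[key]] <- defaults[[key]]
  }
  do.call(study_config, raw[c(mandatory, names(defaults))])
}

#' The shipped example study configuration (supinoxin in the rat)
#'
#' Reads the packaged YAML config for supinoxin: MW 441.465 g/mol, logP 2.7,
#' pKa 1.5 (monoprotic acid), plasma unbound fraction 0.0363, microsomal
#' unbound fraction 0.623, blood-to-plasma ratio 1.
#'
#' @param dose Dose in mg/kg to stamp on the config (default 5).
#' @param route `"iv"` or `"po"` (default `"po"`).
#' @return A `study_config`.
#' @export
supinoxin_config <- function(dose = 5, route = "po") {
  cfg <- read_config(ratpbpk_extdata("study_supinoxin.yaml"))
  cfg$dose <- dose
  cfg$route <- match.arg(route, c("iv", "po"))
  cfg
}
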