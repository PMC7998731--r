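# Tissue partitioning: Kp from AUC ratios, steady-state volume
# reconstruction from Kp x volume sums, and mechanistic Kp prediction for
# unsampled tissues by the Rodgers-Rowland tissue-composition method.

#' Tissue-to-plasma partition coefficient from AUC ratio
#'
#' `Kp = AUC_tissue / AUC_plasma`, the distributional-equilibrium estimate
#' from matched mean exposure profiles.
#'
#' @param auc_tissue Tissue AUC, ug.h/mL (> 0). Vectorized.
#' @param auc_plasma Plasma AUC, ug.h/mL (> 0).
#' @return Kp (dimensionless).
#' @export
kp_from_auc <- function(auc_tissue, auc_plasma) {
  if (!is.numeric(auc_plasma) || length(auc_plasma) != 1L || auc_plasma <= 0) {
    stop("`auc_plasma` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(auc_tissue)) || any(auc_tissue <= 0)) {
    stop("tissue AUCs must be positive and finite", call. = FALSE)
  }
  auc_tissue / auc_plasma
}

#' The shipped observed tissue partition table (supinoxin, oral 5 mg/kg)
#'
#' Mean tissue AUC(0-24h), Kp, literature rat tissue volume, and the tabulated
#' Kp x volume product for plasma and ten sampled tissues, as reported for
#' the oral 5 mg/kg rat distribution study.
#'
#' @return A data frame of class `tissue_kp_table` with columns `tissue`,
#'   `auc_0_24_ug_h_mL`, `kp`, `volume_mL_kg`, `kp_x_volume_mL_kg`,
#'   `provenance`.
#' @export
rat_tissue_kp <- function() {
  df <- utils::read.csv(ratpbpk_extdata("rat_tissue_kp.csv"),
                        stringsAsFactors = FALSE)
  class(df) <- c("tissue_kp_table", "data.frame")
  df
}

#' Steady-state distribution volume reconstructed from Kp x volume sums
#'
#' `Vd = sum(Kp_T * V_T)` over the listed tissues, plus the plasma row
#' (Kp = 1 at the plasma volume) when present/included. `products =
#' "computed"` takes the dot product of the Kp and volume columns;
#' `"tabulated"` sums a pre-computed `kp_x_volume_mL_kg` column when the
#' table carries one (the two differ only by table-level rounding).
#'
#' @param table A data frame with columns `tissue`, `kp`, `volume_mL_kg` and
#'   optionally `kp_x_volume_mL_kg`.
#' @param include_plasma Keep the plasma row in the sum (default `TRUE`).
#' @param products `"computed"` (default) or `"tabulated"`.
#' @return Vd in mL/kg.
#' @export
vss_from_kp <- function(table, include_plasma = TRUE,
                        products = c("computed", "tabulated")) {
  products <- match.arg(products)
  stopifnot(is.data.frame(table), all(c("tissue", "kp", "volume_mL_kg") %in% names(table)))
  if (!include_plasma) {
    table <- table[tolower(table$tissue) != "plasma", , drop = FALSE]
  }
  if (any(is.na(table$volume_mL_kg))) {
    stop("missing tissue volume for: ",
         paste(table$tissue[is.na(table$volume_mL_kg)], collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(table$kp) | table$kp <= 0)) {
    stop("missing or non-positive Kp for: ",
         paste(table$tissue[is.na(table$kp) | table$kp <= 0], collapse = ", "),
         call. = FALSE)
  }
  if (products == "tabulated") {
    if (!"kp_x_volume_mL_kg" %in% names(table)) {
      stop("table has no `kp_x_volume_mL_kg` column", call. = FALSE)
    }
    return(sum(table$kp_x_volume_mL_kg))
  }
  sum(table$kp * table$volume_mL_kg)
}

#' The shipped rat tissue-composition table for partition prediction
#'
#' Fractional tissue volumes of extracellular and intracellular water,
#' neutral lipids and neutral phospholipids, the tissue-to-plasma albumin
#' ratio, and intracellular pH, for the standard rat tissues, from the
#' published tissue-composition compilation underlying the Rodgers-Rowland
#' method (Rodgers & Rowland, J Pharm Sci 2006). The `plasma` row carries the
#' plasma water and lipid fractions used as the reference phase.
#'
#' @return A data frame with columns `tissue`, `f_ew`, `f_iw`, `f_nl`,
#'   `f_np`, `albumin_ratio`, `ph_iw`.
#' @export
rat_tissue_composition <- function() {
  utils::read.csv(ratpbpk_extdata("rat_tissue_composition.csv"),
                  stringsAsFactors = FALSE)
}

#' Predict tissue-to-plasma partition coefficients from tissue composition
#'
#' Mechanistic Kp prediction in the Rodgers-Rowland framework for neutral
#' compounds, monoprotic acids, and weak monoprotic bases - the classes whose
#' tissue binding is dominated by partitioning into tissue water and neutral
#' lipids plus association with extracellular albumin. The unbound
#' tissue-to-plasma water ratio is
#'
#' `Kpu = f_EW + (X_iw / Y_p) f_IW + (P f_NL + (0.3 P + 0.7) f_NP) / Y_p +
#'        (1/fu - 1 - (P f_NL,p + (0.3 P + 0.7) f_NP,p) / Y_p) * AR_T`
#'
#' with `P = 10^logP` (for adipose the vegetable-oil partition coefficient
#' `log P_vow = 1.115 logP - 1.35` replaces P in the neutral-lipid term),
#' Henderson-Hasselbalch ionization terms `X`/`Y` evaluated at intracellular
#' and plasma pH, and `AR_T` the tissue-to-plasma albumin ratio; the reported
#' `Kp = Kpu * fu`. Strong bases (pKa > 7), whose intracellular acidic-
#' phospholipid binding requires blood-cell partitioning data, are refused
#' with an explicit error.
#'
#' @param config A [study_config()] supplying `logP`, `pKa`, `compound_type`,
#'   `fu_plasma`.
#' @param tissues Character vector of tissue names to predict (must appear in
#'   the composition table); default skin and bone.
#' @param composition Tissue-composition table; defaults to
#'   [rat_tissue_composition()].
#' @param ph_plasma Plasma pH (default 7.4).
#' @return A data frame with columns `tissue`, `kpu`, `kp`, `provenance`.
#' @export
rr_kp_predict <- function(config, tissues = c("skin", "bone"),
                          composition = rat_tissue_composition(),
                          ph_plasma = 7.4) {
  stopifnot(inherits(config, "study_config"))
  plasma <- composition[composition$tissue == "plasma", , drop = FALSE]
  if (nrow(plasma) != 1L) stop("composition table needs one `plasma` row", call. = FALSE)
  p_oct <- 10^config$logP
  ion_terms <- function(ph) {
    switch(config$compound_type,
      "neutral" = 1,
      "monoprotic acid" = 1 + 10^(ph - config$pKa),
      "monoprotic base" = {
        if (config$pKa > 7) {
          stop("unsupported compound class: strong monoprotic base (pKa > 7) ",
               "requires the acidic-phospholipid binding equations",
               call. = FALSE)
        }
        1 + 10^(config$pKa - ph)
      }
    )
  }
  y_p <- ion_terms(ph_plasma)
  fu <- config$fu_plasma
  plasma_lipid <- (p_oct * plasma$f_nl + (0.3 * p_oct + 0.7) * plasma$f_np) / y_p
  out <- lapply(tissues, function(tn) {
    row <- composition[composition$tissue == tn, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("tissue '", tn, "' not found in the composition table", call. = FALSE)
    }
    x_iw <- ion_terms(row$ph_iw)
    p_nl <- if (tn == "adipose") 10^(1.115 * config$logP - 1.35) else p_oct
    kpu <- row$f_ew +
      (x_iw / y_p) * row$f_iw +
      (p_nl * row$f_nl + (0.3 * p_oct + 0.7) * row$f_np) / y_p +
      (1 / fu - 1 - plasma_lipid) * row$albumin_ratio
    data.frame(tissue = tn, kpu = kpu, kp = kpu * fu,
               provenance = "predicted", stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(!is.finite(res$kp) | res$kp <= 0)) {
    stop("partition prediction produced a non-positive Kp", call. = FALSE)
  }
  res
}
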