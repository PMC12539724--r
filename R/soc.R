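# 1 ton/acre = 907.18474 kg / 4046.8564224 m^2 = 2.2417022... Mg/ha
TONS_ACRE_TO_MG_HA <- 0.90718474 / 0.40468564224

#' Parameters of the biomass-partition SOC model
#'
#' A winter cover crop leaves aboveground biomass `AG` and belowground
#' biomass `BG` (lbs/acre). A fraction `P` of the aboveground residue stays
#' on the surface to satisfy the conservation-tillage residue threshold; the
#' rest is incorporated. Incorporated plus belowground biomass carries a
#' carbon concentration `Conc`, and a fraction `E` of that carbon survives
#' microbial processing into stable soil organic matter. Defaults are the
#' conservative literature values: AG = 3500, BG = 1747 lbs/acre, P = 0.30,
#' Conc = 0.50, E = 0.50.
#'
#' @param AG aboveground biomass, lbs/acre.
#' @param BG belowground biomass, lbs/acre.
#' @param P surface-residue fraction retained (not incorporated).
#' @param Conc carbon concentration of the biomass.
#' @param E microbial (humification) efficiency.
#' @param lbs_per_ton pounds per ton (2000).
#' @return a validated `soc_params` object.
#' @export
soc_params <- function(AG = 3500, BG = 1747, P = 0.30, Conc = 0.50,
                       E = 0.50, lbs_per_ton = 2000) {
  if (lbs_per_ton <= 0) stop("`lbs_per_ton` must be > 0", call. = FALSE)
  if (AG < 0 || BG < 0) stop("biomasses must be >= 0", call. = FALSE)
  if (!is_proportion(c(P, Conc, E))) {
    stop("P, Conc and E must lie in [0, 1]", call. = FALSE)
  }
  structure(list(AG = AG, BG = BG, P = P, Conc = Conc, E = E,
                 lbs_per_ton = lbs_per_ton), class = "soc_params")
}

#' Biomass-total parameterization
#'
#' Alternative constructor: total biomass `B` plus the aboveground fraction.
#' The defaults reproduce the standard AG = 3500 / BG = 1747 split.
#'
#' @param B total biomass, lbs/acre.
#' @param ag_fraction share of `B` aboveground (nominally 2/3).
#' @param ... passed to [soc_params()].
#' @return a `soc_params` object.
#' @export
soc_params_biomass <- function(B = 5247, ag_fraction = 3500 / 5247, ...) {
  soc_params(AG = B * ag_fraction, BG = B * (1 - ag_fraction), ...)
}

#' SOC sequestration rate
#'
#' The per-acre chain: incorporated aboveground residue `AG * (1 - P)` plus
#' belowground biomass `BG`, times carbon concentration `Conc`, times
#' microbial efficiency `E`, over 2000 lbs/ton. The result is independent of
#' the acreage it is later applied to. Defaults give 0.524625, printed 0.52
#' tons C/acre/year.
#'
#' @param params a `soc_params` object.
#' @return rate in tons C/acre/year.
#' @export
soc_rate <- function(params = soc_params()) {
  stopifnot(inherits(params, "soc_params"))
  (params$AG * (1 - params$P) + params$BG) * params$Conc * params$E /
    params$lbs_per_ton
}

#' Full model chain for one acreage value
#'
#' Exposes every intermediate quantity of the model for a cover-crop acreage
#' `CCA`: total above/belowground biomass in tons (`T_AG`, `T_BG`,
#' `T_AG_BG`), incorporated aboveground biomass (`I_AG`), biomass reaching
#' the soil (`T_BS`), carbon input (`C_S`), carbon after microbial
#' processing (`T_SCM`), and the rate `R = T_SCM / CCA`.
#'
#' @param CCA cover-crop acreage (acres, >= 0).
#' @param params a `soc_params`.
#' @return one-row data frame of all intermediates.
#' @export
soc_components <- function(CCA, params = soc_params()) {
  stopifnot(CCA >= 0)
  T_AG <- params$AG * CCA / params$lbs_per_ton
  T_BG <- params$BG * CCA / params$lbs_per_ton
  T_AG_BG <- T_AG + T_BG
  I_AG <- T_AG * (1 - params$P)
  T_BS <- T_BG + I_AG
  C_S <- T_BS * params$Conc
  T_SCM <- C_S * params$E
  data.frame(CCA = CCA, T_AG = T_AG, T_BG = T_BG, T_AG_BG = T_AG_BG,
             I_AG = I_AG, T_BS = T_BS, C_S = C_S, T_SCM = T_SCM,
             R = ifelse(CCA > 0, T_SCM / CCA, soc_rate(params)))
}

#' Yearly SOC sequestration table
#'
#' Applies the model to an acreage table with any of the columns
#' `government_acres`, `voluntary_acres`, `total_acres`, adding a matching
#' `*_soc` column (tons C) for each. Rows with negative acreage in a column
#' are excluded from that column's SOC (NA) with a warning. Because the
#' model is linear in acreage, total SOC equals government plus voluntary
#' SOC whenever the acreages add up.
#'
#' @param acres data frame with a `year` column and acreage columns.
#' @param params a `soc_params`.
#' @return the input with `*_soc` columns appended; attribute `rate` holds
#'   the tons C/acre/year applied.
#' @export
soc_table <- function(acres, params = soc_params()) {
  stopifnot(is.data.frame(acres), "year" %in% names(acres))
  rate <- soc_rate(params)
  out <- acres
  for (col in c("government_acres", "voluntary_acres", "total_acres")) {
    if (!col %in% names(acres)) next
    a <- acres[[col]]
    soc <- rate * a
    if (any(a < 0, na.rm = TRUE)) {
      warning(sum(a < 0, na.rm = TRUE), " negative acreage row(s) in ", col,
              " excluded from SOC", call. = FALSE)
      soc[a < 0] <- NA_real_
    }
    out[[sub("_acres$", "_soc", col)]] <- soc
  }
  attr(out, "rate") <- rate
  out
}

#' Convert a sequestration rate between tons/acre and Mg/ha
#'
#' 1 ton/acre/year = 2.2417022 Mg/ha/year (907.18474 kg/ton over
#' 0.40468564224 ha/acre). Round-trip conversion is the identity.
#'
#' @param rate non-negative rate.
#' @param to `"Mg_ha"` (from tons/acre) or `"tons_acre"` (from Mg/ha).
#' @return converted rate.
#' @export
convert_rate <- function(rate, to = c("Mg_ha", "tons_acre")) {
  stopifnot(all(rate >= 0))
  to <- match.arg(to)
  if (to == "Mg_ha") rate * TONS_ACRE_TO_MG_HA
  else rate / TONS_ACRE_TO_MG_HA
}

#' Published cover-crop SOC sequestration rates
#'
#' Meta-analysis and review rates (tons C/acre/year) shipped as constants
#' for side-by-side reporting against the computed model rate.
#'
#' @return data frame `rate, sd, source, context`.
#' @export
literature_rates <- function() {
  data.frame(
    rate = c(0.14, 0.22, 0.24, 0.25, 0.21, 0.21, 0.30, 0.15),
    sd = c(0.04, NA, NA, NA, NA, 0.25, 0.28, 0.21),
    source = c("Poeplau & Don", "Ruis & Blanco-Canqui", "Jian et al.",
               "Blanco-Canqui", "Blanco-Canqui", "Causarano et al.",
               "Causarano et al.", "Causarano et al."),
    context = c("global meta-analysis, 0-11.8 in",
                "meta-analysis, 0-11.8 in",
                "meta-analysis, varying layers 0-11.8 in",
                "US review, SOC-increasing subset (22 cases)",
                "US review, all 77 comparisons, 0-30 in",
                "cotton systems, no-till vs conventional",
                "cotton systems, no-till + cover crops",
                "cotton systems, no-till alone"),
    stringsAsFactors = FALSE
  )
}
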