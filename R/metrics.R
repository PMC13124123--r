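# Partial regression coefficients of the energy-requirement systems used
# by the different feed-efficiency metrics (ECM, MBW, BWL, BWG, BCS order
# where applicable). The RDC system doubles as the RFI_Index weights.
.coef_rdc <- c(ECM = 0.456, MBW = 0.0508, BWL = -3.25, BWG = 3.25)
.coef_rzfe <- c(ECM = 0.4, BWL = -4.5, BWG = 4.5, DMI = -1)
.coef_rfi_reported <- c(ECM = 0.276, MBW = 0.068, BWL = -3.80, BWG = 1.44)
.mcal_nel_per_kg_ecm <- 0.752      # NRC 2021 eq. 2-1 milk-energy content
.me_per_kg_ecm_kj <- 4765          # kJ ME required per kg ECM

#' Energy-corrected milk
#'
#' Sjaunja-style standardization of milk yield to a fixed energy content
#' (3,140 kJ/kg): `milk * (38.30 fat + 24.20 protein + 16.54 lactose +
#' 20.7) / 3140`, with the contents in g/kg. Percent contents must be
#' multiplied by 10 before calling (4.43% fat = 44.3 g/kg).
#'
#' @param milk milk yield, kg/d.
#' @param fat,protein,lactose milk contents, g/kg.
#' @return ECM, kg/d.
#' @export
ecm <- function(milk, fat, protein, lactose) {
  if (any(c(milk, fat, protein, lactose) < 0, na.rm = TRUE))
    stop("milk yield and contents must be non-negative")
  milk * (38.30 * fat + 24.20 * protein + 16.54 * lactose + 20.7) / 3140
}

#' Metabolic body weight
#'
#' @param bw body weight, kg (> 0).
#' @return `bw^0.75`, kg^0.75.
#' @export
mbw <- function(bw) {
  if (any(bw <= 0, na.rm = TRUE)) stop("body weight must be positive")
  bw^0.75
}

#' Split a daily body-weight change into loss and gain
#'
#' `BWL = max(0, -delta)`, `BWG = max(0, delta)`; at most one of the two
#' is positive for any record, and `BWG - BWL` reconstructs the change.
#'
#' @param delta_bw daily body-weight change, kg/d.
#' @return A list with numeric vectors `BWL` and `BWG`.
#' @export
split_bw_change <- function(delta_bw) {
  if (any(is.infinite(delta_bw) | is.nan(delta_bw)))
    stop("body-weight change must be finite (NA allowed for missing records)")
  list(BWL = pmax(0, -delta_bw), BWG = pmax(0, delta_bw))
}

#' Expected dry-matter intake, Nordic Red requirement formulation
#'
#' `eDMI = 0.456 ECM + 0.0508 MBW - 3.25 BWL + 3.25 BWG` (kg/d), the
#' energy-sink requirement system tailored to Nordic Red feed-intake data.
#'
#' @param ecm ECM, kg/d.
#' @param mbw metabolic body weight, kg^0.75.
#' @param bwl,bwg body-weight loss and gain, kg/d.
#' @return eDMI, kg/d.
#' @export
edmi_rdc <- function(ecm, mbw, bwl, bwg) {
  .coef_rdc["ECM"] * ecm + .coef_rdc["MBW"] * mbw +
    .coef_rdc["BWL"] * bwl + .coef_rdc["BWG"] * bwg
}

#' Expected dry-matter intake, NRC (2021) prediction equation
#'
#' First-parity form of NRC 2021 equation 2-1:
#' `(3.7 + 0.305 MilkE + 0.022 BW - 0.689 BCS) * (1 - 0.212 exp(-0.053 DIM))`,
#' with MilkE in Mcal NEL/d. The whole-bracket lactation-stage multiplier
#' follows the published NRC form.
#'
#' @param milkE milk energy output, Mcal/d (ECM can be converted via
#'   [milk_energy()]).
#' @param bw body weight, kg.
#' @param bcs body condition score (1-5).
#' @param dim days in milk (>= 1).
#' @return eDMI, kg/d.
#' @export
edmi_nrc2021 <- function(milkE, bw, bcs, dim) {
  stopifnot(all(dim >= 1, na.rm = TRUE))
  (3.7 + 0.305 * milkE + 0.022 * bw - 0.689 * bcs) *
    (1 - 0.212 * exp(-0.053 * dim))
}

#' Milk energy from ECM
#'
#' @param ecm ECM, kg/d.
#' @return Milk energy, Mcal NEL/d (0.752 Mcal per kg ECM).
#' @export
milk_energy <- function(ecm) .mcal_nel_per_kg_ecm * ecm

#' Energy conversion efficiency
#'
#' @param ecm ECM, kg/d.
#' @param mei metabolizable energy intake, MJ/d (> 0).
#' @return ECE, kg ECM per MJ ME.
#' @export
ece <- function(ecm, mei) {
  if (any(mei <= 0, na.rm = TRUE)) stop("MEI must be positive")
  ecm / mei
}

#' Convert the NRC intake coefficients to the energy-sink scales
#'
#' Expresses the NRC 2021 milk-energy coefficient (0.305 kg DM per Mcal)
#' on the ECM scale via the 0.752 Mcal/kg milk-energy content, and the
#' body-weight coefficient (0.022 kg DM per kg BW) on the metabolic
#' body-weight scale at a given mean MBW (BW = MBW^(4/3)).
#'
#' @param mean_mbw mean metabolic body weight, kg^0.75 (> 0).
#' @param digits rounding for reporting (default 3).
#' @return List with `ecm` and `mbw` coefficients.
#' @export
nrc_to_sink_scale <- function(mean_mbw, digits = 3) {
  stopifnot(mean_mbw > 0)
  ecm_coeff <- 0.305 * .mcal_nel_per_kg_ecm
  bw <- mean_mbw^(4 / 3)
  mbw_coeff <- 0.022 * bw / mean_mbw
  list(ecm = round(ecm_coeff, digits), mbw = round(mbw_coeff, digits))
}

#' Minimal diet energy content implied by an ECM coefficient
#'
#' An ECM regression coefficient of `coef` kg DM per kg ECM, combined with
#' the 4,765 kJ ME required per kg ECM, implies a minimum diet energy
#' content of `4765 / coef` kJ/kg DM before lactation energy efficiency
#' would exceed 100%.
#'
#' @param coef kg DM allocated per kg ECM (default 0.30).
#' @return kJ ME per kg DM, rounded to the nearest integer.
#' @export
min_energy_content <- function(coef = 0.30) round(.me_per_kg_ecm_kj / coef)

#' Lactation period class of a lactation week
#'
#' Maps lactation weeks to the five residual-variance period classes
#' (approximate lactation months 1, 2, 3, 4-8 and 9-11): weeks 1-4, 5-9,
#' 10-13, 14-35 and 36-44.
#'
#' @param week lactation week (1-44).
#' @param breaks upper week of each of the first four classes.
#' @return Integer period class 1-5.
#' @export
period_class <- function(week, breaks = c(4, 9, 13, 35)) {
  stopifnot(all(week >= 1 & week <= 44, na.rm = TRUE))
  findInterval(week, breaks + 0.5) + 1L
}

#' Append derived feed-efficiency columns to a weekly record table
#'
#' Adds ECM, MBW, BWL/BWG (from `delta_bw`), milk energy, both eDMI
#' formulations, ECE, DIM (if absent) and the lactation period class.
#' Records for which a particular derived trait is incomputable get `NA`
#' in that column only.
#'
#' @param records data frame with columns `milk`, `fat`, `protein`,
#'   `lactose` (g/kg), `bw` (kg), `delta_bw` (kg/d), `bcs`, `dmi` (kg/d),
#'   `mei` (MJ/d) and `week`.
#' @return The input with derived columns `ECM`, `MBW`, `BWL`, `BWG`,
#'   `MilkE`, `eDMI_RDC`, `eDMI_NRC2021`, `ECE`, `DIM`, `period` added.
#' @export
derive_metrics <- function(records) {
  r <- records
  r$ECM <- ecm(r$milk, r$fat, r$protein, r$lactose)
  r$MBW <- mbw(r$bw)
  s <- split_bw_change(r$delta_bw)
  r$BWL <- s$BWL
  r$BWG <- s$BWG
  if (is.null(r$DIM)) r$DIM <- (r$week - 1) * 7 + 4
  r$MilkE <- milk_energy(r$ECM)
  r$eDMI_RDC <- edmi_rdc(r$ECM, r$MBW, r$BWL, r$BWG)
  r$eDMI_NRC2021 <- edmi_nrc2021(r$MilkE, r$bw, r$bcs, r$DIM)
  r$ECE <- ece(r$ECM, r$mei)
  r$period <- period_class(r$week)
  r
}

# round-half-away-from-zero, used where printed ratios sit on a .5
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
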