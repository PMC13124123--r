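#' Multi-trait residual feed intake index
#'
#' Combines multi-trait breeding values with the Nordic Red
#' energy-requirement weights:
#' `RFI_Index = BV_DMI - 0.456 BV_ECM + 0.0508 BV_MBW - 3.25 BV_BWL +
#' 3.25 BV_BWG`. Lower values are more feed-efficient.
#'
#' @param bvs data frame with columns `id`, `DMI`, `ECM`, `MBW`, `BWL`,
#'   `BWG` (as returned by [ebv()] on a multi-trait fit).
#' @return Data frame with `id` and `ebv`.
#' @export
rfi_index <- function(bvs) {
  .check_bv_cols(bvs, c("DMI", "ECM", "MBW", "BWL", "BWG"))
  v <- bvs$DMI - 0.456 * bvs$ECM + 0.0508 * bvs$MBW -
    3.25 * bvs$BWL + 3.25 * bvs$BWG
  data.frame(id = as.character(bvs$id), ebv = v, row.names = NULL)
}

#' RZFeedEfficiency index
#'
#' The German Holstein feed-efficiency combination,
#' `RZFE = 0.4 BV_ECM - 4.5 BV_BWL + 4.5 BV_BWG - BV_DMI`; it carries no
#' maintenance (MBW) term and its sign is reversed relative to the RFI
#' family, so higher values are more feed-efficient.
#'
#' @param bvs data frame with columns `id`, `DMI`, `ECM`, `BWL`, `BWG`.
#' @return Data frame with `id` and `ebv`.
#' @export
rzfe <- function(bvs) {
  .check_bv_cols(bvs, c("DMI", "ECM", "BWL", "BWG"))
  v <- 0.4 * bvs$ECM - 4.5 * bvs$BWL + 4.5 * bvs$BWG - bvs$DMI
  data.frame(id = as.character(bvs$id), ebv = v, row.names = NULL)
}

.check_bv_cols <- function(bvs, cols) {
  miss <- setdiff(c("id", cols), names(bvs))
  if (length(miss))
    stop("breeding-value table lacks columns: ", paste(miss, collapse = ", "))
  bad <- bvs$id[!stats::complete.cases(bvs[cols])]
  if (length(bad))
    stop("missing trait breeding values for animals: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  invisible(TRUE)
}

#' Ratio of the growth to the milk coefficient per requirement system
#'
#' Reports, for each metric's coefficient system, how many times larger
#' the body-weight-gain coefficient is than the ECM coefficient
#' (half-away-from-zero rounding to one decimal; values on a rounding
#' boundary, such as RZFE's 4.5/0.4 = 11.25, are flagged).
#'
#' @return Data frame with `metric`, `ratio` (exact) and `ratio_reported`.
#' @export
coefficient_ratios <- function() {
  tab <- data.frame(
    metric = c("ReFI_RDC", "RZFE", "RFI"),
    bwg = c(.coef_rdc[["BWG"]], .coef_rzfe[["BWG"]], .coef_rfi_reported[["BWG"]]),
    ecm = c(.coef_rdc[["ECM"]], .coef_rzfe[["ECM"]], .coef_rfi_reported[["ECM"]])
  )
  tab$ratio <- tab$bwg / tab$ecm
  tab$ratio_reported <- round_half_up(tab$ratio, 1)
  tab$on_boundary <- abs(tab$ratio * 10 - floor(tab$ratio * 10) - 0.5) < 1e-9
  tab
}
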