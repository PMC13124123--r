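#' Read and write pedigree CSV files
#'
#' Columns `animal,sire,dam,birth_year,origin` (plus `sex` when present);
#' unknown parents encoded as `0`.
#'
#' @param path file path.
#' @return [read_pedigree()] returns an [fe_pedigree()].
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(animal = "character",
                                        sire = "character",
                                        dam = "character"))
  fe_pedigree(tab$animal, tab$sire, tab$dam, tab$birth_year,
              origin = if (is.null(tab$origin)) "base" else tab$origin,
              sex = tab$sex)
}

#' @rdname read_pedigree
#' @param ped an [fe_pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(animal = ped$id,
                    sire = ifelse(is.na(ped$sire), "0", ped$sire),
                    dam = ifelse(is.na(ped$dam), "0", ped$dam),
                    birth_year = ped$birth_year, origin = ped$origin)
  if (!is.null(ped$sex)) out$sex <- ped$sex
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read and write weekly record tables
#'
#' One weekly record per row; see [derive_metrics()] for the expected
#' columns.
#'
#' @param path file path.
#' @export
read_records <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(cow = "character"))
}

#' @rdname read_records
#' @param records record data frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
}

#' Read and write univariate variance components as YAML
#'
#' @param path file path.
#' @return [read_varcomp()] returns an [fe_varcomp()].
#' @export
read_varcomp <- function(path) {
  y <- yaml::read_yaml(path)
  fe_varcomp(htm = y$htm, pe = y$pe, animal = y$animal,
             residual = as.numeric(y$residual),
             slope_scale = isTRUE(y$slope_scale))
}

#' @rdname read_varcomp
#' @param vc an [fe_varcomp()].
#' @export
write_varcomp <- function(vc, path) {
  stopifnot(vc$type == "univariate")
  yaml::write_yaml(list(htm = vc$components[["htm"]],
                        pe = vc$components[["pe"]],
                        animal = vc$components[["animal"]],
                        residual = as.numeric(vc$residual),
                        slope_scale = isTRUE(vc$slope_scale)), path)
}
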