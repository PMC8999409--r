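#' @export
setGeneric("glycanMass", function(x) standardGeneric("glycanMass"))

#' @export
setGeneric("peptideMass", function(x, ...) standardGeneric("peptideMass"))

#' @export
setGeneric("precursorMz", function(x, z, ...) standardGeneric("precursorMz"))

#' @export
setGeneric("oxoniumMz", function(x, waterLosses = 0L) standardGeneric("oxoniumMz"))

#' @export
setGeneric("scans", function(x) standardGeneric("scans"))

#' @export
setGeneric("msLevels", function(x) standardGeneric("msLevels"))

#' @export
setGeneric("retentionTimes", function(x) standardGeneric("retentionTimes"))

#' @export
setGeneric("peptide", function(x) standardGeneric("peptide"))

#' @export
setGeneric("glycan", function(x) standardGeneric("glycan"))

#' @export
setGeneric("glycoClass", function(x) standardGeneric("glycoClass"))
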