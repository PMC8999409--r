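#' Read a glycan composition library
#'
#' The library is a TSV with columns `name`, `hex`, `hexnac`, `neuac`,
#' `dhex`, `class` (N or O) and `sda` (logical). The `sda` flag annotates
#' which library entries carry the Sda epitope: composition alone cannot
#' distinguish an Sda-extended antenna from a bisecting-GlcNAc isomer, so
#' the diagnostic 860.3143 oxonium ion is predicted only for entries
#' annotated `sda = TRUE` (and only when the NeuAc1Hex1HexNAc2 sub-unit is
#' present).
#'
#' @param path TSV file; defaults to the library shipped with the package,
#'   which contains the disialo biantennary N-glycan precursor
#'   (NeuAc2Hex5HexNAc4), its singly and doubly Sda-extended forms
#'   (NeuAc2Hex5HexNAc5/6, plus fucosylated variants), the bisecting-GlcNAc
#'   isomer control, the disialo core 1 O-glycan precursor
#'   (NeuAc2Hex1HexNAc1) and its Sda forms (NeuAc1/2Hex1HexNAc2)
#' @return data.frame with one row per glycan, plus a `mass` column
#' @export
readGlycanLibrary <- function(path = system.file("extdata",
                                                 "glycan_library.tsv",
                                                 package = "GlycoSda")) {
  lib <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "hex", "hexnac", "neuac", "dhex", "class", "sda")
  if (!all(need %in% names(lib)))
    stop("glycan library must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(lib$name)) stop("duplicate glycan names in library")
  if (!all(lib$class %in% c("N", "O")))
    stop("glycan class must be 'N' or 'O'")
  lib$sda <- as.logical(lib$sda)
  lib$mass <- vapply(seq_len(nrow(lib)), function(i)
    glycanMass(GlycanComposition(lib$hex[i], lib$hexnac[i],
                                 lib$neuac[i], lib$dhex[i])),
    numeric(1))
  lib
}

## library row -> GlycanComposition
.libGlycan <- function(lib, name) {
  i <- match(name, lib$name)
  if (is.na(i)) stop("glycan not in library: ", name)
  GlycanComposition(lib$hex[i], lib$hexnac[i], lib$neuac[i], lib$dhex[i])
}
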