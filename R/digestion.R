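## In-silico protease digestion. Cleavage rules follow the search settings of
## the workflow: trypsin cuts C-terminal of Lys/Arg and chymotrypsin
## C-terminal of Phe/Tyr/Trp/Leu, both with <=2 missed cleavages by default
## and no proline suppression (a config toggle, off by default); pronase is
## treated as nonspecific, enumerating all substrings within length bounds.

.PROTEASES <- list(
  trypsin      = list(residues = c("K", "R"), specific = TRUE),
  chymotrypsin = list(residues = c("F", "Y", "W", "L"), specific = TRUE),
  pronase      = list(residues = character(), specific = FALSE))

#' In-silico protease digestion
#'
#' @param protein character(1) protein sequence
#' @param protease `"trypsin"`, `"chymotrypsin"` or `"pronase"`
#' @param missedCleavages maximum missed cleavages (specific proteases;
#'   default 2)
#' @param lengthBounds numeric(2) peptide length bounds; enforced for
#'   pronase (default 4-20), optional for specific proteases (default no
#'   bounds)
#' @param prolineRule if TRUE, suppress cleavage before Pro (off by default:
#'   the search settings state plain K/R cleavage)
#' @param protein_id identifier recorded with each peptide
#' @return data.frame with columns `sequence`, `protein`, `start`, `end`
#'   (1-based inclusive), `missed`
#' @examples
#' digest("MKIVDVNLTSEGKR", "trypsin")
#' @export
digest <- function(protein, protease = c("trypsin", "chymotrypsin", "pronase"),
                   missedCleavages = 2L, lengthBounds = NULL,
                   prolineRule = FALSE, protein_id = "protein") {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) stop("empty protein sequence")
  if (is.character(protease)) {
    protease <- match.arg(protease)
    rule <- .PROTEASES[[protease]]
    if (is.null(rule)) stop("unknown protease: ", protease)
  } else stop("unknown protease")
  res <- strsplit(protein, "")[[1]]
  n <- length(res)

  if (!rule$specific) {
    if (is.null(lengthBounds)) lengthBounds <- c(4L, 20L)
    lo <- max(1L, lengthBounds[1]); hi <- min(n, lengthBounds[2])
    if (lo > hi) return(.emptyDigest())
    out <- do.call(rbind, lapply(lo:hi, function(len) {
      starts <- seq_len(n - len + 1L)
      data.frame(sequence = substring(protein, starts, starts + len - 1L),
                 protein = protein_id, start = starts,
                 end = starts + len - 1L, missed = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    return(out)
  }

  cut <- which(res %in% rule$residues)
  if (prolineRule) cut <- cut[!(cut < n & res[cut + 1L] == "P")]
  cut <- cut[cut < n]                       # a C-terminal K/R cleaves nothing
  bounds <- c(0L, cut, n)                   # peptide i spans bounds[i]+1..bounds[i+1]
  k <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(k)) {
    for (j in i:min(k, i + missedCleavages)) {
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      len <- e - s + 1L
      if (!is.null(lengthBounds) &&
          (len < lengthBounds[1] || len > lengthBounds[2])) next
      rows[[length(rows) + 1L]] <-
        data.frame(sequence = substr(protein, s, e), protein = protein_id,
                   start = s, end = e, missed = j - i,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyDigest())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.emptyDigest <- function() {
  data.frame(sequence = character(), protein = character(),
             start = integer(), end = integer(), missed = integer(),
             stringsAsFactors = FALSE)
}

#' Reversed-sequence decoy
#'
#' Full sequence reversal for target-decoy FDR estimation. Applying it to an
#' identifier already carrying the decoy prefix strips the prefix again
#' (involution).
#'
#' @param protein character(1) sequence
#' @param id protein identifier; the decoy is returned named
#'   `paste0("decoy_", id)` (or with the prefix removed if present)
#' @return named character(1): the reversed sequence
#' @export
reverseDecoy <- function(protein, id = "protein") {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (!nzchar(protein)) stop("empty protein sequence")
  rev <- paste(rev(strsplit(protein, "")[[1]]), collapse = "")
  newid <- if (startsWith(id, "decoy_")) sub("^decoy_", "", id)
           else paste0("decoy_", id)
  stats::setNames(rev, newid)
}

#' Append reversed decoys to a protein collection
#'
#' @param proteins named character vector of target sequences
#' @return named character vector: targets followed by `decoy_`-prefixed
#'   reversed sequences
#' @export
withDecoys <- function(proteins) {
  stopifnot(!is.null(names(proteins)))
  dec <- unlist(lapply(names(proteins),
                       function(id) reverseDecoy(proteins[[id]], id)))
  c(proteins, dec)
}

#' Read a protein FASTA
#'
#' @param path FASTA file
#' @return named character vector of amino-acid sequences
#' @export
readProteinFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))   # first token of header
  out
}

#' Write a protein collection (optionally with decoys) as FASTA
#'
#' @param proteins named character vector
#' @param path output file
#' @param decoys if TRUE, append `decoy_`-prefixed reversed sequences
#' @export
writeProteinFasta <- function(proteins, path, decoys = FALSE) {
  if (decoys) proteins <- withDecoys(proteins)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), path)
  invisible(path)
}
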