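#' Eisenberg consensus hydrophobicity scale
#'
#' Per-residue hydrophobicity values in kcal/mol (one-letter codes;
#' positive = hydrophobic).  Several variants of the consensus scale
#' circulate; this table is the variant consistent with per-strand sums
#' of pore-facing gasdermin sequences reported to two decimals.  A
#' different published variant can be supplied as a two-column TSV via
#' [readHydrophobicityScale()].
#'
#' @return named numeric vector, all 20 standard residues.
#' @export
eisenbergScale <- function() {
  c(A = 0.25, R = -1.76, N = -0.64, D = -0.72, C = 0.04, Q = -0.69,
    E = -0.62, G = 0.16, H = -0.40, I = 0.73, L = 0.53, K = -1.10,
    M = 0.26, F = 0.61, P = -0.07, S = -0.26, T = -0.18, W = 0.37,
    Y = 0.02, V = 0.54)
}

#' Read a hydrophobicity scale from TSV
#'
#' Two columns: one-letter residue code and value in kcal/mol.  All 20
#' standard residues must be present.
#'
#' @param path TSV file path.
#' @return named numeric vector.
#' @export
readHydrophobicityScale <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   col.names = c("residue", "value"),
                   comment.char = "#", stringsAsFactors = FALSE)
  scale <- setNames(df$value, toupper(df$residue))
  missing <- setdiff(names(eisenbergScale()), names(scale))
  if (length(missing))
    stop("scale is missing residues: ", paste(missing, collapse = ", "))
  scale
}

#' Hydrophobicity score of a residue stretch
#'
#' Sum of per-residue scale values over a one-letter sequence; an empty
#' sequence scores 0.  The sum is additive over concatenation and
#' invariant under permutation.
#'
#' @param sequence one-letter amino-acid string.
#' @param scale named numeric scale (default [eisenbergScale()]).
#' @return score in kcal/mol.
#' @examples
#' eisenbergScore("ADQQSE")  # -2.73
#' @export
eisenbergScore <- function(sequence, scale = eisenbergScale()) {
  if (nchar(sequence) == 0L) return(0)
  letters <- strsplit(toupper(sequence), "")[[1L]]
  unknown <- which(!(letters %in% names(scale)))
  if (length(unknown))
    stop("unknown residue '", letters[unknown[1L]], "' at position ",
         unknown[1L])
  sum(scale[letters])
}

#' Score a set of beta strands and their total
#'
#' Per-strand hydrophobicity scores for the pore-facing residues of a
#' beta sheet, plus the full-sheet total (the sum of the strand
#' scores).
#'
#' @param strands named character vector (or data.frame with columns
#'   `label`, `sequence`) of pore-facing residue stretches.
#' @param scale named numeric scale.
#' @return list(strands = data.frame(label, sequence, score),
#'   total).
#' @export
sheetScore <- function(strands, scale = eisenbergScale()) {
  if (is.data.frame(strands)) {
    labels <- strands$label; seqs <- strands$sequence
  } else {
    labels <- names(strands)
    if (is.null(labels)) labels <- paste0("strand", seq_along(strands))
    seqs <- unname(strands)
  }
  scores <- vapply(seqs, eisenbergScore, numeric(1L), scale = scale,
                   USE.NAMES = FALSE)
  list(strands = data.frame(label = labels, sequence = seqs,
                            score = scores, stringsAsFactors = FALSE),
       total = sum(scores))
}

#' Relative hydrophilicity excess between two sheet scores
#'
#' How much more hydrophilic sheet A is than sheet B, as a percentage
#' of magnitudes: `100 * (|a|/|b| - 1)`.  The phrasing "more
#' hydrophilic" presumes both scores are negative (hydrophilic regime);
#' otherwise the raw magnitude ratio is still returned but flagged.
#'
#' @param scoreA,scoreB sheet scores in kcal/mol.
#' @return list(percent, hydrophilicRegime).
#' @examples
#' hydrophilicityExcess(-11.63, -7.19)$percent  # ~61.75
#' @export
hydrophilicityExcess <- function(scoreA, scoreB) {
  stopifnot(scoreB != 0)
  regime <- scoreA < 0 && scoreB < 0
  if (!regime)
    warning("scores are not both negative; interpreting magnitudes only")
  list(percent = 100 * (abs(scoreA) / abs(scoreB) - 1),
       hydrophilicRegime = regime)
}

#' Pore-facing strand sequences of gasdermin beta barrels
#'
#' The pore-facing residue stretches of the four membrane-spanning
#' strands (beta3, beta5, beta7, beta8) of human GSDMD and mouse GSDMA3
#' N-terminal domains -- the inputs for cross-protein hydrophilicity
#' comparison.
#'
#' @param protein "GSDMD" or "GSDMA3".
#' @return named character vector of strand sequences.
#' @export
poreFacingStrands <- function(protein = c("GSDMD", "GSDMA3")) {
  protein <- match.arg(protein)
  switch(protein,
         GSDMD = c(beta3 = "ADQQSE", beta5 = "KAGASS",
                   beta7 = "TKESRS", beta8 = "QEQHSK"),
         GSDMA3 = c(beta3 = "MDQQLE", beta5 = "TKKTGS",
                    beta7 = "TNNISP", beta8 = "LGQSNN"))
}
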