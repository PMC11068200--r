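# Average-mass arithmetic for intact-protein fragment prediction.
#
# All masses are average (not monoisotopic): at intact-protein resolution a
# TOF-TOF instrument does not resolve isotopes, and predicted fragment m/z
# values are compared against centroided average-mass peaks.

#' Average residue masses
#'
#' Average masses (Da) of the 20 standard amino-acid residues, i.e. the mass
#' contributed by one residue inside a peptide chain (free amino-acid mass
#' minus one water).
#'
#' @format Named numeric vector, names are 1-letter residue codes.
#' @keywords internal
.residue_avg_mass <- c(
  G =  57.0519, A =  71.0788, S =  87.0782, P =  97.1167, V =  99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Mass constants (average, Da)
#'
#' Water, proton (average H) and ammonia masses used throughout fragment
#' arithmetic. The proton is taken as the average hydrogen atomic mass for
#' consistency with average-mass fragment prediction.
#'
#' @name mass-constants
#' @keywords internal
MASS_WATER   <- 18.0153
MASS_PROTON  <- 1.00794
MASS_AMMONIA <- 17.0305

#' Average mass of one amino-acid residue
#'
#' @param code 1-letter residue code (one of the 20 standard residues).
#' @return Average residue mass in Da.
#' @examples
#' residue_average_mass("G")  # 57.0519
#' @export
residue_average_mass <- function(code) {
  if (!is.character(code) || length(code) != 1L || nchar(code) != 1L)
    stop("'code' must be a single 1-letter residue code")
  m <- .residue_avg_mass[code]
  if (is.na(m)) stop("unknown residue code: '", code, "'")
  unname(m)
}

.check_sequence <- function(sequence, what = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop(what, " must be a non-empty character scalar")
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(res), names(.residue_avg_mass))
  if (length(bad) > 0L)
    stop("non-standard residue code(s) in ", what, ": ",
         paste(bad, collapse = ", "))
  res
}

#' Singly protonated average mass of a protein
#'
#' Sum of residue average masses plus one water (terminal H and OH) plus one
#' proton: the m/z of the +1 charge state.
#'
#' @param sequence Protein sequence, 1-letter codes.
#' @return \eqn{[M+H]^+} average m/z in Da.
#' @examples
#' protonated_mass("G")  # 76.0751
#' @export
protonated_mass <- function(sequence) {
  res <- .check_sequence(sequence)
  sum(.residue_avg_mass[res]) + MASS_WATER + MASS_PROTON
}
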