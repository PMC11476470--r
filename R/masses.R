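# Average residue masses (Da), free N/C termini, no PTMs.
.aa_residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

.water_mass <- 18.01524

#' Molecular weight of a protein sequence
#'
#' Average (not monoisotopic) mass of an intact, unmodified polypeptide with
#' free termini: the sum of average residue masses plus one water. This is
#' the convention under which intact-protein masses (e.g. the ~247 kDa of a
#' midi-dystrophin) are normally quoted.
#'
#' Additivity holds exactly: `MW(paste0(a, b)) == MW(a) + MW(b) - 0.01801524`
#' kDa, i.e. joining two chains releases one water.
#'
#' @param seq A character vector of protein sequences (one-letter codes,
#'   standard 20-residue alphabet).
#' @return A numeric vector of masses in kDa (full precision; round for
#'   display).
#' @examples
#' molecular_weight("G") # ~0.0751 kDa
#' @export
molecular_weight <- function(seq) {
  vapply(seq, function(s) {
    check_protein_seq(s)
    aa <- strsplit(s, "", fixed = TRUE)[[1]]
    (sum(.aa_residue_mass[aa]) + .water_mass) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mass bookkeeping for a split design
#'
#' Tabulates the masses of the full construct, the two expressed halves
#' (extein + intein half, plus any tag on the N-half), and the mass the two
#' halves carry beyond the full construct (the intein halves + tag that are
#' excised during trans-splicing).
#'
#' @param design A [split_design()].
#' @param construct_seq The assembled construct sequence.
#' @return A tibble with one row per species (`full`, `n_half`, `c_half`)
#'   plus the derived `excised_mass_kda` attribute column repeated.
#' @export
mass_report <- function(design, construct_seq) {
  halves <- build_halves(design, construct_seq)
  mw <- molecular_weight(c(full = construct_seq,
                           n_half = halves$n_half,
                           c_half = halves$c_half))
  tibble(
    species = c("full", "n_half", "c_half"),
    length_aa = nchar(c(construct_seq, halves$n_half, halves$c_half)),
    mass_kda = round(mw, 1),
    excised_mass_kda = round(mw[2] + mw[3] - mw[1], 1)
  )
}
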