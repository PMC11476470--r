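#' @keywords internal
check_protein_seq <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    abort(sprintf("`%s` must be a single non-empty protein sequence.", arg))
  }
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]),
                 names(.aa_residue_mass))
  if (length(bad) > 0) {
    abort(sprintf(
      "`%s` contains non-standard residue letters: %s. Only the 20 standard amino acids are supported.",
      arg, paste(bad, collapse = ", ")))
  }
  invisible(seq)
}

#' Read and write protein FASTA
#'
#' Thin wrappers around Biostrings that return/accept plain named character
#' vectors so sequences slot into tidy pipelines.
#'
#' @param path File path.
#' @param seqs Named character vector of protein sequences.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  setNames(as.character(aas), names(aas))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Enumerate candidate intein split sites
#'
#' For GP41-1 (and most class-1 inteins) the catalytically required residue
#' is the first amino acid of the C-extein, a serine. A valid split point
#' `split_after = i` therefore requires residue `i + 1` to be Ser: the
#' N-extein is `seq[1..i]`, the C-extein starts with the serine at `i + 1`.
#'
#' @param seq Protein sequence (standard 20-letter alphabet).
#' @param allowed_range Optional integer vector `c(lo, hi)` restricting the
#'   returned `split_after` indices (inclusive, 1-based).
#' @return Integer vector of `split_after` positions, ascending. An index
#'   `i` means "cut between `i` and `i + 1`".
#' @examples
#' enumerate_split_sites("MASAS") # c(2, 4)
#' @export
enumerate_split_sites <- function(seq, allowed_range = NULL) {
  check_protein_seq(seq)
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  ser <- which(aa == "S")
  sites <- ser[ser >= 2L] - 1L
  if (!is.null(allowed_range)) {
    stopifnot(length(allowed_range) == 2L, allowed_range[1] <= allowed_range[2])
    sites <- sites[sites >= allowed_range[1] & sites <= allowed_range[2]]
  }
  as.integer(sites)
}
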