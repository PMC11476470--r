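#' GP41-1 split-intein sequences
#'
#' The N- and C-terminal halves of the GP41-1 split intein (one of the
#' smallest and fastest trans-splicing inteins known; 88 + 37 aa) and the HA
#' epitope tag. GP41-1's native extein junction is SGY/SSS; the serine that
#' starts the C-extein is catalytically required, the remaining native
#' extein residues are dispensable, which allows traceless insertion at any
#' internal serine.
#'
#' @return Named character vector with elements `intein_n`, `intein_c`,
#'   `ha_tag`.
#' @export
gp41_1_sequences <- function() {
  c(
    intein_n = "CLDLKTQVQTPQGMKEISNIQVGDLVLSNTGYNEVLNVFPKSKKKSYKITLEDGKEIICSEEHLFPTQTGEMNISGGLKEGMCLYVKE",
    intein_c = "MMLKKILKIEELDERELIDIEVSGNHLFYANDILTHN",
    ha_tag = "YPYDVPDYA"
  )
}

#' Define a split design on a construct
#'
#' A split design places an intein junction after residue `split_after` of
#' the construct: the N-half cassette expresses
#' `construct[1..split_after] + intein_n + tag` and the C-half expresses
#' `intein_c + construct[(split_after+1)..end]`. The residue at
#' `split_after + 1` (the first C-extein residue) must be serine.
#'
#' @param name Design name.
#' @param construct Name of the construct the split applies to.
#' @param split_after 1-based residue index in construct coordinates.
#' @param intein_n_seq,intein_c_seq Intein half sequences (default GP41-1).
#' @param n_tag_seq Optional tag appended to the N-half (e.g. HA); `NULL`
#'   for none.
#' @param extein_window Number of extein residues on each side of the
#'   junction used when predicting the split complex (default 200).
#' @return An object of class `split_design`.
#' @export
split_design <- function(name, construct, split_after,
                         intein_n_seq = gp41_1_sequences()[["intein_n"]],
                         intein_c_seq = gp41_1_sequences()[["intein_c"]],
                         n_tag_seq = NULL, extein_window = 200L) {
  stopifnot(is.numeric(split_after), length(split_after) == 1L,
            split_after >= 1L)
  check_protein_seq(intein_n_seq, "intein_n_seq")
  check_protein_seq(intein_c_seq, "intein_c_seq")
  if (!is.null(n_tag_seq)) check_protein_seq(n_tag_seq, "n_tag_seq")
  structure(list(name = name, construct = construct,
                 split_after = as.integer(split_after),
                 intein_n_seq = intein_n_seq, intein_c_seq = intein_c_seq,
                 n_tag_seq = n_tag_seq,
                 extein_window = as.integer(extein_window)),
            class = "split_design")
}

#' @export
print.split_design <- function(x, ...) {
  cat("<split_design>", x$name, "on", x$construct,
      "- split after residue", x$split_after, "\n")
  invisible(x)
}

#' Read split designs from YAML
#'
#' Schema: top-level `designs:` list of `{name, construct, split_after,
#' intein_n_seq?, intein_c_seq?, n_tag_seq?, extein_window?}`.
#'
#' @param path YAML file path.
#' @return Named list of `split_design` objects.
#' @export
read_split_designs <- function(path) {
  y <- yaml::read_yaml(path)
  ds <- y$designs %||% y
  out <- purrr::map(ds, function(d) {
    split_design(
      name = d$name, construct = d$construct,
      split_after = d$split_after,
      intein_n_seq = d$intein_n_seq %||% gp41_1_sequences()[["intein_n"]],
      intein_c_seq = d$intein_c_seq %||% gp41_1_sequences()[["intein_c"]],
      n_tag_seq = d$n_tag_seq,
      extein_window = d$extein_window %||% 200L
    )
  })
  setNames(out, map_chr(out, "name"))
}

#' Build the two expressed halves of a split design
#'
#' @param design A [split_design()].
#' @param construct_seq The assembled construct sequence the design splits.
#' @return A list with `n_half` and `c_half` sequences. Stripping the
#'   intein halves and tag and joining the extein parts reproduces the
#'   construct exactly.
#' @export
build_halves <- function(design, construct_seq) {
  stopifnot(inherits(design, "split_design"))
  check_protein_seq(construct_seq, "construct_seq")
  n <- nchar(construct_seq)
  i <- design$split_after
  if (i < 1L || i >= n) {
    abort(sprintf("split_after = %d outside 1..%d.", i, n - 1L))
  }
  first_c <- substring(construct_seq, i + 1L, i + 1L)
  if (first_c != "S") {
    abort(sprintf(
      "Residue %d (first C-extein position) is '%s', not the serine required for trans-splicing.",
      i + 1L, first_c))
  }
  list(
    n_half = paste0(substring(construct_seq, 1L, i), design$intein_n_seq,
                    design$n_tag_seq %||% ""),
    c_half = paste0(design$intein_c_seq, substring(construct_seq, i + 1L, n))
  )
}

#' AAV cassette layout
#'
#' Lengths (nt) of the regulatory elements packaged alongside the coding
#' sequence. Element sizes vary between cloning designs, so the defaults
#' here are documented typical values: a CK8 muscle
#' promoter (~436 nt), an SV40 late polyA (~135 nt) and two AAV2 ITRs
#' (145 nt each); override them for a real cloning design. Capacity
#' defaults to the ~4.7 kb rAAV packaging limit.
#'
#' @param promoter_nt,polya_nt,itr_nt,extra_nt Element lengths in nt.
#' @param capacity_nt Packaging capacity in nt.
#' @return A `cassette_layout` list.
#' @export
cassette_layout <- function(promoter_nt = 436, polya_nt = 135, itr_nt = 145,
                            extra_nt = 0, capacity_nt = 4700) {
  vals <- c(promoter_nt, polya_nt, itr_nt, extra_nt, capacity_nt)
  if (any(vals < 0)) abort("Cassette element lengths must be >= 0.")
  structure(list(promoter_nt = promoter_nt, polya_nt = polya_nt,
                 itr_nt = itr_nt, extra_nt = extra_nt,
                 capacity_nt = capacity_nt),
            class = "cassette_layout")
}

#' Cassette size accounting for the halves of a split design
#'
#' Payload = `3 * (aa + 1)` nt of coding sequence (one stop codon per
#' cassette) plus promoter, polyA, both ITRs and any extra elements. An
#' oversize payload is reported as `"warn"`, not an error: packaging above
#' ~4.7 kb is inefficient but not impossible, and a design may accept it
#' where no smaller split exists.
#'
#' @param design A [split_design()].
#' @param construct_seq The assembled construct sequence.
#' @param layout A [cassette_layout()].
#' @return A tibble with one row per half: `half`, `aa_length`,
#'   `payload_nt`, `capacity_nt`, `fits` (`"pass"`/`"warn"`).
#' @export
cassette_size <- function(design, construct_seq, layout = cassette_layout()) {
  stopifnot(inherits(layout, "cassette_layout"))
  halves <- build_halves(design, construct_seq)
  aa <- c(nchar(halves$n_half), nchar(halves$c_half))
  payload <- 3 * (aa + 1) + layout$promoter_nt + layout$polya_nt +
    2 * layout$itr_nt + layout$extra_nt
  tibble(
    design = design$name,
    half = c("N", "C"),
    aa_length = aa,
    payload_nt = payload,
    capacity_nt = layout$capacity_nt,
    fits = ifelse(payload > layout$capacity_nt, "warn", "pass")
  )
}
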