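#' Synthetic dystrophin-like design example
#'
#' A fully synthetic stand-in for a Dp427m-style reference: a seeded random
#' protein with a dystrophin-shaped domain architecture (ABD1, hinge 1 of
#' 96 aa, 24 spectrin-like repeats of 109 aa, hinges 2-4, cysteine-rich
#' domain, C-terminus) plus three midi-construct specifications and their
#' GP41-1 split designs (splits in R11, R17 and hinge 3 respectively, each
#' at a serine junction). Hinge edits remove the first 54 residues of
#' hinge 1 (a 56.25% reduction) and 36-38% of the other hinges.
#'
#' This is NOT the real dystrophin sequence or the published domain table;
#' it exists so the whole pipeline (assembly, split placement, mass and
#' cassette accounting, evaluation) runs end-to-end with realistic sizes
#' and no external data.
#'
#' @param seed Integer seed for the random reference sequence.
#' @return A list: `reference` (sequence), `annotations` (tibble),
#'   `constructs` (named list of [construct_spec()]), `construct_seqs`
#'   (named character), `designs` (named list of [split_design()]).
#' @export
synthetic_dystrophin_example <- function(seed = 42L) {
  ann <- synthetic_dystrophin_annotations()
  set.seed(seed)
  n_ref <- max(ann$end)
  aa <- sample(names(.aa_residue_mass), n_ref, replace = TRUE)
  # guarantee a serine mid-domain where the splits go
  for (dom in c("R11", "R17", "H3")) {
    row <- ann[ann$name == dom, ]
    aa[row$start + row$length %/% 2] <- "S"
  }
  reference <- paste(aa, collapse = "")

  seg <- function(domain, ks = NA, ke = NA) {
    tibble(domain = domain, keep_start = as.integer(ks),
           keep_end = as.integer(ke))
  }
  h1 <- seg("H1", 55, 96)    # drop first 54 of 96: 56.25% reduction
  h2 <- seg("H2", 1, 32)     # 36.00%
  h3 <- seg("H3", 1, 30)     # 37.50%
  h4 <- seg("H4", 1, 44)     # 37.14%
  reps <- function(idx) bind_rows(lapply(paste0("R", idx), seg))
  common_n <- bind_rows(seg("ABD1"), h1)
  common_c <- bind_rows(seg("H4", 1, 44), seg("CR"), seg("CT"))

  constructs <- list(
    `midi-1` = construct_spec("midi-1", bind_rows(
      common_n, reps(1:3), h2, reps(8:13), reps(16:17), reps(24), common_c)),
    `midi-2` = construct_spec("midi-2", bind_rows(
      common_n, reps(1), h2, reps(8:12), reps(16:17), h3, reps(20:24), common_c)),
    `midi-3` = construct_spec("midi-3", bind_rows(
      common_n, reps(1:3), h2, reps(8:9), reps(16:17), h3, reps(20:24), common_c))
  )
  construct_seqs <- purrr::map(constructs,
                               function(cs) assemble_construct(reference, ann, cs))

  split_in <- function(construct_name, domain) {
    seq <- construct_seqs[[construct_name]]
    segs <- construct_segments(seq)
    row <- segs[segs$domain == domain, ][1, ]
    sites <- enumerate_split_sites(as.character(seq),
                                   c(row$construct_start, row$construct_end - 1L))
    if (length(sites) == 0) abort(sprintf("No serine junction in %s.", domain))
    sites[ceiling(length(sites) / 2)]
  }
  designs <- list(
    `midi-1` = split_design("split-midi-1", "midi-1", split_in("midi-1", "R11")),
    `midi-2` = split_design("split-midi-2", "midi-2", split_in("midi-2", "R17")),
    `midi-3` = split_design("split-midi-3", "midi-3", split_in("midi-3", "H3"))
  )
  list(reference = reference, annotations = ann, constructs = constructs,
       construct_seqs = construct_seqs, designs = designs)
}

#' @rdname synthetic_dystrophin_example
#' @export
synthetic_dystrophin_annotations <- function() {
  widths <- c(
    ABD1 = 246L, H1 = 96L,
    setNames(rep(109L, 3), paste0("R", 1:3)), H2 = 50L,
    setNames(rep(109L, 16), paste0("R", 4:19)), H3 = 48L,
    setNames(rep(109L, 5), paste0("R", 20:24)), H4 = 70L,
    CR = 280L, CT = 200L
  )
  ends <- cumsum(widths)
  cat_of <- function(nm) {
    dplyr::case_when(
      nm == "ABD1" ~ "terminal",
      grepl("^H\\d$", nm) ~ "hinge",
      grepl("^R\\d+$", nm) ~ "repeat",
      nm == "CR" ~ "cysteine-rich",
      TRUE ~ "c-terminal"
    )
  }
  domain_annotations(names(widths), ends - widths + 1L, ends,
                     cat_of(names(widths)))
}
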