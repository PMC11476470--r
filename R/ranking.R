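#' Evaluate a split design from its confidence bundle
#'
#' Combines the region-restricted confidence metrics into one evaluation
#' row: intein-complex confidence (mean pLDDT over both intein halves,
#' mean inter-subunit PAE), optional superposition RMSD of the
#' complex-context intein against an isolated-intein prediction, and the
#' extein-extein interface statistics that track trans-splicing
#' competence. The favorable/unfavorable call applies `call_cutoff` to the
#' extein `pct_pae_below`; it is a documented heuristic (it separates the
#' reconstituting from the failing designs in the motivating data), not a
#' validated classifier, and intein-region confidence is deliberately not
#' part of it because it barely varies between designs.
#'
#' @param bundle [confidence_bundle()] of the split-complex prediction.
#' @param regions Named list with region expressions/[chain_region()]s:
#'   `intein_n`, `intein_c`, `extein_n`, `extein_c`.
#' @param name Design name.
#' @param model Optional `structure_model` of the complex.
#' @param isolated_intein_model Optional `structure_model` of the intein
#'   predicted alone; with `model`, yields `intein_rmsd`.
#' @param intein_region_model,intein_region_isolated Optional regions
#'   selecting the intein in each model (default: whole models).
#' @param threshold PAE cutoff (Angstrom, default 10).
#' @param max_cycles,reject_sigma Refinement parameters for the RMSD.
#' @param call_cutoff Extein `pct_pae_below` (percent) at or above which
#'   the design is called favorable (default 10).
#' @return A one-row tibble (class `design_evaluation` rows are plain):
#'   `design`, `intein_plddt`, `intein_pae`, `intein_rmsd`,
#'   `extein_n_pairs`, `extein_pct_pae_below`, `extein_mean_pae`,
#'   `extein_contact_cond`, `call_cutoff`, `call`.
#' @export
evaluate_design <- function(bundle, regions, name, model = NULL,
                            isolated_intein_model = NULL,
                            intein_region_model = NULL,
                            intein_region_isolated = NULL,
                            threshold = 10, max_cycles = 5L,
                            reject_sigma = 2, call_cutoff = 10) {
  req <- c("intein_n", "intein_c", "extein_n", "extein_c")
  if (!all(req %in% names(regions))) {
    abort(paste0("`regions` must name: ", paste(req, collapse = ", ")))
  }
  rin <- resolve_region(bundle, regions$intein_n)
  ric <- resolve_region(bundle, regions$intein_c)
  intein_union <- chain_region(c(rin$chain, ric$chain), c(rin$resno, ric$resno))
  intein_if <- interface_metrics(bundle, rin, ric, threshold)
  extein_if <- interface_metrics(bundle, regions$extein_n, regions$extein_c,
                                 threshold)
  intein_rmsd <- NA_real_
  if (!is.null(model) && !is.null(isolated_intein_model)) {
    pairing <- pair_by_sequence(model, isolated_intein_model,
                                region_a = intein_region_model,
                                region_b = intein_region_isolated)
    intein_rmsd <- refine_superpose(pairing, max_cycles, reject_sigma)$rmsd
  }
  pct <- extein_if$pct_pae_below
  tibble(
    design = name,
    intein_plddt = mean_plddt(bundle, intein_union),
    intein_pae = intein_if$mean_pae,
    intein_rmsd = intein_rmsd,
    extein_n_pairs = extein_if$n_pairs,
    extein_pct_pae_below = pct,
    extein_mean_pae = extein_if$mean_pae,
    extein_contact_cond = extein_if$mean_contact_prob_conditional,
    call_cutoff = call_cutoff,
    call = ifelse(pct >= call_cutoff, "favorable", "unfavorable")
  )
}

#' Rank design evaluations by predicted trans-splicing competence
#'
#' Stable deterministic order: extein `pct_pae_below` descending, ties by
#' conditional contact mean descending (absent sorts last), then by name.
#'
#' @param evals A tibble of rows from [evaluate_design()].
#' @return The same tibble, sorted, with a `rank` column prepended.
#' @export
rank_designs <- function(evals) {
  stopifnot(nrow(evals) >= 1)
  out <- evals |>
    arrange(desc(.data$extein_pct_pae_below),
            desc(dplyr::coalesce(.data$extein_contact_cond, -Inf)),
            .data$design) |>
    mutate(rank = row_number())
  out[, c("rank", setdiff(names(out), "rank"))]
}

#' Render a per-design report
#'
#' Writes `evaluations.tsv` (all metric columns) and `report.md` (ranked
#' table plus per-design verdicts); with `bundles`, per-design pLDDT band
#' tables and PAE-matrix TSVs are added, and with `plots = TRUE` PAE
#' heatmap PNGs. Text outputs are bit-stable given identical inputs.
#'
#' @param evals Evaluations tibble (ranked or not; ranked on write).
#' @param out_dir Output directory (created if needed).
#' @param bundles Optional named list of bundles (names matching
#'   `evals$design`).
#' @param plots Write PNG heatmaps (default FALSE).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(evals, out_dir, bundles = NULL, plots = FALSE) {
  stopifnot(nrow(evals) >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ranked <- if ("rank" %in% names(evals)) evals else rank_designs(evals)
  paths <- file.path(out_dir, "evaluations.tsv")
  readr::write_tsv(ranked, paths[1])

  md <- c("# Split-design evaluation report", "",
          sprintf("%d design(s); PAE threshold-based interface statistics; call cutoff %s%% extein pairs below threshold.",
                  nrow(ranked), format(ranked$call_cutoff[1])), "",
          "| rank | design | intein pLDDT | intein PAE (A) | intein RMSD (A) | extein %PAE<thr | extein contact (cond.) | call |",
          "|---|---|---|---|---|---|---|---|")
  md <- c(md, vapply(seq_len(nrow(ranked)), function(i) {
    r <- ranked[i, ]
    sprintf("| %d | %s | %.2f | %.2f | %s | %.2f | %s | %s |",
            r$rank, r$design, r$intein_plddt, r$intein_pae,
            ifelse(is.na(r$intein_rmsd), "-", sprintf("%.3f", r$intein_rmsd)),
            r$extein_pct_pae_below,
            ifelse(is.na(r$extein_contact_cond), "absent",
                   sprintf("%.5f", r$extein_contact_cond)),
            r$call)
  }, character(1)))
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    bands <- plddt_bands(b, chain_region(b$chain_ids, b$res_ids))
    bp <- file.path(out_dir, paste0(nm, "_plddt_bands.tsv"))
    readr::write_tsv(bands, bp)
    mp <- file.path(out_dir, paste0(nm, "_pae.tsv"))
    utils::write.table(b$pae, mp, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    paths <- c(paths, bp, mp)
    if (plots) {
      pp <- file.path(out_dir, paste0(nm, "_pae.png"))
      ggplot2::ggsave(pp, autoplot.confidence_bundle(b), width = 5,
                      height = 4, dpi = 120)
      paths <- c(paths, pp)
    }
  }
  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  invisible(c(paths, md_path))
}
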