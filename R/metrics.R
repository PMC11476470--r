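#' Mean pLDDT over a region
#'
#' @param bundle A [confidence_bundle()].
#' @param region A region expression or [chain_region()].
#' @return Arithmetic mean of per-residue pLDDT over the region, rounded
#'   to two decimals.
#' @export
mean_plddt <- function(bundle, region) {
  idx <- region_tokens(bundle, region)
  round(mean(bundle$plddt[idx]), 2)
}

#' Inter-region PAE / contact statistics
#'
#' The trans-splicing-competence statistics for a pair of regions A, B
#' (typically the two intein halves, or the two 200-residue extein
#' windows):
#' \itemize{
#'   \item `pct_pae_below`: percent of cross pairs with PAE strictly below
#'     `threshold`;
#'   \item `mean_pae`: mean PAE over all cross pairs;
#'   \item `mean_contact_prob_conditional`: mean contact probability over
#'     the cross pairs that qualify (PAE < threshold); `NA` when the bundle
#'     has no contact matrix or no pair qualifies.
#' }
#' PAE is asymmetric, so both off-diagonal blocks are pooled:
#' `n_pairs = 2 * |A| * |B|`, which makes every statistic symmetric in
#' (A, B).
#'
#' @param bundle A [confidence_bundle()].
#' @param region_a,region_b Disjoint, non-empty regions.
#' @param threshold PAE cutoff in Angstrom (default 10).
#' @return A one-row tibble: `region_a`, `region_b`, `threshold`,
#'   `n_pairs`, `n_below`, `pct_pae_below`, `mean_pae`,
#'   `mean_contact_prob_conditional`.
#' @export
interface_metrics <- function(bundle, region_a, region_b, threshold = 10) {
  stopifnot(threshold > 0)
  ra <- resolve_region(bundle, region_a)
  rb <- resolve_region(bundle, region_b)
  if (nrow(dplyr::inner_join(ra, rb, by = c("chain", "resno"))) > 0) {
    abort("Regions A and B overlap; interface metrics need disjoint regions.")
  }
  ia <- region_tokens(bundle, ra)
  ib <- region_tokens(bundle, rb)
  pae_cross <- c(bundle$pae[ia, ib], bundle$pae[ib, ia])
  below <- pae_cross < threshold
  cond <- NA_real_
  if (!is.null(bundle$contact_probs) && any(below)) {
    cp_cross <- c(bundle$contact_probs[ia, ib], bundle$contact_probs[ib, ia])
    cond <- mean(cp_cross[below])
  }
  tibble(
    region_a = region_label(ra), region_b = region_label(rb),
    threshold = threshold,
    n_pairs = length(pae_cross), n_below = sum(below),
    pct_pae_below = 100 * mean(below),
    mean_pae = mean(pae_cross),
    mean_contact_prob_conditional = cond
  )
}

region_label <- function(region) {
  region |>
    group_by(.data$chain) |>
    summarise(lab = paste0(.data$chain[1], ":", collapse_runs(.data$resno)),
              .groups = "drop") |>
    pull("lab") |>
    paste(collapse = ",")
}

collapse_runs <- function(x) {
  x <- sort(unique(x))
  brk <- c(0, which(diff(x) != 1), length(x))
  paste(vapply(seq_len(length(brk) - 1), function(i) {
    seg <- x[(brk[i] + 1):brk[i + 1]]
    if (length(seg) == 1) as.character(seg) else paste0(seg[1], "-", seg[length(seg)])
  }, character(1)), collapse = ",")
}

#' pLDDT confidence bands
#'
#' Counts region residues in the conventional five AlphaFold confidence
#' bands: 0-50 (very low), 50-60 (low), 60-80 (medium), 80-90 (high,
#' inclusive of 90) and >90 (very high). Intervals are half-open
#' `[lo, hi)` except the last, `(90, 100]`.
#'
#' @inheritParams mean_plddt
#' @return A tibble with columns `band` (ordered factor) and `n`; counts
#'   sum to the region size.
#' @export
plddt_bands <- function(bundle, region) {
  idx <- region_tokens(bundle, region)
  p <- bundle$plddt[idx]
  lev <- c("0-50", "50-60", "60-80", "80-90", ">90")
  band <- ifelse(p < 50, lev[1],
          ifelse(p < 60, lev[2],
          ifelse(p < 80, lev[3],
          ifelse(p <= 90, lev[4], lev[5]))))
  counts <- table(factor(band, levels = lev))
  tibble(band = factor(lev, levels = lev), n = as.integer(counts))
}

#' Tabulate pTM scores across predictions
#'
#' Pass-through table of global pTM values, e.g. to compare structure
#' predictions of hinge-shortened constructs against their original-hinge
#' counterparts. With `pairs`, pairwise differences are appended.
#'
#' @param bundles A named list of [confidence_bundle()]s.
#' @param pairs Optional two-column data frame (`a`, `b`) naming bundle
#'   pairs to difference (`ptm_a - ptm_b`).
#' @return A tibble `name`, `ptm` (NA when a bundle has no pTM); with
#'   `pairs`, a list with elements `scores` and `differences`.
#' @export
ptm_report <- function(bundles, pairs = NULL) {
  stopifnot(is.list(bundles), !is.null(names(bundles)))
  scores <- tibble(
    name = names(bundles),
    ptm = unname(map_dbl(bundles, function(b) b$ptm %||% NA_real_))
  )
  if (is.null(pairs)) return(scores)
  pairs <- as_tibble(pairs)
  diffs <- pairs |>
    mutate(ptm_a = scores$ptm[match(.data$a, scores$name)],
           ptm_b = scores$ptm[match(.data$b, scores$name)],
           difference = .data$ptm_a - .data$ptm_b)
  list(scores = scores, differences = diffs)
}
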