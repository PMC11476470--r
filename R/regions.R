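#' Chain regions
#'
#' A chain region is an explicit set of (chain, residue-number) pairs used
#' to restrict confidence metrics and superpositions, e.g. "the GP41-1
#' N-intein on chain A" or "the 200 extein residues upstream of the
#' junction".
#'
#' `chain_region()` builds one directly; `resolve_region()` parses a
#' compact expression such as `"A:1-125"` or `"A:1-2,A:5,B:10-20"` and
#' validates every residue against a bundle or structure model.
#'
#' @param chain Chain label(s), recycled against `resno`.
#' @param resno Residue numbers.
#' @return A tibble of class `chain_region` with columns `chain`, `resno`.
#' @export
chain_region <- function(chain, resno) {
  df <- distinct(tibble(chain = as.character(chain), resno = as.integer(resno)))
  if (nrow(df) == 0) abort("A chain region cannot be empty.")
  df <- arrange(df, .data$chain, .data$resno)
  class(df) <- c("chain_region", class(df))
  df
}

#' @rdname chain_region
#' @param x A [confidence_bundle()] or `structure_model` to validate
#'   against (may be `NULL` to skip validation).
#' @param spec A region expression like `"B:1-125"` (comma-separated
#'   `chain:lo-hi` or `chain:res` terms), or an existing `chain_region`.
#' @export
resolve_region <- function(x, spec) {
  if (inherits(spec, "chain_region")) {
    region <- spec
  } else if (is.character(spec) && length(spec) == 1L) {
    terms <- strsplit(spec, ",", fixed = TRUE)[[1]]
    parts <- purrr::map(terms, function(tm) {
      tm <- trimws(tm)
      m <- regmatches(tm, regexec("^([A-Za-z0-9]+):(\\d+)(?:-(\\d+))?$", tm))[[1]]
      if (length(m) == 0) abort(sprintf("Cannot parse region term '%s'.", tm))
      lo <- as.integer(m[3])
      hi <- if (m[4] == "") lo else as.integer(m[4])
      if (hi < lo) abort(sprintf("Reversed range in region term '%s'.", tm))
      tibble(chain = m[2], resno = seq.int(lo, hi))
    })
    region <- chain_region(list_rbind(parts)$chain, list_rbind(parts)$resno)
  } else {
    abort("`spec` must be a region expression string or a chain_region.")
  }
  if (!is.null(x)) {
    avail <- if (inherits(x, "confidence_bundle")) {
      tibble(chain = x$chain_ids, resno = x$res_ids)
    } else if (inherits(x, "structure_model")) {
      tibble(chain = x$chain, resno = x$resno)
    } else {
      abort("`x` must be a confidence_bundle, structure_model or NULL.")
    }
    missing_rows <- dplyr::anti_join(region, avail, by = c("chain", "resno"))
    if (nrow(missing_rows) > 0) {
      abort(sprintf(
        "Region refers to %d residue(s) absent from the object (e.g. %s:%d).",
        nrow(missing_rows), missing_rows$chain[1], missing_rows$resno[1]))
    }
  }
  region
}

# Token indices of a region within a bundle (order: region order).
region_tokens <- function(bundle, region) {
  region <- resolve_region(bundle, region)
  key <- paste(bundle$chain_ids, bundle$res_ids)
  idx <- match(paste(region$chain, region$resno), key)
  idx
}
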