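#' Pair CA atoms between two structure models
#'
#' Pairs residues positionally between corresponding chains of two models
#' (optionally restricted to regions): chains are matched in order of
#' appearance, residues are matched on residue number, and pairs whose
#' residue names disagree are excluded (with a message). This is the
#' CA-level pairing used to compare an intein predicted in complex context
#' against the same intein predicted alone.
#'
#' @param model_a,model_b `structure_model` tibbles from
#'   [read_structure()] or [generate_structure_pair()].
#' @param region_a,region_b Optional regions restricting each model.
#' @return A `coordinate_pairing`: list with `a`, `b` (n x 3 coordinate
#'   matrices) and `meta` (tibble of chain/resno/resid per pair).
#' @export
pair_by_sequence <- function(model_a, model_b, region_a = NULL, region_b = NULL) {
  sub_model <- function(model, region) {
    if (is.null(region)) return(model)
    region <- resolve_region(model, region)
    dplyr::semi_join(model, region, by = c("chain", "resno"))
  }
  a <- sub_model(model_a, region_a)
  b <- sub_model(model_b, region_b)
  chains_a <- unique(a$chain)
  chains_b <- unique(b$chain)
  k <- min(length(chains_a), length(chains_b))
  pairs <- purrr::map(seq_len(k), function(i) {
    ai <- a |> filter(.data$chain == chains_a[i])
    bi <- b |> filter(.data$chain == chains_b[i])
    j <- inner_join(ai, bi, by = "resno", suffix = c("_a", "_b"))
    mismatch <- j$resid_a != j$resid_b
    if (any(mismatch)) {
      inform(sprintf("Excluding %d residue pair(s) with mismatched names in chain %s/%s.",
                     sum(mismatch), chains_a[i], chains_b[i]))
      j <- j[!mismatch, ]
    }
    j
  }) |> list_rbind()
  if (nrow(pairs) < 3) {
    abort("Fewer than 3 matchable residue pairs; cannot superpose.")
  }
  structure(list(
    a = as.matrix(pairs[, c("x_a", "y_a", "z_a")]),
    b = as.matrix(pairs[, c("x_b", "y_b", "z_b")]),
    meta = tibble(chain_a = pairs$chain_a, chain_b = pairs$chain_b,
                  resno = pairs$resno, resid = pairs$resid_a)
  ), class = "coordinate_pairing")
}

#' Pairing from raw coordinate matrices
#'
#' @param a,b n x 3 matrices of paired coordinates.
#' @return A `coordinate_pairing`.
#' @export
coordinate_pairing <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(ncol(a) == 3, ncol(b) == 3, nrow(a) == nrow(b))
  if (nrow(a) < 3) abort("Need at least 3 coordinate pairs.")
  structure(list(a = unname(a), b = unname(b),
                 meta = tibble(chain_a = NA_character_, chain_b = NA_character_,
                               resno = seq_len(nrow(a)), resid = NA_character_)),
            class = "coordinate_pairing")
}

#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation `R` (det +1, via sign-corrected SVD) and
#' translation `t` minimizing the RMSD between the reference coordinates
#' `a` and the transformed moving coordinates `R b + t`. Degenerate
#' (collinear) inputs are rejected.
#'
#' @param pairing A `coordinate_pairing`.
#' @return A `superposition_result`: list with `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom), `n_used`, `cycles` (0),
#'   `used` (logical per input pair), `residuals` (per-pair distances
#'   after superposition, all pairs).
#' @export
kabsch <- function(pairing) {
  stopifnot(inherits(pairing, "coordinate_pairing"))
  fit <- kabsch_core(pairing$a, pairing$b)
  res <- superposition_residuals(pairing, fit)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_used = nrow(pairing$a), cycles = 0L,
                 used = rep(TRUE, nrow(pairing$a)), residuals = res,
                 meta = pairing$meta),
            class = "superposition_result")
}

kabsch_core <- function(a, b) {
  n <- nrow(a)
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  sv <- svd(t(B) %*% A)
  if (sv$d[2] <= 1e-10 * max(sv$d[1], 1e-300)) {
    abort("Degenerate (collinear) coordinates: superposition is not unique.")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(ca - R %*% cb)
  resid <- A - B %*% t(R)
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(rowSums(resid^2))))
}

superposition_residuals <- function(pairing, fit) {
  moved <- pairing$b %*% t(fit$rotation)
  moved <- sweep(moved, 2, fit$translation, `+`)
  sqrt(rowSums((pairing$a - moved)^2))
}

#' Superposition with iterative outlier rejection
#'
#' Emulates PyMOL-style refinement: fit, drop pairs whose residual exceeds
#' `reject_sigma` times the current RMSD (the RMS residual), refit, and
#' repeat until no pair is dropped or `max_cycles` is reached.
#' `max_cycles = 0` is a plain Kabsch fit.
#'
#' @param pairing A `coordinate_pairing`.
#' @param max_cycles Maximum refinement iterations (default 5).
#' @param reject_sigma Rejection multiple of the RMS residual (default 2).
#' @return A `superposition_result`; `rmsd` and the transform refer to the
#'   surviving pairs, `used` flags them, `residuals` covers all input
#'   pairs under the final transform.
#' @export
refine_superpose <- function(pairing, max_cycles = 5L, reject_sigma = 2) {
  stopifnot(inherits(pairing, "coordinate_pairing"),
            max_cycles >= 0, reject_sigma > 0)
  keep <- rep(TRUE, nrow(pairing$a))
  fit <- kabsch_core(pairing$a, pairing$b)
  cycles <- 0L
  while (cycles < max_cycles) {
    r_keep <- superposition_residuals(
      list(a = pairing$a[keep, , drop = FALSE],
           b = pairing$b[keep, , drop = FALSE]), fit)
    cutoff <- reject_sigma * fit$rmsd
    drop_now <- r_keep > cutoff & cutoff > 0
    if (!any(drop_now)) break
    if (sum(keep) - sum(drop_now) < 3) {
      abort("Outlier rejection would leave fewer than 3 pairs.")
    }
    keep[which(keep)[drop_now]] <- FALSE
    fit <- kabsch_core(pairing$a[keep, , drop = FALSE],
                       pairing$b[keep, , drop = FALSE])
    cycles <- cycles + 1L
  }
  res <- superposition_residuals(pairing, fit)
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = fit$rmsd, n_used = sum(keep), cycles = cycles,
                 used = keep, residuals = res, meta = pairing$meta),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition_result> rmsd = %.4f A over %d pairs (%d cycle%s)\n",
              x$rmsd, x$n_used, x$cycles, if (x$cycles == 1) "" else "s"))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#'
#' @param result A `superposition_result`.
#' @param coords n x 3 matrix.
#' @return The transformed n x 3 matrix `R coords + t`.
#' @export
apply_transform <- function(result, coords) {
  coords <- as.matrix(coords)
  sweep(coords %*% t(result$rotation), 2, result$translation, `+`)
}

#' @rdname kabsch
#' @param x A `superposition_result`.
#' @param ... Unused.
#' @export
tidy.superposition_result <- function(x, ...) {
  tibble(x$meta, residual = x$residuals, used = x$used)
}

#' @rdname kabsch
#' @export
glance.superposition_result <- function(x, ...) {
  tibble(rmsd = x$rmsd, n_used = x$n_used, cycles = x$cycles,
         det_rotation = det(x$rotation))
}
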