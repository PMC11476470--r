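#' Generate a synthetic AlphaFold3-like confidence bundle
#'
#' Builds a two-chain bundle with a planted inter-chain interaction
#' fraction: exactly `round(planted_fraction * n_pairs)` of the
#' `n_pairs = 2 * n_res_a * n_res_b` ordered cross pairs get a PAE drawn
#' below the threshold (uniform on `pae_low`), the rest above (uniform on
#' `pae_high`). Contact probabilities are symmetric and are drawn from
#' `contact_high` on unordered cross pairs with at least one qualifying
#' direction, `contact_low` elsewhere. Within-chain PAE is low (the chains
#' are individually well-predicted); pLDDT is Gaussian, clipped to
#' \[0, 100\]. Only threshold-side membership matters for the metrics
#' under test, so no attempt is made to mimic AlphaFold's real error
#' distribution or its spatial correlation.
#'
#' @param n_res_a,n_res_b Residues in chains A and B.
#' @param planted_fraction Target fraction of qualifying cross pairs in
#'   \[0, 1\].
#' @param threshold PAE cutoff (Angstrom) the fraction refers to.
#' @param pae_low,pae_high Sampling ranges (Angstrom) strictly below/above
#'   `threshold`.
#' @param plddt_mean,plddt_sd Per-residue pLDDT distribution.
#' @param contact_high,contact_low Contact-probability ranges for
#'   qualifying vs non-qualifying pairs.
#' @param ptm Optional planted pTM scalar.
#' @param seed Integer seed; identical arguments + seed give an identical
#'   bundle.
#' @return A list: `bundle` (a [confidence_bundle()]) and `truth`
#'   (`planted_fraction`, `n_pairs`, `n_below`, `expected_pct`,
#'   `region_a`, `region_b`).
#' @export
generate_bundle <- function(n_res_a, n_res_b, planted_fraction,
                            threshold = 10, pae_low = c(3, 8),
                            pae_high = c(15, 31), plddt_mean = 85,
                            plddt_sd = 8, contact_high = c(0.5, 0.95),
                            contact_low = c(0, 0.05), ptm = NULL,
                            seed = 1L) {
  stopifnot(planted_fraction >= 0, planted_fraction <= 1,
            pae_low[2] < threshold, pae_high[1] > threshold,
            pae_low[1] > 0)
  set.seed(seed)
  n <- n_res_a + n_res_b
  chain_ids <- c(rep("A", n_res_a), rep("B", n_res_b))
  res_ids <- c(seq_len(n_res_a), seq_len(n_res_b))
  ia <- seq_len(n_res_a)
  ib <- n_res_a + seq_len(n_res_b)

  pae <- matrix(runif(n * n, 0.5, 6), n, n)
  diag(pae) <- 0.25
  n_pairs <- 2L * n_res_a * n_res_b
  k <- round(planted_fraction * n_pairs)
  if (abs(k - planted_fraction * n_pairs) > 1e-9) {
    inform(sprintf(
      "planted_fraction %.6g is not representable with %d cross pairs; using %d/%d = %.6g.",
      planted_fraction, n_pairs, k, n_pairs, k / n_pairs))
  }
  # ordered cross cells: first block rows A cols B, then rows B cols A
  cross_cells <- rbind(
    as.matrix(expand.grid(row = ia, col = ib)),
    as.matrix(expand.grid(row = ib, col = ia))
  )
  qual <- sample.int(n_pairs, k)
  lo_cells <- cross_cells[qual, , drop = FALSE]
  hi_cells <- cross_cells[-qual, , drop = FALSE]
  if (k == n_pairs) hi_cells <- cross_cells[0, , drop = FALSE]
  if (k == 0) { lo_cells <- cross_cells[0, , drop = FALSE]; hi_cells <- cross_cells }
  pae[lo_cells] <- runif(nrow(lo_cells), pae_low[1], pae_low[2])
  pae[hi_cells] <- runif(nrow(hi_cells), pae_high[1], pae_high[2])
  pae <- pmin(pae, 31.75)

  cp <- matrix(runif(n * n, contact_low[1], contact_low[2]), n, n)
  cp[lower.tri(cp)] <- t(cp)[lower.tri(cp)]
  if (nrow(lo_cells) > 0) {
    # one draw per unordered pair keeps the matrix exactly symmetric even
    # when both directions of a pair qualify
    un <- unique(cbind(pmin(lo_cells[, 1], lo_cells[, 2]),
                       pmax(lo_cells[, 1], lo_cells[, 2])))
    v <- runif(nrow(un), contact_high[1], contact_high[2])
    cp[un] <- v
    cp[un[, c(2, 1), drop = FALSE]] <- v
  }
  diag(cp) <- 1

  plddt <- pmin(pmax(rnorm(n, plddt_mean, plddt_sd), 0), 100)

  bundle <- confidence_bundle(chain_ids, res_ids, plddt, pae,
                              contact_probs = cp, ptm = ptm)
  truth <- list(planted_fraction = planted_fraction, n_pairs = n_pairs,
                n_below = k, expected_pct = 100 * k / n_pairs,
                region_a = sprintf("A:1-%d", n_res_a),
                region_b = sprintf("B:1-%d", n_res_b))
  list(bundle = bundle, truth = truth)
}

#' Generate a toy structure pair with a known rigid transform
#'
#' Model A is an ideal alpha-helical CA trace (rise 1.5 Angstrom, 100
#' degrees per residue, radius 2.3 Angstrom) or a self-avoiding-ish random
#' coil with 3.8 Angstrom CA-CA steps. Model B is A under a known rotation
#' and translation, plus optional isotropic Gaussian noise and planted
#' outliers displaced by `outlier_shift` in random directions.
#'
#' @param n_res Residue count.
#' @param geometry `"helix"` or `"coil"`.
#' @param noise_sigma Per-coordinate Gaussian noise sd (Angstrom) added to
#'   model B.
#' @param n_outliers Number of planted outlier residues.
#' @param outlier_shift Outlier displacement magnitude (Angstrom).
#' @param rotation,translation Optional fixed transform; random when NULL.
#' @param seed Integer seed.
#' @return A list: `model_a`, `model_b` (structure_model tibbles, chain
#'   "A"), `rotation`, `translation`, `outlier_resno`.
#' @export
generate_structure_pair <- function(n_res = 100, geometry = c("helix", "coil"),
                                    noise_sigma = 0, n_outliers = 0,
                                    outlier_shift = 10, rotation = NULL,
                                    translation = NULL, seed = 1L) {
  geometry <- match.arg(geometry)
  set.seed(seed)
  i <- seq_len(n_res)
  if (geometry == "helix") {
    ang <- (i - 1) * 100 * pi / 180
    xyz <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (i - 1))
  } else {
    steps <- matrix(rnorm(3 * n_res), ncol = 3)
    steps <- 3.8 * steps / sqrt(rowSums(steps^2))
    xyz <- apply(steps, 2, cumsum)
  }
  if (is.null(rotation)) rotation <- random_rotation()
  if (is.null(translation)) translation <- runif(3, -20, 20)
  noisy <- xyz %*% t(rotation) +
    matrix(translation, n_res, 3, byrow = TRUE) +
    matrix(rnorm(3 * n_res, 0, noise_sigma), ncol = 3)
  outlier_resno <- integer(0)
  if (n_outliers > 0) {
    outlier_resno <- sort(sample.int(n_res, n_outliers))
    dirs <- matrix(rnorm(3 * n_outliers), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    noisy[outlier_resno, ] <- noisy[outlier_resno, ] + outlier_shift * dirs
  }
  resid <- sample(.std_res3, n_res, replace = TRUE)
  mk <- function(m) new_structure_model(tibble(
    chain = "A", resno = i, resid = resid,
    x = m[, 1], y = m[, 2], z = m[, 3]))
  list(model_a = mk(xyz), model_b = mk(noisy),
       rotation = rotation, translation = translation,
       outlier_resno = outlier_resno)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a random reporter-like sequence with planted split sites
#'
#' Random protein sequence containing exactly `n_ser_sites` serines, all
#' at interior positions (2..n), so [enumerate_split_sites()] recovers
#' exactly `n_ser_sites` candidate junctions.
#'
#' @param n_res Sequence length.
#' @param n_ser_sites Number of serines to plant.
#' @param seed Integer seed.
#' @return A protein sequence with attribute `ser_positions`.
#' @export
generate_reporter_sequence <- function(n_res, n_ser_sites, seed = 1L) {
  stopifnot(n_res >= 2, n_ser_sites >= 0, n_ser_sites <= n_res - 1)
  set.seed(seed)
  non_ser <- setdiff(names(.aa_residue_mass), "S")
  aa <- sample(non_ser, n_res, replace = TRUE)
  pos <- integer(0)
  if (n_ser_sites > 0) {
    pos <- sort(sample(2:n_res, n_ser_sites))
    aa[pos] <- "S"
  }
  seq <- paste(aa, collapse = "")
  attr(seq, "ser_positions") <- pos
  seq
}
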