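# Independent brute-force oracles, deliberately naive.

# Double-loop interface statistics over explicit residue index vectors.
oracle_interface <- function(pae, contact, ia, ib, threshold) {
  vals <- c()
  cps <- c()
  for (a in ia) for (b in ib) {
    vals <- c(vals, pae[a, b], pae[b, a])
    if (!is.null(contact)) cps <- c(cps, contact[a, b], contact[b, a])
  }
  below <- vals < threshold
  list(
    n_pairs = length(vals),
    pct = 100 * sum(below) / length(vals),
    mean_pae = mean(vals),
    cond = if (!is.null(contact) && any(below)) mean(cps[below]) else NA_real_
  )
}

# Character-by-character serine scan.
oracle_split_sites <- function(seq) {
  aa <- strsplit(seq, "")[[1]]
  out <- integer(0)
  for (i in seq_len(length(aa) - 1)) {
    if (aa[i + 1] == "S") out <- c(out, i)
  }
  out
}

random_protein <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# A raw random bundle (no planted structure) for oracle comparisons.
random_bundle <- function(n_a, n_b, seed, with_contact = TRUE) {
  set.seed(seed)
  n <- n_a + n_b
  pae <- matrix(runif(n * n, 0.25, 31.75), n, n)
  cp <- NULL
  if (with_contact) {
    cp <- matrix(runif(n * n), n, n)
    cp[lower.tri(cp)] <- t(cp)[lower.tri(cp)]
  }
  confidence_bundle(
    chain_ids = c(rep("A", n_a), rep("B", n_b)),
    res_ids = c(seq_len(n_a), seq_len(n_b)),
    plddt = runif(n, 0, 100), pae = pae, contact_probs = cp
  )
}

rigid_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, `+`)
}

rand_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
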