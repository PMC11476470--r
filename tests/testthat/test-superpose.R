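test_that("identical coordinate sets superpose at zero RMSD", {
  sp <- generate_structure_pair(50, noise_sigma = 0, seed = 1,
                                rotation = diag(3), translation = c(0, 0, 0))
  fit <- kabsch(pair_by_sequence(sp$model_a, sp$model_b))
  expect_lt(fit$rmsd, 1e-12)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("a known rigid transform is recovered to numerical precision", {
  set.seed(8)
  for (i in 1:20) {
    R <- rand_rotation()
    t <- runif(3, -50, 50)
    a <- matrix(rnorm(3 * 20, sd = 10), ncol = 3)
    b <- rigid_transform(a, R, t)
    # moving b back onto a must invert the transform
    fit <- kabsch(coordinate_pairing(a, b))
    expect_lt(fit$rmsd, 1e-9)
    expect_lt(max(abs(fit$rotation - t(R))), 1e-9)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    # residual identity: applying the transform reproduces the rmsd
    moved <- apply_transform(fit, b)
    expect_equal(sqrt(mean(rowSums((a - moved)^2))), fit$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("mirrored coordinates never yield an improper rotation", {
  set.seed(21)
  for (i in 1:10) {
    a <- matrix(rnorm(30, sd = 5), ncol = 3)
    b <- a %*% diag(c(-1, 1, 1)) # reflection
    fit <- kabsch(coordinate_pairing(a, b))
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
    expect_gt(fit$rmsd, 0.1) # a reflection cannot be absorbed
  }
})

test_that("RMSD is invariant under rigid transforms of either input", {
  sp <- generate_structure_pair(80, noise_sigma = 0.7, seed = 12)
  pairing <- pair_by_sequence(sp$model_a, sp$model_b)
  base <- kabsch(pairing)$rmsd
  set.seed(13)
  R <- rand_rotation(); t <- runif(3, -30, 30)
  moved_a <- rigid_transform(pairing$a, R, t)
  moved_b <- rigid_transform(pairing$b, R, t)
  expect_equal(kabsch(coordinate_pairing(moved_a, pairing$b))$rmsd, base,
               tolerance = 1e-9)
  expect_equal(kabsch(coordinate_pairing(pairing$a, moved_b))$rmsd, base,
               tolerance = 1e-9)
  # swap symmetry
  expect_equal(kabsch(coordinate_pairing(pairing$b, pairing$a))$rmsd, base,
               tolerance = 1e-9)
})

test_that("degenerate inputs are rejected", {
  line <- cbind(1:10, 0, 0)
  expect_error(kabsch(coordinate_pairing(line, line)), "collinear")
  expect_error(coordinate_pairing(matrix(0, 2, 3), matrix(0, 2, 3)),
               "at least 3")
})

test_that("pairing matches residues and logs gaps and mismatches", {
  sp <- generate_structure_pair(5, seed = 3)
  p <- pair_by_sequence(sp$model_a, sp$model_b)
  expect_equal(nrow(p$a), 5)
  # one model missing residue 3 -> 4 pairs
  m_b <- sp$model_b[sp$model_b$resno != 3, ]
  p4 <- pair_by_sequence(sp$model_a, m_b)
  expect_equal(nrow(p4$a), 4)
  expect_false(3 %in% p4$meta$resno)
  # a renamed residue is excluded with a message
  m_mis <- sp$model_b
  m_mis$resid[2] <- setdiff(c("ALA", "GLY"), m_mis$resid[2])[1]
  expect_message(p_mis <- pair_by_sequence(sp$model_a, m_mis), "mismatched")
  expect_equal(nrow(p_mis$a), 4)
  expect_error(pair_by_sequence(sp$model_a, m_b[1:2, ]), "Fewer than 3")
})

test_that("refinement leaves clean data alone and strips planted outliers", {
  clean <- generate_structure_pair(100, noise_sigma = 0, seed = 30)
  pairing <- pair_by_sequence(clean$model_a, clean$model_b)
  plain <- kabsch(pairing)
  refined <- refine_superpose(pairing)
  expect_lte(refined$cycles, 1)
  expect_equal(refined$rmsd, plain$rmsd, tolerance = 1e-12)
  expect_equal(refined$n_used, 100)
  noisy <- generate_structure_pair(100, noise_sigma = 0.4, seed = 32)
  pn <- pair_by_sequence(noisy$model_a, noisy$model_b)
  expect_lte(refine_superpose(pn)$rmsd, kabsch(pn)$rmsd + 1e-12)
  # 95 clean + 5 outliers at 10 A
  dirty <- generate_structure_pair(100, noise_sigma = 0.4, n_outliers = 5,
                                   outlier_shift = 10, seed = 31)
  pd <- pair_by_sequence(dirty$model_a, dirty$model_b)
  ref <- refine_superpose(pd)
  expect_true(all(!ref$used[dirty$outlier_resno]))
  # within 10% of the fit on the clean pairs only
  clean_fit <- kabsch(coordinate_pairing(pd$a[-dirty$outlier_resno, ],
                                         pd$b[-dirty$outlier_resno, ]))
  expect_lt(abs(ref$rmsd - clean_fit$rmsd) / clean_fit$rmsd, 0.10)
  expect_lte(ref$rmsd, kabsch(pd)$rmsd)
})

test_that("tidy and glance expose per-pair residuals and fit summary", {
  sp <- generate_structure_pair(40, noise_sigma = 0.3, n_outliers = 2,
                                outlier_shift = 8, seed = 55)
  fit <- refine_superpose(pair_by_sequence(sp$model_a, sp$model_b))
  td <- tidy(fit)
  expect_equal(nrow(td), 40)
  expect_true(all(td$residual[!td$used] > max(td$residual[td$used])))
  gl <- glance(fit)
  expect_equal(gl$n_used, sum(td$used))
  expect_equal(gl$det_rotation, 1, tolerance = 1e-9)
})
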