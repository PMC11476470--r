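ed <- system.file("extdata", package = "midisplit")

test_that("the AF3-server dialect fixture parses with atom-level collapse", {
  b <- read_confidence(file.path(ed, "af3_server_example.json"))
  expect_s3_class(b, "confidence_bundle")
  expect_equal(length(b$chain_ids), 4)
  # residue pLDDT = mean of its atoms' pLDDTs
  expect_equal(b$plddt, c(mean(c(80, 90, 100)), mean(c(70, 80)),
                          mean(c(60, 70)), mean(c(90, 95))))
  expect_equal(b$pae[1, 2], 2)
  expect_equal(b$pae[2, 1], 3) # asymmetry preserved, no transposition
  expect_equal(b$ptm, 0.83)
  expect_equal(unique(b$chain_ids), c("A", "B"))
})

test_that("minimal plain-dialect bundles parse as written", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(chain_ids = c("A", "A"), res_ids = 1:2,
                            plddt = c(50, 60),
                            pae = matrix(c(1, 2, 3, 4), 2, byrow = TRUE)),
                       path, auto_unbox = TRUE, digits = NA)
  b <- read_confidence(path)
  expect_equal(b$pae, matrix(c(1, 2, 3, 4), 2, byrow = TRUE))
  expect_null(b$contact_probs)
  expect_null(b$ptm)
})

test_that("parse -> serialize -> parse is idempotent", {
  gb <- generate_bundle(8, 6, 0.3, ptm = 0.71, seed = 5)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_confidence(gb$bundle, p1)
  b1 <- read_confidence(p1)
  write_confidence(b1, p2)
  b2 <- read_confidence(p2)
  expect_equal(b1, b2)
  expect_equal(b1$pae, gb$bundle$pae)
  expect_equal(b1$contact_probs, gb$bundle$contact_probs)
})

test_that("missing PAE is fatal; non-protein tokens are rejected", {
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(chain_ids = "A", res_ids = 1, plddt = 50), p,
                       auto_unbox = TRUE)
  expect_error(read_confidence(p), "pae")
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(chain_ids = c("A", "A"), res_ids = 1:2,
                            plddt = c(50, 60), token_res_names = c("ALA", "NAG"),
                            pae = matrix(1, 2, 2)), p2, auto_unbox = TRUE)
  expect_error(read_confidence(p2), "Non-protein")
})

test_that("bundle invariants are enforced", {
  expect_error(confidence_bundle("A", 1, 120, matrix(1)), "pLDDT")
  expect_error(confidence_bundle(c("A", "A"), 1:2, c(50, 60),
                                 matrix(-1, 2, 2)), ">= 0")
  cp <- matrix(c(1, 0.5, 0.2, 1), 2)
  expect_error(confidence_bundle(c("A", "A"), 1:2, c(50, 60),
                                 matrix(1, 2, 2), contact_probs = cp),
               "symmetric")
  expect_error(confidence_bundle(c("A", "A"), 1:2, c(50, 60),
                                 matrix(1, 3, 3)), "token count")
})

test_that("PDB and mmCIF serializations load to the identical CA model", {
  m_pdb <- read_structure(file.path(ed, "toy_model.pdb"))
  m_cif <- read_structure(file.path(ed, "toy_model.cif"))
  expect_equal(as.data.frame(m_pdb), as.data.frame(m_cif))
  expect_equal(nrow(m_pdb), 3)
  expect_equal(m_pdb$resid, c("ALA", "GLY", "SER"))
})

test_that("residues without CA are dropped with a warning", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 90.00           C",
    "ATOM      2  N   GLY A   2       1.000   0.000   0.000  1.00 90.00           N",
    "ATOM      3  CA  SER A   3       2.000   0.000   0.000  1.00 90.00           C",
    "END"), p)
  expect_warning(m <- read_structure(p), "without a CA")
  expect_equal(m$resno, c(1L, 3L))
})

test_that("region expressions resolve to explicit residue sets", {
  b <- random_bundle(10, 5, seed = 9)
  r <- resolve_region(b, "A:1-3")
  expect_equal(r$resno, 1:3)
  u <- resolve_region(b, "A:1-2,A:5")
  expect_equal(u$resno, c(1L, 2L, 5L))
  multi <- resolve_region(b, "A:9-10,B:1-2")
  expect_equal(multi$chain, c("A", "A", "B", "B"))
  expect_error(resolve_region(b, "A:11-12"), "absent")
  expect_error(resolve_region(b, "C:1"), "absent")
  expect_error(resolve_region(b, "A:"), "parse")
})
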