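#' Construct a confidence bundle
#'
#' The in-memory form of an AlphaFold3 confidence download: per-residue
#' pLDDT, the token-pair PAE matrix (rows = aligned/conditioning residue,
#' stored exactly as in the file; it is generally asymmetric), the optional
#' contact-probability matrix and the optional global pTM. All tokens must
#' be protein residues; one token per residue after atom-level collapse.
#'
#' @param chain_ids Character vector, chain label per residue token.
#' @param res_ids Integer vector, residue number per token.
#' @param plddt Numeric vector in \[0, 100\], one value per token.
#' @param pae Square numeric matrix (Angstrom), `N x N`.
#' @param contact_probs Optional symmetric numeric matrix in \[0, 1\].
#' @param ptm Optional scalar in \[0, 1\].
#' @return An object of class `confidence_bundle`.
#' @export
confidence_bundle <- function(chain_ids, res_ids, plddt, pae,
                              contact_probs = NULL, ptm = NULL) {
  n <- length(chain_ids)
  if (length(res_ids) != n || length(plddt) != n) {
    abort("chain_ids, res_ids and plddt must have one entry per token.")
  }
  pae <- as.matrix(pae)
  if (nrow(pae) != n || ncol(pae) != n) {
    abort(sprintf("PAE must be a %d x %d matrix to match the token count.", n, n))
  }
  if (any(pae < 0)) abort("PAE values must be >= 0.")
  if (any(plddt < 0 | plddt > 100)) abort("pLDDT values must lie in [0, 100].")
  if (!is.null(contact_probs)) {
    contact_probs <- as.matrix(contact_probs)
    if (!all(dim(contact_probs) == n)) {
      abort("contact_probs must match the token count.")
    }
    if (any(contact_probs < 0 | contact_probs > 1)) {
      abort("contact probabilities must lie in [0, 1].")
    }
    if (max(abs(contact_probs - t(contact_probs))) > 1e-6) {
      abort("contact_probs must be symmetric (within 1e-6).")
    }
  }
  if (!is.null(ptm) && (ptm < 0 || ptm > 1)) abort("ptm must lie in [0, 1].")
  structure(list(chain_ids = as.character(chain_ids),
                 res_ids = as.integer(res_ids),
                 plddt = as.numeric(plddt), pae = pae,
                 contact_probs = contact_probs,
                 ptm = if (is.null(ptm)) NULL else as.numeric(ptm)),
            class = "confidence_bundle")
}

#' @export
print.confidence_bundle <- function(x, ...) {
  cat("<confidence_bundle>", length(x$chain_ids), "residue tokens,",
      length(unique(x$chain_ids)), "chain(s)",
      if (is.null(x$contact_probs)) "(no contact_probs)" else "",
      if (is.null(x$ptm)) "" else sprintf("pTM = %.2f", x$ptm), "\n")
  invisible(x)
}

#' Residue tokens of a bundle as a tibble
#'
#' @param bundle A [confidence_bundle()].
#' @return A tibble with columns `token`, `chain`, `resno`, `plddt`.
#' @export
bundle_tokens <- function(bundle) {
  stopifnot(inherits(bundle, "confidence_bundle"))
  tibble(token = seq_along(bundle$chain_ids), chain = bundle$chain_ids,
         resno = bundle$res_ids, plddt = bundle$plddt)
}

#' Read an AlphaFold3 confidence JSON
#'
#' Two dialects are supported and auto-detected:
#' \describe{
#'   \item{server}{The AlphaFold3-server "full data" download: per-atom
#'     `atom_plddts` with `atom_chain_ids`/`atom_res_ids`, token-level
#'     `token_chain_ids`/`token_res_ids`, `pae`, optional `contact_probs`
#'     and optional `ptm`. Atom pLDDTs are collapsed to per-residue means.}
#'   \item{plain}{Already per-residue: `chain_ids`, `res_ids`, `plddt`,
#'     `pae`, optional `contact_probs`/`ptm`. This is the dialect
#'     [write_confidence()] emits and the synthetic generator uses.}
#' }
#' A missing PAE matrix is a hard error; missing contact probabilities give
#' a bundle whose `contact_probs` is `NULL` (metrics that need them flag
#' the result as absent). Non-protein tokens (anything whose
#' `token_res_names`, when present, is not a standard amino acid) are
#' rejected.
#'
#' @param path JSON file path.
#' @return A [confidence_bundle()].
#' @export
read_confidence <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$pae)) abort("Confidence JSON has no `pae` matrix.")
  if (!is.null(j$token_res_names)) {
    std3 <- c("ALA","ARG","ASN","ASP","CYS","GLU","GLN","GLY","HIS","ILE",
              "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")
    bad <- setdiff(unique(toupper(j$token_res_names)), std3)
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-protein tokens are not supported (found: %s). Strip ligands/glycans before analysis.",
        paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(j$atom_plddts)) {
    if (is.null(j$atom_chain_ids) || is.null(j$atom_res_ids)) {
      abort("Server-dialect JSON needs atom_chain_ids and atom_res_ids alongside atom_plddts.")
    }
    chain_ids <- j$token_chain_ids
    res_ids <- j$token_res_ids
    if (is.null(chain_ids) || is.null(res_ids)) {
      abort("Server-dialect JSON needs token_chain_ids and token_res_ids.")
    }
    key <- paste(j$atom_chain_ids, j$atom_res_ids)
    means <- tapply(j$atom_plddts, key, mean)
    plddt <- as.numeric(means[paste(chain_ids, res_ids)])
    if (anyNA(plddt)) abort("Some tokens have no atoms in the pLDDT arrays.")
  } else {
    chain_ids <- j$chain_ids %||% j$token_chain_ids
    res_ids <- j$res_ids %||% j$token_res_ids
    plddt <- j$plddt
    if (is.null(chain_ids) || is.null(res_ids) || is.null(plddt)) {
      abort("Plain-dialect JSON needs chain_ids, res_ids and plddt.")
    }
  }
  confidence_bundle(chain_ids, res_ids, plddt, j$pae,
                    contact_probs = j$contact_probs, ptm = j$ptm)
}

#' Write a bundle in the normalized (plain) JSON dialect
#'
#' @param bundle A [confidence_bundle()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confidence <- function(bundle, path) {
  stopifnot(inherits(bundle, "confidence_bundle"))
  out <- list(chain_ids = bundle$chain_ids, res_ids = bundle$res_ids,
              plddt = bundle$plddt, pae = bundle$pae)
  if (!is.null(bundle$contact_probs)) out$contact_probs <- bundle$contact_probs
  if (!is.null(bundle$ptm)) out$ptm <- bundle$ptm
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# --- structures ------------------------------------------------------------

.std_res3 <- c("ALA","ARG","ASN","ASP","CYS","GLU","GLN","GLY","HIS","ILE",
               "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

new_structure_model <- function(df) {
  df <- as_tibble(df)[, c("chain", "resno", "resid", "x", "y", "z")]
  df <- df |> arrange(.data$chain, .data$resno)
  dup <- df |> dplyr::count(.data$chain, .data$resno) |> filter(n > 1)
  if (nrow(dup) > 0) abort("Duplicate (chain, resno) residues in structure.")
  class(df) <- c("structure_model", class(df))
  df
}

# Minimal name-keyed mmCIF _atom_site reader (handles arbitrary column
# order, which AF3-server files need).
read_atom_site_cif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0) abort("No _atom_site loop in mmCIF file.")
  cols <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1L
  body <- character()
  for (i in body_start:length(lines)) {
    l <- trimws(lines[i])
    if (l == "" || startsWith(l, "#") || startsWith(l, "_") ||
        startsWith(l, "loop_") || startsWith(l, "data_")) break
    body <- c(body, l)
  }
  toks <- scan(text = body, what = character(), quiet = TRUE,
               quote = "'\"")
  if (length(toks) %% length(cols) != 0) {
    abort("Malformed _atom_site loop: token count not a multiple of the column count.")
  }
  m <- matrix(toks, ncol = length(cols), byrow = TRUE)
  colnames(m) <- cols
  as_tibble(m)
}

#' Read a structure model (CA-only) from PDB or mmCIF
#'
#' Keeps one CA coordinate per standard amino-acid residue; chain labels
#' and residue numbers are preserved (auth numbering for mmCIF when
#' present). Residues with no CA atom are dropped with a warning;
#' insertion codes are rejected.
#'
#' @param path A `.pdb` or `.cif`/`.mmcif` file.
#' @return A `structure_model` tibble with columns `chain`, `resno`,
#'   `resid` (3-letter code), `x`, `y`, `z`.
#' @export
read_structure <- function(path) {
  if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
    a <- read_atom_site_cif(path)
    pick <- function(nm, alt = NULL) {
      if (nm %in% names(a)) a[[nm]] else if (!is.null(alt) && alt %in% names(a)) a[[alt]] else NULL
    }
    atoms <- tibble(
      elety = pick("label_atom_id", "auth_atom_id"),
      resid = toupper(pick("auth_comp_id", "label_comp_id")),
      chain = pick("auth_asym_id", "label_asym_id"),
      resno = suppressWarnings(as.integer(pick("auth_seq_id", "label_seq_id"))),
      insert = pick("pdbx_PDB_ins_code") %||% "?",
      x = as.numeric(a$Cartn_x), y = as.numeric(a$Cartn_y),
      z = as.numeric(a$Cartn_z),
      type = pick("group_PDB") %||% "ATOM"
    )
    atoms$insert[atoms$insert %in% c("?", ".")] <- NA_character_
  } else {
    p <- bio3d::read.pdb(path)
    atoms <- as_tibble(p$atom[, c("elety", "resid", "chain", "resno",
                                  "insert", "x", "y", "z", "type")])
  }
  atoms <- atoms |> filter(.data$type == "ATOM")
  if (any(!is.na(atoms$insert) & nzchar(atoms$insert))) {
    abort("Insertion codes are not supported; renumber the structure first.")
  }
  atoms <- atoms |> filter(.data$resid %in% .std_res3)
  ca <- atoms |> filter(.data$elety == "CA")
  all_res <- atoms |> distinct(.data$chain, .data$resno)
  ca_res <- ca |> distinct(.data$chain, .data$resno)
  n_dropped <- nrow(all_res) - nrow(ca_res)
  if (n_dropped > 0) {
    warn(sprintf("%d residue(s) without a CA atom were dropped.", n_dropped))
  }
  new_structure_model(ca)
}
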