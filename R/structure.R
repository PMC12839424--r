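#' Single-chain C-alpha structure model
#'
#' Ordered C-alpha trace of one protein chain: every backbone-level metric in
#' this package (global/local RMSD, neighbor distances) is defined on Cα
#' atoms, so the model keeps one coordinate per residue. Residues are
#' renumbered sequentially from 1; author numbering is preserved in the
#' `author` column.
#'
#' @param chain_id Chain identifier.
#' @param aa Character vector of one-letter codes (unknown residues `"X"`).
#' @param xyz Numeric matrix, `n x 3`, Cα coordinates in Angstrom.
#' @param author Optional character vector of author residue numbers
#'   (insertion codes folded in).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(chain_id, aa, xyz, author = as.character(seq_along(aa))) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L || nrow(xyz) != length(aa))
    vs_abort("xyz must be an n x 3 matrix matching length(aa)", "varstruct_domain")
  if (nrow(xyz) < 2L)
    vs_abort("a structure model needs at least 2 residues", "varstruct_empty_model")
  if (any(!is.finite(xyz)))
    vs_abort("non-finite coordinates", "varstruct_domain")
  aa <- toupper(aa)
  bad <- !aa %in% c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], "X")
  if (any(bad)) aa[bad] <- "X"
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(chain_id = chain_id,
                 residues = data.frame(index = seq_along(aa), aa = aa,
                                       x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                       author = author)),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> chain %s: %d residues (C-alpha trace)\n",
              x$chain_id, nrow(x$residues)))
  invisible(x)
}

#' Number of residues in a structure model
#' @param model A [structure_model()].
#' @return Integer count.
#' @export
n_residues <- function(model) nrow(model$residues)

#' C-alpha coordinate matrix
#' @param model A [structure_model()].
#' @return Numeric `n x 3` matrix (Angstrom).
#' @export
ca_coords <- function(model) {
  m <- as.matrix(model$residues[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' One-letter sequence of a structure model
#' @param model A [structure_model()].
#' @return Amino-acid string, one letter per residue in order.
#' @export
sequence_of <- function(model) paste(model$residues$aa, collapse = "")

#' Read a single-chain C-alpha model from a PDB file
#'
#' Parses ATOM records via bio3d, keeps Cα atoms of the requested chain,
#' resolves altlocs by highest occupancy then first-seen, skips residues
#' lacking a Cα (with a warning), and renumbers residues sequentially while
#' keeping author numbering (insertion codes folded in).
#'
#' @param path PDB file.
#' @param chain Chain identifier. Required when the file holds several
#'   chains; a single-chain file may omit it.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, chain = NULL) {
  # rm.alt = FALSE: altlocs are resolved here (highest occupancy, first seen)
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                          verbose = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      vs_abort(sprintf("file has chains %s; specify one explicitly",
                       paste(chains, collapse = ", ")),
               "varstruct_chain_not_found")
    chain <- chains[1L]
  }
  if (!chain %in% chains)
    vs_abort(sprintf("chain '%s' not found (available: %s)", chain,
                     paste(chains, collapse = ", ")),
             "varstruct_chain_not_found")
  at <- at[at$chain == chain, , drop = FALSE]

  res_key <- paste0(at$resno, ifelse(is.na(at$insert) | at$insert == "", "",
                                     at$insert))
  at$res_key <- res_key
  keys <- unique(res_key)  # file order
  ca <- at[at$elety == "CA", , drop = FALSE]
  n_skipped <- sum(!keys %in% ca$res_key)
  if (n_skipped > 0L)
    vs_warn(sprintf("%d residue(s) without a C-alpha atom skipped", n_skipped),
            "varstruct_missing_ca")
  if (nrow(ca) == 0L)
    vs_abort(sprintf("no C-alpha atoms in chain '%s'", chain),
             "varstruct_empty_model")

  pick <- lapply(split(seq_len(nrow(ca)), factor(ca$res_key, levels = unique(ca$res_key))),
                 function(ii) {
                   occ <- ca$o[ii]
                   occ[is.na(occ)] <- 1
                   ii[which.max(occ)]  # highest occupancy, first seen on ties
                 })
  ca <- ca[unlist(pick, use.names = FALSE), , drop = FALSE]

  aa <- vapply(ca$resid, function(r) {
    one <- suppressWarnings(bio3d::aa321(r))
    if (is.na(one) || !nzchar(one)) "X" else one
  }, "")
  structure_model(chain, aa, cbind(ca$x, ca$y, ca$z), author = ca$res_key)
}

#' Write a C-alpha model as PDB ATOM records
#'
#' Emits standard fixed-column ATOM records (Cα only), occupancy 1.00,
#' B-factor 0.00, sequential residue numbering.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  xyz <- ca_coords(model)
  if (any(abs(xyz) > 9999.999))
    vs_abort("coordinate exceeds the PDB fixed-column width (|x| > 9999.999)",
             "varstruct_io")
  resid3 <- vapply(model$residues$aa, function(a) {
    three <- suppressWarnings(bio3d::aa123(a))
    if (is.na(three) || !nzchar(three)) "UNK" else three
  }, "")
  suppressWarnings(bio3d::write.pdb(
    file = path, xyz = as.vector(t(xyz)),
    resno = model$residues$index, resid = resid3,
    chain = model$chain_id, elety = rep("CA", n_residues(model)),
    o = rep(1, n_residues(model)), b = rep(0, n_residues(model))))
  invisible(path)
}
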