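# Independent oracles and fixture builders. Nothing here shares code with
# the implementation paths it checks.

# --- rotations ---------------------------------------------------------------

# Rodrigues rotation from a rotation vector (axis * angle).
rot_from_vec <- function(r) {
  theta <- sqrt(sum(r^2))
  if (theta < 1e-12) return(diag(3))
  k <- r / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_rotation <- function() rot_from_vec(stats::rnorm(3))

# RMSD after rotating Q by R and optimally translating (centroid match).
rmsd_given_rotation <- function(P, Q, R) {
  Pc <- sweep(P, 2, colMeans(P))
  Qr <- sweep(Q, 2, colMeans(Q)) %*% t(R)
  sqrt(mean(rowSums((Qr - Pc)^2)))
}

# Brute-force numeric minimization of RMSD over rotations (multi-start BFGS
# on the rotation-vector parametrization). Independent of the closed form.
brute_force_min_rmsd <- function(P, Q, n_starts = 6) {
  obj <- function(r) rmsd_given_rotation(P, Q, rot_from_vec(r))
  starts <- c(list(c(0, 0, 0)),
              lapply(seq_len(n_starts), function(i) stats::rnorm(3, sd = 2)))
  vals <- vapply(starts, function(r0)
    stats::optim(r0, obj, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))$value, 0)
  min(vals)
}

# --- alignment ---------------------------------------------------------------

# Exhaustive global affine-gap alignment score: enumerate every monotone
# alignment path, score each (BLOSUM62 matches, each maximal gap run costs
# open + extend * length), return the maximum. Feasible for length <= 6.
brute_force_align_score <- function(a, b, open = 10, extend = 1) {
  mat <- blosum62()
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  best <- -Inf
  recurse <- function(i, j, score, last_move) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(a) && j <= length(b))
      recurse(i + 1L, j + 1L, score + mat[a[i], b[j]], "M")
    if (i <= length(a))  # gap in b (deletion)
      recurse(i + 1L, j,
              score - extend - if (last_move == "D") 0 else open, "D")
    if (j <= length(b))  # gap in a (insertion)
      recurse(i, j + 1L,
              score - extend - if (last_move == "I") 0 else open, "I")
  }
  recurse(1L, 1L, 0, "start")
  best
}

blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# --- SNP classification ------------------------------------------------------

# Full re-translation diff for a single SNP: translate WT and mutant codon
# by codon via Biostrings' code table, compare position-wise.
brute_force_snp_effect <- function(cds_seq, pos, alt) {
  code <- Biostrings::GENETIC_CODE
  tr <- function(s) {
    n <- nchar(s) %/% 3L
    unname(code[substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))])
  }
  mut_seq <- cds_seq
  substr(mut_seq, pos, pos) <- alt
  w <- tr(cds_seq); m <- tr(mut_seq)
  d <- which(w != m)
  if (!length(d))
    return(list(class = "synonymous", index = ceiling(pos / 3),
                wt = w[ceiling(pos / 3)], mut = m[ceiling(pos / 3)]))
  stopifnot(length(d) == 1L)
  cls <- if (m[d] == "*") "stop_gained" else if (w[d] == "*") "stop_lost"
         else "missense"
  list(class = cls, index = d, wt = w[d], mut = m[d])
}

# --- PDB fixture -------------------------------------------------------------

# Hand-formatted fixed-column ATOM record (independent of bio3d's writer).
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, b = 0, alt = " ", icode = " ") {
  name_fmt <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name_fmt, alt, resn, chain, resno, icode, x, y, z, occ, b)
}

write_fixture_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- sequence generators -----------------------------------------------------

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

random_cds <- function(n_codons, stop_free = TRUE) {
  code <- varstruct::standard_genetic_code()
  pool <- names(code)[if (stop_free) code != "*" else TRUE]
  paste(sample(pool, n_codons, replace = TRUE), collapse = "")
}
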