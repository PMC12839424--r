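#' Coding sequence
#'
#' A validated coding sequence: an id plus a DNA string over `{A,C,G,T}`,
#' positions counted 1-based from the first base of the start codon.
#' Ambiguity codes are rejected.
#'
#' @param id Character label.
#' @param seq DNA string; lowercase accepted and upper-cased.
#' @return An object of class `coding_sequence` with elements `id` and `seq`.
#' @examples
#' cds <- coding_sequence("toy", "ATGGCTTAA")
#' nchar(cds$seq)
#' @export
coding_sequence <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 3L)
    vs_abort("coding sequence must be at least one codon (3 nt)", "varstruct_domain")
  if (!grepl("^[ACGT]+$", seq))
    vs_abort("coding sequence restricted to A/C/G/T (no ambiguity codes)",
             "varstruct_domain")
  structure(list(id = id, seq = seq), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons%s)\n",
              x$id, nchar(x$seq), nchar(x$seq) %/% 3L,
              if (nchar(x$seq) %% 3L) " + partial" else ""))
  invisible(x)
}

as_coding_sequence <- function(x) {
  if (inherits(x, "coding_sequence")) return(x)
  if (is.character(x) && length(x) == 1L) return(coding_sequence("cds", x))
  vs_abort("expected a coding_sequence or a single DNA string", "varstruct_domain")
}

#' Codon index of a CDS nucleotide position
#'
#' Codon `c` spans CDS nucleotides `3c - 2 ... 3c`, so the codon (equivalently
#' the residue) index of a 1-based CDS position is `ceiling(pos / 3)`.
#'
#' @param pos 1-based CDS nucleotide position(s).
#' @return Integer vector of 1-based codon indices.
#' @examples
#' codon_index(34)   # 12
#' codon_index(764)  # 255
#' @export
codon_index <- function(pos) {
  if (!is.numeric(pos) || any(!is.finite(pos)) || any(pos < 1) ||
      any(pos != floor(pos)))
    vs_abort("positions must be positive integers", "varstruct_domain")
  as.integer(ceiling(pos / 3))
}

split_codons <- function(seq) {
  n_full <- nchar(seq) %/% 3L
  substring(seq, 3L * seq_len(n_full) - 2L, 3L * seq_len(n_full))
}

#' Translate a coding sequence
#'
#' Translates successive codons from position 1 under the supplied genetic
#' code. Translation stops at (and excludes) the first stop codon; a trailing
#' partial codon is ignored with a warning.
#'
#' @param cds A [coding_sequence()] or DNA string.
#' @param code Genetic code table (default [standard_genetic_code()]).
#' @return Single amino-acid string (one-letter codes).
#' @examples
#' translate_cds("ATGGAA")  # "ME"
#' @export
translate_cds <- function(cds, code = standard_genetic_code()) {
  cds <- as_coding_sequence(cds)
  seq <- cds$seq
  if (nchar(seq) %% 3L != 0L)
    vs_warn(sprintf("'%s': trailing partial codon (%d nt) ignored",
                    cds$id, nchar(seq) %% 3L), "varstruct_partial_codon")
  aas <- unname(code[split_codons(seq)])
  stop_at <- which(aas == "*")
  if (length(stop_at)) aas <- aas[seq_len(stop_at[1L] - 1L)]
  paste(aas, collapse = "")
}

#' Read coding sequences from a FASTA file
#'
#' @param path FASTA file (single- or multi-record). Sequences are
#'   upper-cased and validated.
#' @return Named list of [coding_sequence()] objects.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i)
    coding_sequence(names(set)[i], as.character(set[[i]])))
  names(out) <- names(set)
  out
}

#' Write coding sequences to a FASTA file
#'
#' @param cds_list A [coding_sequence()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds_list, path) {
  if (inherits(cds_list, "coding_sequence")) cds_list <- list(cds_list)
  set <- Biostrings::DNAStringSet(vapply(cds_list, `[[`, "", "seq"))
  names(set) <- vapply(cds_list, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
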