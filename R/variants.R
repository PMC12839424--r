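#' CDS-coordinate variant
#'
#' One coding-sequence edit. For SNPs and deletions `pos` is the 1-based CDS
#' position of the first reference base; for insertions `pos` is the position
#' *after which* `alt` is inserted (an insertion "between positions p and
#' p+1" has `pos = p`).
#'
#' @param kind One of `"SNP"`, `"INS"`, `"DEL"`.
#' @param pos 1-based CDS nucleotide position.
#' @param ref Reference bases (`""` for insertions).
#' @param alt Alternate bases (`""` for deletions).
#' @param id Optional record id.
#' @return An object of class `variant`.
#' @examples
#' variant("SNP", 34, "G", "T")
#' variant("INS", 579, "", "ATG")
#' @export
variant <- function(kind, pos, ref = "", alt = "", id = NULL) {
  kind <- match.arg(kind, c("SNP", "INS", "DEL"))
  if (!is.numeric(pos) || length(pos) != 1L || pos < 1 || pos != floor(pos))
    vs_abort("variant position must be a positive integer", "varstruct_domain")
  ref <- toupper(ref); alt <- toupper(alt)
  ok_dna <- function(x) x == "" || grepl("^[ACGT]+$", x)
  if (!ok_dna(ref) || !ok_dna(alt))
    vs_abort("ref/alt restricted to A/C/G/T", "varstruct_domain")
  switch(kind,
    SNP = if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt)
      vs_abort("SNP requires single-base ref and alt with ref != alt",
               "varstruct_domain"),
    INS = if (nchar(ref) != 0L || nchar(alt) < 1L)
      vs_abort("INS requires empty ref and non-empty alt", "varstruct_domain"),
    DEL = if (nchar(alt) != 0L || nchar(ref) < 1L)
      vs_abort("DEL requires empty alt and non-empty ref", "varstruct_domain"))
  structure(list(kind = kind, pos = as.integer(pos), ref = ref, alt = alt,
                 id = if (is.null(id)) sprintf("%s_%d", kind, pos) else id),
            class = "variant")
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("<variant> %s %s@%d %s>%s\n", x$id, x$kind, x$pos,
              if (x$ref == "") "-" else x$ref,
              if (x$alt == "") "-" else x$alt))
  invisible(x)
}

as_variant_list <- function(variants) {
  if (inherits(variants, "variant")) return(list(variants))
  if (is.data.frame(variants)) {
    return(lapply(seq_len(nrow(variants)), function(i) {
      r <- variants[i, ]
      dash <- function(x) if (is.na(x) || x == "-" ) "" else x
      variant(r$kind, r$pos, dash(r$ref), dash(r$alt),
              id = if ("id" %in% names(variants)) r$id else NULL)
    }))
  }
  stopifnot(is.list(variants), all(vapply(variants, inherits, TRUE, "variant")))
  variants
}

# Occupied CDS interval; insertions sit strictly between pos and pos+1.
variant_interval <- function(v) {
  switch(v$kind,
    SNP = c(v$pos, v$pos),
    DEL = c(v$pos, v$pos + nchar(v$ref) - 1L),
    INS = c(v$pos + 0.4, v$pos + 0.6))
}

#' Read a variant TSV
#'
#' Columns `id  kind  pos  ref  alt` with a header row; `-` denotes an empty
#' ref (insertions) or alt (deletions).
#'
#' @param path TSV path.
#' @return List of [variant()] objects.
#' @export
read_variant_tsv <- function(path) {
  # colClasses = "character" so a lone T/F base is never read as a logical
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "kind", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    vs_abort(sprintf("variant TSV must have columns: %s",
                     paste(need, collapse = ", ")), "varstruct_io")
  df$pos <- as.integer(df$pos)
  as_variant_list(df)
}

#' Write variants to a TSV
#'
#' @param variants List of [variant()] objects (or a data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_tsv <- function(variants, path) {
  variants <- as_variant_list(variants)
  df <- data.frame(
    id = vapply(variants, `[[`, "", "id"),
    kind = vapply(variants, `[[`, "", "kind"),
    pos = vapply(variants, `[[`, 1L, "pos"),
    ref = vapply(variants, function(v) if (v$ref == "") "-" else v$ref, ""),
    alt = vapply(variants, function(v) if (v$alt == "") "-" else v$alt, ""))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Apply CDS variants to a coding sequence
#'
#' Edits are applied in descending coordinate order so that earlier
#' coordinates are unaffected by downstream length changes. Reference bases
#' of SNPs and deletions are checked against the sequence; overlapping
#' variants are rejected.
#'
#' @param cds A [coding_sequence()].
#' @param variants List of [variant()] objects (or a variant data frame).
#' @return The edited [coding_sequence()] (id suffixed `"_mut"`).
#' @examples
#' cds <- coding_sequence("toy", "ATGGCA")
#' apply_variants(cds, list(variant("SNP", 4, "G", "T")))$seq  # "ATGTCA"
#' @export
apply_variants <- function(cds, variants) {
  cds <- as_coding_sequence(cds)
  variants <- as_variant_list(variants)
  if (!length(variants)) return(cds)
  n <- nchar(cds$seq)

  iv <- t(vapply(variants, variant_interval, numeric(2)))
  if (any(iv[, 2] > n) || any(vapply(variants, `[[`, 1L, "pos") > n))
    vs_abort("variant position outside the CDS", "varstruct_domain")
  ord <- order(iv[, 1])
  if (length(variants) > 1L &&
      any(iv[ord[-length(ord)], 2] >= iv[ord[-1L], 1]))
    vs_abort("overlapping variants supplied", "varstruct_overlap")

  seq <- cds$seq
  for (v in variants[order(iv[, 1], decreasing = TRUE)]) {
    if (v$kind %in% c("SNP", "DEL")) {
      found <- substr(seq, v$pos, v$pos + nchar(v$ref) - 1L)
      if (found != v$ref)
        vs_abort(sprintf("reference mismatch at CDS position %d: expected %s, found %s",
                         v$pos, v$ref, found), "varstruct_ref_mismatch")
    }
    seq <- switch(v$kind,
      SNP = paste0(substr(seq, 1L, v$pos - 1L), v$alt,
                   substr(seq, v$pos + 1L, nchar(seq))),
      INS = paste0(substr(seq, 1L, v$pos), v$alt,
                   substr(seq, v$pos + 1L, nchar(seq))),
      DEL = paste0(substr(seq, 1L, v$pos - 1L),
                   substr(seq, v$pos + nchar(v$ref), nchar(seq))))
  }
  coding_sequence(paste0(cds$id, "_mut"), seq)
}
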