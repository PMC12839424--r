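#' Classify protein-level effects of CDS variants
#'
#' Each variant is classified independently against the wild-type frame (the
#' convention under which per-variant calls are reported); use
#' [translate_haplotype()] for the combined mutant protein. SNPs are compared
#' codon-wise; in-frame indels are resolved by re-translating the mutant and
#' diffing against the wild-type protein; indels whose net length is not a
#' multiple of 3 are frameshifts.
#'
#' @param cds A [coding_sequence()].
#' @param variants List of [variant()] objects or a variant data frame.
#' @param code Genetic code table.
#' @return Data frame with one row per variant: `variant_id`, `effect_class`
#'   (one of synonymous / missense / stop_gained / stop_lost /
#'   inframe_insertion / inframe_deletion / frameshift), `residue_index`,
#'   `wt_aa`, `mut_aa` (peptides for indels, `fs` marks a frameshift) and
#'   `notation`.
#' @examples
#' cds <- coding_sequence("toy", "ATGGCTCAA")
#' classify_effects(cds, list(variant("SNP", 4, "G", "T")))
#' @export
classify_effects <- function(cds, variants, code = standard_genetic_code()) {
  cds <- as_coding_sequence(cds)
  variants <- as_variant_list(variants)
  if (!length(variants))
    return(data.frame(variant_id = character(), effect_class = character(),
                      residue_index = integer(), wt_aa = character(),
                      mut_aa = character(), notation = character()))
  rows <- lapply(variants, classify_one, cds = cds, code = code)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

classify_one <- function(v, cds, code) {
  # reference check up front (shared with apply_variants semantics)
  if (v$kind %in% c("SNP", "DEL")) {
    found <- substr(cds$seq, v$pos, v$pos + nchar(v$ref) - 1L)
    if (found != v$ref)
      vs_abort(sprintf("reference mismatch at CDS position %d: expected %s, found %s",
                       v$pos, v$ref, found), "varstruct_ref_mismatch")
  }
  if (v$pos > nchar(cds$seq))
    vs_abort("variant position outside the CDS", "varstruct_domain")

  if (v$kind == "SNP") return(classify_snp(v, cds, code))
  net <- nchar(v$alt) - nchar(v$ref)
  if (net %% 3L != 0L) return(classify_frameshift(v, cds, code))
  classify_inframe(v, cds, code)
}

classify_snp <- function(v, cds, code) {
  ci <- codon_index(v$pos)
  wt_codon <- substr(cds$seq, 3L * ci - 2L, 3L * ci)
  if (nchar(wt_codon) < 3L)
    vs_abort("SNP falls in a trailing partial codon", "varstruct_domain")
  off <- v$pos - (3L * ci - 3L)
  mut_codon <- wt_codon
  substr(mut_codon, off, off) <- v$alt
  wt_aa <- unname(code[wt_codon]); mut_aa <- unname(code[mut_codon])
  cls <- if (wt_aa == mut_aa) "synonymous"
    else if (mut_aa == "*") "stop_gained"
    else if (wt_aa == "*") "stop_lost"
    else "missense"
  effect_row(v$id, cls, ci, wt_aa, mut_aa,
             notation = paste0(wt_aa, ci, mut_aa))
}

classify_frameshift <- function(v, cds, code) {
  first_nt <- if (v$kind == "INS") v$pos + 1L else v$pos
  ri <- codon_index(min(first_nt, nchar(cds$seq)))
  wt_prot <- suppressWarnings(translate_cds(cds, code))
  wt_aa <- if (ri <= nchar(wt_prot)) substr(wt_prot, ri, ri) else "X"
  effect_row(v$id, "frameshift", ri, wt_aa, "fs",
             notation = paste0(wt_aa, ri, "fs"))
}

classify_inframe <- function(v, cds, code) {
  mut <- apply_variants(cds, list(v))
  wt_prot <- suppressWarnings(translate_cds(cds, code))
  mut_prot <- suppressWarnings(translate_cds(mut, code))
  d <- diff_proteins(wt_prot, mut_prot)
  cls <- if (v$kind == "INS") "inframe_insertion" else "inframe_deletion"
  if (cls == "inframe_insertion") {
    ri <- d$prefix  # left anchor residue (0 = insertion before residue 1)
    nota <- insertion_notation(wt_prot, d)
    effect_row(v$id, cls, ri, d$wt_pep, d$mut_pep, nota)
  } else {
    ri <- d$prefix + 1L      # first deleted residue
    nota <- deletion_notation(wt_prot, d)
    effect_row(v$id, cls, ri, d$wt_pep, d$mut_pep, nota)
  }
}

# Longest common prefix/suffix decomposition of two protein strings.
diff_proteins <- function(wt, mut) {
  nw <- nchar(wt); nm <- nchar(mut)
  wt_c <- strsplit(wt, "")[[1L]]; mut_c <- strsplit(mut, "")[[1L]]
  p <- 0L
  while (p < min(nw, nm) && wt_c[p + 1L] == mut_c[p + 1L]) p <- p + 1L
  s <- 0L
  while (s < min(nw, nm) - p && wt_c[nw - s] == mut_c[nm - s]) s <- s + 1L
  list(prefix = p, suffix = s,
       wt_pep = substr(wt, p + 1L, nw - s),
       mut_pep = substr(mut, p + 1L, nm - s))
}

insertion_notation <- function(wt_prot, d) {
  p <- d$prefix; nw <- nchar(wt_prot)
  if (d$wt_pep != "")  # junction residues altered as well: delins form
    return(paste0(substr(wt_prot, p + 1L, p + 1L), p + 1L, "_",
                  substr(wt_prot, nw - d$suffix, nw - d$suffix), nw - d$suffix,
                  "delins", d$mut_pep))
  if (p >= 1L && p < nw)
    paste0(substr(wt_prot, p, p), p, "_",
           substr(wt_prot, p + 1L, p + 1L), p + 1L, "ins", d$mut_pep)
  else
    paste0("ins", d$mut_pep)  # terminal insertion: no two-sided anchor
}

deletion_notation <- function(wt_prot, d) {
  p <- d$prefix
  first <- p + 1L
  last <- first + nchar(d$wt_pep) - 1L
  base <- if (last > first)
    paste0(substr(wt_prot, first, first), first, "_",
           substr(wt_prot, last, last), last, "del")
  else paste0(substr(wt_prot, first, first), first, "del")
  if (d$mut_pep != "") paste0(base, "ins", d$mut_pep) else base
}

effect_row <- function(id, cls, ri, wt_aa, mut_aa, notation) {
  data.frame(variant_id = id, effect_class = cls, residue_index = ri,
             wt_aa = wt_aa, mut_aa = mut_aa, notation = notation)
}

#' Compact notation for one protein effect
#'
#' `A12S` for substitutions, `H194_S195insY` for in-frame insertions,
#' `A10del` / `A10_C12del` for in-frame deletions, `K5fs` for frameshifts.
#' This is the notation column that [classify_effects()] emits; exposed for
#' working with externally assembled effect rows.
#'
#' @param effect One-row data frame (or list) with `effect_class`,
#'   `residue_index`, `wt_aa`, `mut_aa` and, for insertions, `anchor_left`
#'   and `anchor_right` one-letter codes.
#' @return Character notation.
#' @export
effect_notation <- function(effect) {
  e <- as.list(effect)
  switch(e$effect_class,
    missense = ,
    synonymous = paste0(e$wt_aa, e$residue_index, e$mut_aa),
    stop_gained = paste0(e$wt_aa, e$residue_index, "*"),
    stop_lost = paste0("*", e$residue_index, e$mut_aa),
    frameshift = paste0(e$wt_aa, e$residue_index, "fs"),
    inframe_insertion = paste0(e$anchor_left, e$residue_index, "_",
                               e$anchor_right, e$residue_index + 1L,
                               "ins", e$mut_aa),
    inframe_deletion = {
      last <- e$residue_index + nchar(e$wt_aa) - 1L
      if (last > e$residue_index)
        paste0(substr(e$wt_aa, 1L, 1L), e$residue_index, "_",
               substr(e$wt_aa, nchar(e$wt_aa), nchar(e$wt_aa)), last, "del")
      else paste0(e$wt_aa, e$residue_index, "del")
    },
    vs_abort(sprintf("unknown effect class '%s'", e$effect_class),
             "varstruct_domain"))
}

#' Translate the combined mutant haplotype
#'
#' Applies all variants jointly and translates the resulting mutant CDS —
#' the complement to the per-variant classification of [classify_effects()].
#'
#' @inheritParams classify_effects
#' @return Mutant protein string.
#' @export
translate_haplotype <- function(cds, variants, code = standard_genetic_code()) {
  suppressWarnings(translate_cds(apply_variants(cds, variants), code))
}

#' Write an effects table to TSV
#'
#' @param effects Data frame from [classify_effects()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_effects_tsv <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
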