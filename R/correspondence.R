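#' Wild-type / mutant residue correspondence
#'
#' Ordered pairing of WT and mutant residue indices plus the unmatched
#' (deleted / inserted) residues. Pairs are strictly increasing in both
#' coordinates (no crossings).
#'
#' @param pairs Two-column integer matrix `(wt_index, mut_index)`.
#' @param wt_only Integer vector: WT residues deleted in the mutant.
#' @param mut_only Integer vector: mutant residues inserted relative to WT.
#' @return An object of class `correspondence_map`.
#' @export
correspondence_map <- function(pairs, wt_only = integer(), mut_only = integer()) {
  pairs <- matrix(as.integer(pairs), ncol = 2L,
                  dimnames = list(NULL, c("wt", "mut")))
  if (nrow(pairs) > 1L &&
      (any(diff(pairs[, 1]) <= 0L) || any(diff(pairs[, 2]) <= 0L)))
    vs_abort("correspondence pairs must be strictly increasing in both coordinates",
             "varstruct_domain")
  if (any(wt_only %in% pairs[, 1]) || any(mut_only %in% pairs[, 2]))
    vs_abort("an index may appear at most once across pairs and unmatched sets",
             "varstruct_domain")
  structure(list(pairs = pairs, wt_only = as.integer(sort(wt_only)),
                 mut_only = as.integer(sort(mut_only))),
            class = "correspondence_map")
}

#' @export
print.correspondence_map <- function(x, ...) {
  cat(sprintf("<correspondence_map> %d pairs, %d WT-only, %d mutant-only\n",
              nrow(x$pairs), length(x$wt_only), length(x$mut_only)))
  invisible(x)
}

#' Mutant partner of WT residue indices
#' @param map A [correspondence_map()].
#' @param wt_index WT residue indices.
#' @return Integer vector of mutant indices; `NA` where unmatched.
#' @export
mut_partner <- function(map, wt_index) {
  map$pairs[match(wt_index, map$pairs[, 1]), 2]
}

#' Build a correspondence map from classified effects
#'
#' The exact route when the variants are known: substitutions map i to i,
#' an in-frame insertion of k residues after WT residue r contributes mutant
#' indices r+1 ... r+k to `mut_only` and shifts downstream pairs by +k;
#' deletions are symmetric. Frameshift (and stop-altering) effects make the
#' proteins non-comparable residue-wise and raise an error.
#'
#' @param effects Data frame from [classify_effects()].
#' @param wt_len,mut_len Residue counts of the two proteins.
#' @return A [correspondence_map()].
#' @export
map_from_effects <- function(effects, wt_len, mut_len) {
  bad <- effects$effect_class %in% c("frameshift", "stop_gained", "stop_lost")
  if (any(bad))
    vs_abort(sprintf("residue-wise correspondence undefined for %s effects",
                     paste(unique(effects$effect_class[bad]), collapse = "/")),
             "varstruct_frameshift_correspondence")

  ins_after <- integer(0)  # named: wt index -> inserted count
  del_at <- logical(wt_len)
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    if (e$effect_class == "inframe_insertion") {
      k <- nchar(e$mut_aa) - nchar(e$wt_aa)  # net gain (delins-safe)
      anchor <- as.character(e$residue_index)
      ins_after[anchor] <- k + if (anchor %in% names(ins_after)) ins_after[[anchor]] else 0L
      if (e$wt_aa != "")  # delins: altered junction residues still pair i<->i
        next
    } else if (e$effect_class == "inframe_deletion") {
      first <- e$residue_index
      lost <- nchar(e$wt_aa) - nchar(e$mut_aa)
      del_at[seq.int(first, first + lost - 1L)] <- TRUE
    }
  }

  pairs_wt <- integer(0); pairs_mut <- integer(0)
  wt_only <- which(del_at); mut_only <- integer(0)
  mut_pos <- 0L
  if ("0" %in% names(ins_after)) {  # N-terminal insertion
    mut_only <- seq_len(ins_after[["0"]])
    mut_pos <- ins_after[["0"]]
  }
  for (w in seq_len(wt_len)) {
    if (!del_at[w]) {
      mut_pos <- mut_pos + 1L
      pairs_wt <- c(pairs_wt, w); pairs_mut <- c(pairs_mut, mut_pos)
    }
    key <- as.character(w)
    if (key %in% names(ins_after)) {
      k <- ins_after[[key]]
      mut_only <- c(mut_only, mut_pos + seq_len(k))
      mut_pos <- mut_pos + k
    }
  }
  if (mut_pos != mut_len)
    vs_abort(sprintf("effects imply a mutant length of %d, but mut_len = %d",
                     mut_pos, mut_len), "varstruct_domain")
  correspondence_map(cbind(pairs_wt, pairs_mut), wt_only, mut_only)
}

#' Build a correspondence map by global sequence alignment
#'
#' Fallback when no variant list is available: Needleman-Wunsch global
#' alignment of the two amino-acid strings (affine gaps, BLOSUM62, gap open
#' 10, gap extend 1 by default); aligned non-gap columns become pairs.
#'
#' @param wt_seq,mut_seq Amino-acid strings.
#' @param gap_open,gap_extend Affine gap penalties (positive).
#' @param substitution_matrix Name of the scoring matrix shipped with
#'   Biostrings.
#' @return A [correspondence_map()].
#' @export
map_by_alignment <- function(wt_seq, mut_seq, gap_open = 10, gap_extend = 1,
                             substitution_matrix = "BLOSUM62") {
  stopifnot(nzchar(wt_seq), nzchar(mut_seq))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(wt_seq), Biostrings::AAString(mut_seq),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  wi <- 0L; mi <- 0L
  pairs_wt <- integer(0); pairs_mut <- integer(0)
  wt_only <- integer(0); mut_only <- integer(0)
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") {
      wi <- wi + 1L; mi <- mi + 1L
      pairs_wt <- c(pairs_wt, wi); pairs_mut <- c(pairs_mut, mi)
    } else if (a[k] != "-") {
      wi <- wi + 1L; wt_only <- c(wt_only, wi)
    } else {
      mi <- mi + 1L; mut_only <- c(mut_only, mi)
    }
  }
  correspondence_map(cbind(pairs_wt, pairs_mut), wt_only, mut_only)
}

#' Write a correspondence map to TSV
#'
#' Columns `wt_index  mut_index`, one row per pair plus one per unmatched
#' residue with `-` on the missing side.
#'
#' @param map A [correspondence_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correspondence_tsv <- function(map, path) {
  df <- rbind(
    data.frame(wt_index = as.character(map$pairs[, 1]),
               mut_index = as.character(map$pairs[, 2])),
    data.frame(wt_index = as.character(map$wt_only),
               mut_index = rep("-", length(map$wt_only))),
    data.frame(wt_index = rep("-", length(map$mut_only)),
               mut_index = as.character(map$mut_only)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
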