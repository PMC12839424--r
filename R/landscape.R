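#' Read a minimal VCF subset
#'
#' Reads `CHROM POS ID REF ALT` from a plain or gzipped VCF, ignoring INFO
#' and sample columns (calling and genotyping are out of scope). Multi-allelic
#' records are expanded to one row per ALT. Malformed lines and records with
#' ambiguity-code bases are skipped; the skip count is attached as attribute
#' `n_skipped`.
#'
#' @param path VCF path (`.gz` accepted).
#' @return Data frame `chrom, pos, id, ref, alt, kind` with
#'   `kind` in SNP / INS / DEL / OTHER.
#' @export
read_vcf_minimal <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  n_skipped <- 0L
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L || is.na(suppressWarnings(as.integer(f[2L])))) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]
    data.frame(chrom = f[1L], pos = as.integer(f[2L]), id = f[3L],
               ref = toupper(f[4L]), alt = toupper(alts))
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df))
    df <- data.frame(chrom = character(), pos = integer(), id = character(),
                     ref = character(), alt = character())
  ok <- grepl("^[ACGT]+$", df$ref) & grepl("^[ACGT]+$", df$alt)
  n_skipped <- n_skipped + sum(!ok)
  if (any(!ok))
    vs_warn(sprintf("%d record(s) with non-ACGT bases skipped", sum(!ok)),
            "varstruct_ambiguous_base")
  df <- df[ok, , drop = FALSE]
  df$kind <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNP",
             ifelse(nchar(df$alt) > nchar(df$ref), "INS",
             ifelse(nchar(df$alt) < nchar(df$ref), "DEL", "OTHER")))
  attr(df, "n_skipped") <- n_skipped
  df
}

#' Strand-collapsed SNP mutation spectrum
#'
#' Assigns each SNP to one of the six pyrimidine-context substitution
#' classes: records with a purine reference are complemented onto the
#' pyrimidine label, so e.g. C>T and G>A both count as `C:G>T:A`. Non-SNP
#' records are filtered out; their count is attached as attribute
#' `n_non_snp`. Totals are conserved.
#'
#' @param variants Genomic variant data frame (`ref`, `alt`, optionally
#'   `kind`), e.g. from [read_vcf_minimal()].
#' @return Named integer vector over the six classes, attributes
#'   `n_non_snp`.
#' @examples
#' v <- data.frame(ref = c("C", "G"), alt = c("T", "A"))
#' snp_spectrum(v)  # both collapse to C:G>T:A
#' @export
snp_spectrum <- function(variants) {
  is_snp <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref != variants$alt
  n_non_snp <- sum(!is_snp)
  v <- variants[is_snp, , drop = FALSE]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- v$ref; alt <- v$alt
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]; alt[flip] <- comp[alt[flip]]
  label <- sprintf("%s:%s>%s:%s", ref, comp[ref], alt, comp[alt])
  classes <- c("C:G>T:A", "T:A>C:G", "C:G>A:T", "C:G>G:C", "T:A>A:T", "T:A>G:C")
  counts <- table(factor(label, levels = classes))
  out <- stats::setNames(as.integer(counts), classes)
  attr(out, "n_non_snp") <- n_non_snp
  out
}

#' Signed InDel length histogram
#'
#' Signed length is `nchar(alt) - nchar(ref)`; positive for insertions.
#'
#' @param variants Genomic variant data frame with `ref` and `alt`; non-indel
#'   records (net length 0) are excluded with attribute `n_non_indel`.
#' @return Named integer vector of counts keyed by signed length.
#' @export
indel_lengths <- function(variants) {
  len <- nchar(variants$alt) - nchar(variants$ref)
  n_non_indel <- sum(len == 0L)
  len <- len[len != 0L]
  tab <- table(len)
  out <- stats::setNames(as.integer(tab), names(tab))
  attr(out, "n_non_indel") <- n_non_indel
  out
}

#' Windowed feature density along chromosomes
#'
#' Counts features per non-overlapping tiling window of `window_size`
#' (1-based, closed; the last window is truncated at the chromosome end).
#'
#' @param features Data frame with `chrom` and `pos` (1-based positions).
#' @param window_size Window width in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   defaults to the maximum observed position per chromosome.
#' @return Data frame `chrom, start, end, count`.
#' @export
windowed_density <- function(features, window_size, chrom_lengths = NULL) {
  if (window_size <= 0)
    vs_abort("window_size must be positive", "varstruct_domain")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(features$pos, features$chrom, max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                     names(chrom_lengths))
  }
  if (!length(chrom_lengths))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), count = integer()))
  tiles <- GenomicRanges::tileGenome(chrom_lengths, tilewidth = window_size,
                                     cut.last.tile.in.chrom = TRUE)
  feats <- features[features$chrom %in% names(chrom_lengths), , drop = FALSE]
  gr <- GenomicRanges::GRanges(feats$chrom,
                               IRanges::IRanges(feats$pos, feats$pos))
  counts <- GenomicRanges::countOverlaps(tiles, gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(tiles)),
             start = GenomicRanges::start(tiles),
             end = GenomicRanges::end(tiles),
             count = as.integer(counts))
}

#' Association between two density tracks
#'
#' Spearman and Pearson correlations plus the least-squares fit of `y ~ x`.
#' Spearman is Pearson on mid-ranks (ties averaged); `r_squared` is the
#' squared Pearson correlation of the fit.
#'
#' @param x,y Equal-length numeric vectors (window counts), `n >= 3`.
#' @return List: `spearman`, `pearson`, `slope`, `intercept`, `r_squared`,
#'   `n`.
#' @export
density_association <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    vs_abort("x and y must be equal-length vectors with n >= 3",
             "varstruct_domain")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  list(spearman = stats::cor(x, y, method = "spearman"),
       pearson = r,
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = r^2,  # squared Pearson of the simple linear fit
       n = length(x))
}

#' Read gene intervals from a BED file
#'
#' BED is 0-based half-open; intervals are converted to 1-based closed. The
#' returned `pos` is the interval midpoint, the anchor used for windowed
#' gene density.
#'
#' @param path BED path.
#' @return Data frame `chrom, start, end, pos`.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  start <- GenomicRanges::start(gr); end <- GenomicRanges::end(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = start, end = end,
             pos = as.integer(floor((start + end) / 2)))
}
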