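# Stage runners behind the command-line interface (inst/cli/varstruct.R).
# All outputs are byte-stable: Angstrom values printed at 3 decimals, JSON
# written with a fixed field order and a config echo.

fmt3 <- function(x) sprintf("%.3f", x)

pkg_version <- function() as.character(utils::packageVersion("varstruct"))

write_stable_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], fmt3)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Annotate CDS variants with protein-level effects
#'
#' Reads a CDS FASTA and a variant TSV, classifies each variant against the
#' wild-type frame, and writes `effects.tsv`.
#'
#' @param cds_fasta FASTA with the coding sequence (first record used unless
#'   `cds_id` names one).
#' @param variants_tsv Variant TSV (`id kind pos ref alt`).
#' @param out_dir Output directory (created if absent).
#' @param cds_id Optional record id to select from a multi-record FASTA.
#' @return The effects data frame, invisibly.
#' @export
run_annotate <- function(cds_fasta, variants_tsv, out_dir, cds_id = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cds_list <- read_cds_fasta(cds_fasta)
  cds <- if (is.null(cds_id)) cds_list[[1L]] else cds_list[[cds_id]]
  if (is.null(cds))
    vs_abort(sprintf("CDS record '%s' not found", cds_id), "varstruct_io")
  variants <- read_variant_tsv(variants_tsv)
  effects <- classify_effects(cds, variants)
  write_effects_tsv(effects, file.path(out_dir, "effects.tsv"))
  invisible(effects)
}

# Substitution/insertion site specs from an effects table.
sites_from_effects <- function(effects, map) {
  sites <- list()
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    if (e$effect_class == "missense") {
      sites[[length(sites) + 1L]] <-
        site_spec("substitution", wt_index = e$residue_index,
                  mut_index = mut_partner(map, e$residue_index),
                  label = e$notation)
    } else if (e$effect_class == "inframe_insertion") {
      prev_mut <- if (e$residue_index >= 1L)
        mut_partner(map, e$residue_index) else 0L
      k <- nchar(e$mut_aa) - nchar(e$wt_aa)
      for (j in seq_len(k))  # one site per inserted residue
        sites[[length(sites) + 1L]] <-
          site_spec("insertion", mut_index = prev_mut + j, label = e$notation)
    }
  }
  sites
}

# Fallback: sites from an alignment-derived map (mismatched pairs and
# inserted residues).
sites_from_alignment <- function(wt, mut, map) {
  wt_chars <- wt$residues$aa; mut_chars <- mut$residues$aa
  sites <- list()
  for (r in seq_len(nrow(map$pairs))) {
    wi <- map$pairs[r, 1]; mi <- map$pairs[r, 2]
    if (wt_chars[wi] != mut_chars[mi])
      sites[[length(sites) + 1L]] <-
        site_spec("substitution", wt_index = wi, mut_index = mi,
                  label = sprintf("%s%d%s", wt_chars[wi], wi, mut_chars[mi]))
  }
  for (mi in map$mut_only)
    sites[[length(sites) + 1L]] <-
      site_spec("insertion", mut_index = mi,
                label = sprintf("ins%s%d", mut_chars[mi], mi))
  sites
}

#' Run the structural perturbation stage
#'
#' Reads WT and mutant Cα models, builds the residue correspondence (exactly
#' from the variant list when a CDS FASTA + variant TSV are given, otherwise
#' by global sequence alignment), superposes, and writes `summary.json`
#' (global RMSD block + config echo), `local_rmsd.tsv` and `delta_d.tsv`.
#'
#' @param wt_pdb,mut_pdb PDB paths.
#' @param out_dir Output directory.
#' @param chain Chain identifier (both files).
#' @param cds_fasta,variants_tsv Optional exact-correspondence inputs.
#' @param flank,neighbor_cutoff,flag_threshold See [metric_config()].
#' @param cycles,reject_cutoff See [superpose()].
#' @return The [perturbation_report()], invisibly.
#' @export
run_perturb <- function(wt_pdb, mut_pdb, out_dir, chain = NULL,
                        cds_fasta = NULL, variants_tsv = NULL,
                        flank = 5L, neighbor_cutoff = 8.0,
                        flag_threshold = 3.0, cycles = 0L,
                        reject_cutoff = 2.0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- read_structure(wt_pdb, chain)
  mut <- read_structure(mut_pdb, chain)
  cfg <- metric_config(flank, neighbor_cutoff, flag_threshold)

  if (!is.null(cds_fasta) && !is.null(variants_tsv)) {
    cds <- read_cds_fasta(cds_fasta)[[1L]]
    variants <- read_variant_tsv(variants_tsv)
    effects <- classify_effects(cds, variants)
    map <- map_from_effects(effects, n_residues(wt), n_residues(mut))
    sites <- sites_from_effects(effects, map)
    route <- "effects"
  } else {
    map <- map_by_alignment(sequence_of(wt), sequence_of(mut))
    sites <- sites_from_alignment(wt, mut, map)
    route <- "alignment"
  }

  rep <- perturbation_report(wt, mut, map, sites, cfg,
                             cycles = cycles, reject_cutoff = reject_cutoff)
  if (!is.null(rep$local))
    write_stable_tsv(rep$local, file.path(out_dir, "local_rmsd.tsv"))
  if (!is.null(rep$delta_d))
    write_stable_tsv(rep$delta_d, file.path(out_dir, "delta_d.tsv"))
  jsonlite::write_json(list(
    tool = "varstruct", version = pkg_version(),
    config = list(chain = wt$chain_id, flank = cfg$flank,
                  neighbor_cutoff = cfg$neighbor_cutoff,
                  flag_threshold = cfg$flag_threshold,
                  cycles = cycles, reject_cutoff = reject_cutoff,
                  correspondence = route,
                  insertion_site_convention = paste(
                    "insertion site Calpha = inserted mutant residue;",
                    "WT reference = residue preceding the insertion point")),
    global = list(rmsd_all = round(rep$global$rmsd_all, 3),
                  rmsd_retained = round(rep$global$rmsd_retained, 3),
                  n_pairs = rep$global$n_pairs,
                  n_retained = rep$global$n_retained,
                  cycles_run = rep$global$cycles_run),
    n_sites = if (is.null(rep$local)) 0L else nrow(rep$local),
    n_delta_d = if (is.null(rep$delta_d)) 0L else nrow(rep$delta_d),
    n_flagged = if (is.null(rep$delta_d)) 0L else sum(rep$delta_d$flagged),
    failures = rep$failures),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Run the genome-wide variant landscape stage
#'
#' SNP spectrum, InDel length classes, windowed densities and the
#' SNP-vs-InDel density association, written as `spectrum.tsv`,
#' `indel_lengths.tsv`, `density.tsv` and `association.json`.
#'
#' @param vcf Minimal-VCF path (see [read_vcf_minimal()]).
#' @param out_dir Output directory.
#' @param genes_bed Optional BED of gene intervals for a gene-density track.
#' @param window_size Tiling window in bp (default 1 Mb).
#' @return List of the computed summaries, invisibly.
#' @export
run_landscape <- function(vcf, out_dir, genes_bed = NULL, window_size = 1e6) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gv <- read_vcf_minimal(vcf)
  spec <- snp_spectrum(gv)
  lens <- indel_lengths(gv[gv$kind %in% c("INS", "DEL"), , drop = FALSE])

  chrom_lengths <- tapply(gv$pos, gv$chrom, max)
  chrom_lengths <- stats::setNames(as.numeric(chrom_lengths),
                                   names(chrom_lengths))
  snp_d <- windowed_density(gv[gv$kind == "SNP", , drop = FALSE],
                            window_size, chrom_lengths)
  ind_d <- windowed_density(gv[gv$kind %in% c("INS", "DEL"), , drop = FALSE],
                            window_size, chrom_lengths)
  dens <- data.frame(chrom = snp_d$chrom, start = snp_d$start,
                     end = snp_d$end, snp = snp_d$count, indel = ind_d$count)
  if (!is.null(genes_bed)) {
    genes <- read_genes_bed(genes_bed)
    dens$gene <- windowed_density(genes, window_size, chrom_lengths)$count
  }

  utils::write.table(
    data.frame(type = names(spec), count = as.integer(spec)),
    file.path(out_dir, "spectrum.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(length = names(lens), count = as.integer(lens)),
    file.path(out_dir, "indel_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(dens, file.path(out_dir, "density.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  assoc <- if (nrow(dens) >= 3L) {
    a <- density_association(dens$snp, dens$indel)
    lapply(a, function(v) if (is.numeric(v)) round(v, 6) else v)
  } else NULL
  jsonlite::write_json(list(
    tool = "varstruct", version = pkg_version(),
    config = list(window_size = window_size),
    n_records = nrow(gv), n_skipped = attr(gv, "n_skipped"),
    snp_total = sum(spec), indel_total = sum(lens),
    snp_vs_indel = assoc),
    file.path(out_dir, "association.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(spectrum = spec, indel_lengths = lens, density = dens,
                 association = assoc))
}

#' Write a complete synthetic fixture set
#'
#' Generates the CDS FASTA + variant TSV for a printed-variant fixture and a
#' WT/mutant helix pair under a controlled perturbation, together with the
#' expected-metrics oracle, into one directory — every pipeline stage can
#' then be exercised with no external data.
#'
#' @param out_dir Output directory.
#' @param gene_tag Passed to [cds_for_printed_effects()].
#' @param n Helix length (residues).
#' @param segment Residue indices displaced in the mutant.
#' @param displacement Length-3 displacement vector (Angstrom).
#' @param jitter_sigma,seed Jitter parameters (see [perturbation_plan()]).
#' @return Invisible list of generated paths.
#' @export
run_simulate <- function(out_dir, gene_tag = "015992", n = 60L,
                         segment = 30:40, displacement = c(5, 0, 0),
                         jitter_sigma = 0, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- cds_for_printed_effects(gene_tag)
  write_cds_fasta(fx$cds, file.path(out_dir, "cds.fasta"))
  write_variant_tsv(fx$variants, file.path(out_dir, "variants.tsv"))

  wt <- make_helix(n)
  pert <- apply_perturbation(wt, perturbation_plan(segment, displacement,
                                                   jitter_sigma, seed))
  write_structure(wt, file.path(out_dir, "wt.pdb"))
  write_structure(pert$mutant, file.path(out_dir, "mut.pdb"))
  jsonlite::write_json(list(
    tool = "varstruct", version = pkg_version(),
    config = list(gene_tag = gene_tag, n = n,
                  segment = range(segment), displacement = displacement,
                  jitter_sigma = jitter_sigma, seed = seed),
    displacement_norm = sqrt(sum(displacement^2)),
    per_residue_shift = round(pert$expected$per_residue_shift, 6),
    displaced = which(pert$expected$displaced)),
    file.path(out_dir, "expected_metrics.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(list(dir = out_dir,
                 files = c("cds.fasta", "variants.tsv", "wt.pdb", "mut.pdb",
                           "expected_metrics.json")))
}
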