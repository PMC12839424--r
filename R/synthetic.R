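#' Ideal alpha-helix C-alpha trace
#'
#' Deterministic generator for a synthetic Cα backbone: helix radius 2.3 A,
#' rise 1.5 A per residue, twist 100 degrees per residue — the textbook
#' alpha-helix parameters, giving the realistic ~3.8 A consecutive Cα-Cα
#' spacing and non-trivial 8 A neighborhoods. Poly-Ala unless a sequence is
#' supplied.
#'
#' @param n Number of residues (>= 4).
#' @param seed Accepted for generator-interface symmetry; the ideal helix is
#'   fully determined by `n`.
#' @param sequence Optional amino-acid string of length `n`.
#' @return A [structure_model()] (chain `"A"`).
#' @examples
#' h <- make_helix(10)
#' dist(ca_coords(h)[1:2, ])  # ~3.83 A
#' @export
make_helix <- function(n, seed = NULL, sequence = NULL) {
  if (n < 4L)
    vs_abort("a helix fixture needs at least 4 residues", "varstruct_domain")
  radius <- 2.3; rise <- 1.5; twist <- 100 * pi / 180
  i <- seq_len(n) - 1L
  xyz <- cbind(radius * cos(i * twist), radius * sin(i * twist), rise * i)
  aa <- if (is.null(sequence)) rep("A", n) else {
    stopifnot(nchar(sequence) == n)
    strsplit(sequence, "")[[1L]]
  }
  structure_model("A", aa, xyz)
}

#' Controlled structural perturbation plan
#'
#' Describes a rigid displacement of one residue segment plus optional
#' seeded Gaussian jitter — the synthetic stand-in for a mutation-induced
#' conformational change whose expected metrics are known analytically.
#'
#' @param segment Integer vector of residue indices to displace.
#' @param displacement Length-3 displacement vector in Angstrom.
#' @param jitter_sigma Standard deviation (Angstrom) of isotropic Gaussian
#'   jitter added to every residue.
#' @param seed RNG seed for the jitter.
#' @return An object of class `perturbation_plan`.
#' @export
perturbation_plan <- function(segment, displacement, jitter_sigma = 0,
                              seed = 1L) {
  if (jitter_sigma < 0)
    vs_abort("jitter_sigma must be >= 0", "varstruct_domain")
  stopifnot(length(displacement) == 3L)
  structure(list(segment = as.integer(segment),
                 displacement = as.numeric(displacement),
                 jitter_sigma = jitter_sigma, seed = as.integer(seed)),
            class = "perturbation_plan")
}

#' Apply a perturbation plan and compute its expected metrics
#'
#' Copies the model, translates the segment's Cα coordinates by the plan's
#' displacement, then adds seeded Gaussian jitter to all residues. The
#' returned `expected` oracle is computed by direct distance measurement on
#' the pre/post coordinates (base-R `dist`, no shared code with the metric
#' implementations): full WT and mutant Cα-Cα distance matrices, per-residue
#' shift norms, and the displaced-residue mask (the expected retained set
#' under outlier rejection is its complement when the displacement exceeds
#' the cutoff).
#'
#' @param model A [structure_model()] (the WT).
#' @param plan A [perturbation_plan()].
#' @return List: `mutant` ([structure_model()]) and `expected` (class
#'   `expected_metrics`: `d_wt`, `d_mut` distance matrices,
#'   `per_residue_shift`, `displaced`, `displacement`).
#' @export
apply_perturbation <- function(model, plan) {
  n <- n_residues(model)
  if (any(plan$segment < 1L | plan$segment > n))
    vs_abort("plan segment outside the model", "varstruct_domain")
  wt_xyz <- ca_coords(model)
  mut_xyz <- wt_xyz
  mut_xyz[plan$segment, ] <- sweep(mut_xyz[plan$segment, , drop = FALSE], 2,
                                   plan$displacement, `+`)
  if (plan$jitter_sigma > 0) {
    set.seed(plan$seed)
    mut_xyz <- mut_xyz + matrix(stats::rnorm(3L * n, sd = plan$jitter_sigma),
                                n, 3L)
  }
  mutant <- structure_model(model$chain_id, model$residues$aa, mut_xyz,
                            author = model$residues$author)
  expected <- structure(list(
    d_wt = as.matrix(stats::dist(wt_xyz)),
    d_mut = as.matrix(stats::dist(mut_xyz)),
    per_residue_shift = sqrt(rowSums((mut_xyz - wt_xyz)^2)),
    displaced = seq_len(n) %in% plan$segment,
    displacement = plan$displacement),
    class = "expected_metrics")
  list(mutant = mutant, expected = expected)
}

#' Expected local RMSD from an expected-metrics oracle
#'
#' Valid when the superposition is fitted on undisplaced residues and the
#' jitter is zero: the transform is then the identity and each window
#' residue contributes exactly its shift norm.
#'
#' @param expected An `expected_metrics` object.
#' @param window WT residue indices of the local window.
#' @return Expected RMSD (Angstrom).
#' @export
expected_local_rmsd <- function(expected, window) {
  sqrt(mean(expected$per_residue_shift[window]^2))
}

#' Expected delta-D from an expected-metrics oracle
#'
#' @param expected An `expected_metrics` object.
#' @param site,neighbor WT residue indices (identity correspondence).
#' @return Expected `d_mut - d_wt` (Angstrom).
#' @export
expected_delta_d <- function(expected, site, neighbor) {
  expected$d_mut[site, neighbor] - expected$d_wt[site, neighbor]
}

#' CDS fixtures realizing the printed MYB variant calls
#'
#' Builds a synthetic coding sequence whose codons at the mutated positions
#' carry exactly the bases forced by the reported substitutions, with fixed
#' GCT (Ala) filler codons elsewhere so fixtures are identical across
#' platforms and translation is stop-free.
#'
#' Tag `"015992"`: 255 codons with codon 12 = GCT (Ala), codon 114 = CAA
#' (Gln), codon 255 = GGA (Gly) and SNPs G>T at 34, C>G at 340, G>A at 764.
#' Tag `"040854"`: 223 codons with codon 187 = AAT (Asn), codon 223 = ATT
#' (Ile), SNPs A>G at 560 and 667, and the three-base ATG insertion between
#' CDS positions 579 and 580 (a codon boundary, so one residue is inserted
#' after codon 193; note the inserted codon encodes Met).
#'
#' @param gene_tag `"015992"` or `"040854"`.
#' @return List: `cds` ([coding_sequence()]) and `variants` (list of
#'   [variant()]).
#' @export
cds_for_printed_effects <- function(gene_tag = c("015992", "040854")) {
  gene_tag <- match.arg(gene_tag)
  if (gene_tag == "015992") {
    codons <- rep("GCT", 255)
    codons[1] <- "ATG"; codons[114] <- "CAA"; codons[255] <- "GGA"
    cds <- coding_sequence("gene_015992_cds", paste(codons, collapse = ""))
    variants <- list(variant("SNP", 34, "G", "T", id = "snp_34"),
                     variant("SNP", 340, "C", "G", id = "snp_340"),
                     variant("SNP", 764, "G", "A", id = "snp_764"))
  } else {
    codons <- rep("GCT", 223)
    codons[1] <- "ATG"; codons[187] <- "AAT"; codons[223] <- "ATT"
    cds <- coding_sequence("gene_040854_cds", paste(codons, collapse = ""))
    variants <- list(variant("SNP", 560, "A", "G", id = "snp_560"),
                     variant("SNP", 667, "A", "G", id = "snp_667"),
                     variant("INS", 579, "", "ATG", id = "ins_579_580"))
  }
  list(cds = cds, variants = variants)
}
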