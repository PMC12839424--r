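test_that("codon_index maps CDS positions to residue indices", {
  # printed position/residue pairs of the analyzed MYB variants
  expect_identical(codon_index(c(34, 340, 764, 560, 667)),
                   c(12L, 114L, 255L, 187L, 223L))
  # codon boundaries forced by the definition
  expect_identical(codon_index(c(1, 3, 4)), c(1L, 1L, 2L))
  expect_identical(codon_index(3 * (1:50)), 1:50)
  expect_identical(codon_index(3 * (1:50) - 2), 1:50)
  expect_error(codon_index(0), class = "varstruct_domain")
  expect_error(codon_index(-3), class = "varstruct_domain")
})

test_that("apply_variants performs checked, coordinate-stable edits", {
  cds <- coding_sequence("toy", "ATGGCA")
  expect_equal(apply_variants(cds, list(variant("SNP", 4, "G", "T")))$seq,
               "ATGTCA")
  expect_equal(apply_variants(cds, list(variant("INS", 3, "", "TAC")))$seq,
               "ATGTACGCA")
  expect_equal(apply_variants(cds, list(variant("DEL", 4, "GCA", "")))$seq,
               "ATG")
  # multi-variant: descending application keeps upstream coordinates valid
  out <- apply_variants(cds, list(variant("SNP", 1, "A", "C"),
                                  variant("INS", 3, "", "TT"),
                                  variant("SNP", 6, "A", "G")))
  expect_equal(out$seq, "CTGTTGCG")
  expect_error(apply_variants(cds, list(variant("SNP", 4, "C", "T"))),
               class = "varstruct_ref_mismatch")
  expect_error(apply_variants(cds, list(variant("DEL", 2, "TGG", ""),
                                        variant("SNP", 3, "G", "A"))),
               class = "varstruct_overlap")
  expect_error(apply_variants(cds, list(variant("SNP", 99, "A", "C"))),
               class = "varstruct_domain")
})

test_that("applying a SNP then its inverse restores the sequence", {
  set.seed(42)
  for (i in 1:100) {
    cds <- coding_sequence("rt", random_cds(30, stop_free = FALSE))
    pos <- sample(nchar(cds$seq), 1)
    ref <- substr(cds$seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mut <- apply_variants(cds, list(variant("SNP", pos, ref, alt)))
    back <- apply_variants(mut, list(variant("SNP", pos, alt, ref)))
    expect_identical(back$seq, cds$seq)
  }
})

test_that("translation follows the standard code and truncates at stops", {
  expect_equal(translate_cds("ATGGAA"), "ME")
  expect_equal(translate_cds("GCT"), "A")
  expect_equal(translate_cds("TCT"), "S")
  expect_equal(translate_cds("ATGTAAGCT"), "M")      # stop excluded
  expect_warning(out <- translate_cds("ATGGAAG"),
                 class = "varstruct_partial_codon")
  expect_equal(out, "ME")
})

test_that("the hand-typed genetic code matches the reference table", {
  mine <- standard_genetic_code()
  ref <- Biostrings::GENETIC_CODE
  expect_length(mine, 64)
  expect_equal(sum(mine == "*"), 3)
  expect_equal(mine[names(ref)], ref[names(ref)], ignore_attr = TRUE)
})

test_that("SNP classification reproduces the printed substitution calls", {
  fx <- cds_for_printed_effects("015992")
  eff <- classify_effects(fx$cds, fx$variants)
  expect_equal(eff$effect_class, rep("missense", 3))
  expect_equal(eff$residue_index, c(12L, 114L, 255L))
  expect_equal(eff$notation, c("A12S", "Q114E", "G255E"))
  # Q -> E at 114 and G -> E at 255, wt-first direction
  expect_equal(eff$wt_aa, c("A", "Q", "G"))
  expect_equal(eff$mut_aa, c("S", "E", "E"))
})

test_that("every single-base SNP classifies as the brute-force oracle says", {
  toy <- coding_sequence("toy6", "ATGGCTTACCAATGGGGA")  # 6 codons, stop-free
  for (pos in seq_len(nchar(toy$seq))) {
    ref <- substr(toy$seq, pos, pos)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      got <- classify_effects(toy, list(variant("SNP", pos, ref, alt)))
      want <- brute_force_snp_effect(toy$seq, pos, alt)
      expect_equal(got$effect_class, want$class,
                   info = sprintf("pos %d %s>%s", pos, ref, alt))
      expect_equal(got$residue_index, want$index)
      expect_equal(got$wt_aa, want$wt)
      if (got$effect_class %in% c("missense", "synonymous"))
        expect_equal(got$mut_aa, want$mut)
    }
  }
})

test_that("stop gain and loss are recognized", {
  cds <- coding_sequence("s", "ATGTAAGCT")
  lost <- classify_effects(cds, list(variant("SNP", 4, "T", "C")))
  expect_equal(lost$effect_class, "stop_lost")
  cds2 <- coding_sequence("s2", "ATGTGGGCT")
  gained <- classify_effects(cds2, list(variant("SNP", 6, "G", "A")))
  expect_equal(gained$effect_class, "stop_gained")
  expect_equal(gained$notation, "W2*")
})

test_that("in-frame and frameshift indels are classified correctly", {
  # M H S A: insertion of Tyr codon at the codon-2/3 boundary
  cds <- coding_sequence("ins", "ATGCATTCTGCT")
  eff <- classify_effects(cds, list(variant("INS", 6, "", "TAC")))
  expect_equal(eff$effect_class, "inframe_insertion")
  expect_equal(eff$mut_aa, "Y")
  expect_equal(eff$notation, "H2_S3insY")

  del <- classify_effects(cds, list(variant("DEL", 4, "CAT", "")))
  expect_equal(del$effect_class, "inframe_deletion")
  expect_equal(del$wt_aa, "H")
  expect_equal(del$notation, "H2del")

  fs1 <- classify_effects(cds, list(variant("INS", 6, "", "TA")))
  expect_equal(fs1$effect_class, "frameshift")
  expect_equal(fs1$residue_index, 3L)
  fs2 <- classify_effects(cds, list(variant("DEL", 7, "T", "")))
  expect_equal(fs2$effect_class, "frameshift")
  expect_equal(fs2$notation, "S3fs")
})

test_that("codon-boundary 3n insertions never alter wild-type residues; 1-2 nt indels always frameshift", {
  set.seed(7)
  for (i in 1:25) {
    cds <- coding_sequence("p", random_cds(20))
    wt_prot <- translate_cds(cds)
    k <- sample(1:3, 1)
    boundary <- 3L * sample(19, 1)
    ins <- paste(sample(names(standard_genetic_code())[standard_genetic_code() != "*"],
                        k, replace = TRUE), collapse = "")
    mut_prot <- translate_cds(apply_variants(cds, list(variant("INS", boundary, "", ins))))
    # all WT residues survive in order
    expect_equal(paste0(substr(mut_prot, 1, boundary / 3),
                        substr(mut_prot, boundary / 3 + k + 1, nchar(mut_prot))),
                 wt_prot)
    short <- sample(1:2, 1)
    pos <- sample(18, 1)
    fs <- classify_effects(cds, list(
      variant("DEL", pos, substr(cds$seq, pos, pos + short - 1L), "")))
    expect_equal(fs$effect_class, "frameshift")
  }
})

test_that("one effect row is returned per variant and TSV IO round-trips", {
  fx <- cds_for_printed_effects("040854")
  eff <- classify_effects(fx$cds, fx$variants)
  expect_equal(nrow(eff), length(fx$variants))

  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_variant_tsv(fx$variants, tmp)
  back <- read_variant_tsv(tmp)
  expect_equal(length(back), 3L)
  expect_equal(vapply(back, `[[`, "", "kind"), c("SNP", "SNP", "INS"))
  expect_equal(vapply(back, `[[`, "", "alt"), c("G", "G", "ATG"))
  expect_equal(classify_effects(fx$cds, back), eff)
})

test_that("effect_notation renders the compact forms", {
  expect_equal(effect_notation(list(effect_class = "missense",
                                    residue_index = 114L,
                                    wt_aa = "Q", mut_aa = "E")), "Q114E")
  expect_equal(effect_notation(list(effect_class = "synonymous",
                                    residue_index = 10L,
                                    wt_aa = "A", mut_aa = "A")), "A10A")
  expect_equal(effect_notation(list(effect_class = "inframe_insertion",
                                    residue_index = 194L, wt_aa = "",
                                    mut_aa = "Y", anchor_left = "H",
                                    anchor_right = "S")), "H194_S195insY")
  expect_equal(effect_notation(list(effect_class = "inframe_deletion",
                                    residue_index = 10L, wt_aa = "AVC",
                                    mut_aa = "")), "A10_C12del")
})

test_that("haplotype translation applies all variants jointly", {
  fx <- cds_for_printed_effects("015992")
  hap <- translate_haplotype(fx$cds, fx$variants)
  expect_equal(substr(hap, 12, 12), "S")
  expect_equal(substr(hap, 114, 114), "E")
  expect_equal(substr(hap, 255, 255), "E")
  expect_equal(nchar(hap), 255L)
})
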