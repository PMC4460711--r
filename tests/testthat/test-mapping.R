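mention_row <- function(ref_aa, aa_pos, alt_aa, year = 2012L,
                        class_label = "LoF") {
  data.frame(gene = "G", kind = "substitution_protein", ref_aa = ref_aa,
             alt_aa = alt_aa, aa_pos = aa_pos, nt_pos = NA_integer_,
             nt_ref = NA_character_, nt_alt = NA_character_, year = year,
             class_label = class_label, start = 1L, end = 1L, span = "",
             stringsAsFactors = FALSE)
}

test_that("plus-strand substitution back-maps to the expected edit", {
  v <- backmap_substitution(mention_row("A", 2L, "V"), toy_plus_tx(),
                            toy_plus_genome)
  expect_identical(v$ref_codon, "GCA")
  expect_identical(v$alt_codon, "GTA")
  expect_identical(v$genomic_pos, 7L)
  expect_identical(v$ref_base_coding, "C")
  expect_identical(v$alt_base_coding, "T")
  expect_identical(v$ref_base_genome, "C")
  expect_identical(v$alt_base_genome, "T")
  expect_identical(v$subtype, "missense")
  expect_identical(v$n_edits, 1L)
  # independent forward annotation of the reported genomic edit
  fw <- oracle_forward_annotate(toy_plus_tx(), toy_plus_genome,
                                v$genomic_pos, v$alt_base_genome)
  expect_identical(fw$aa_pos, 2L)
  expect_identical(fw$ref_aa, "A")
  expect_identical(fw$alt_aa, "V")
})

test_that("minus-strand substitution complements the genomic alleles", {
  v <- backmap_substitution(mention_row("A", 2L, "V"), toy_minus_tx(),
                            toy_minus_genome)
  expect_identical(v$ref_codon, "GCA")
  expect_identical(v$alt_codon, "GTA")
  expect_identical(v$ref_base_coding, "C")
  expect_identical(v$alt_base_coding, "T")
  # plus-strand alleles are the complements
  expect_identical(v$ref_base_genome, "G")
  expect_identical(v$alt_base_genome, "A")
  fw <- oracle_forward_annotate(toy_minus_tx(), toy_minus_genome,
                                v$genomic_pos, v$alt_base_genome)
  expect_identical(fw$aa_pos, 2L)
  expect_identical(fw$ref_aa, "A")
  expect_identical(fw$alt_aa, "V")
})

test_that("stated reference residue is validated against the genome", {
  expect_error(backmap_substitution(mention_row("S", 2L, "V"), toy_plus_tx(),
                                    toy_plus_genome),
               class = "lofgof_reference_mismatch")
  expect_error(backmap_substitution(mention_row("A", 9L, "V"), toy_plus_tx(),
                                    toy_plus_genome),
               class = "lofgof_position_out_of_range")
})

test_that("nonsense and silent subtypes are resolved from the codon change", {
  # aa3 of the plus toy is the stop codon TAG; use aa1 (ATG, M)
  v <- backmap_substitution(mention_row("M", 1L, "M"), toy_plus_tx(),
                            toy_plus_genome)
  expect_identical(v$subtype, "silent")
  expect_identical(v$n_edits, 0L)
  g <- c(chrT = "AATGGTGGTAGCC") # ATG GTG GTA? no: CDS 2..13 = ATGGTGGTAGCC
  tx <- transcript_model("T", "G", "chrT", "+", 2L, 13L)
  # CDS ATG GTG GTA GCC; aa2 = V (GTG)
  v2 <- backmap_substitution(mention_row("V", 2L, "*"), tx, g)
  expect_identical(v2$subtype, "nonsense")
  expect_identical(translate_codon(v2$alt_codon), "*")
})

test_that("cDNA substitutions map through the CDS coordinate", {
  mn <- data.frame(gene = "G", kind = "substitution_nucleotide",
                   ref_aa = NA_character_, alt_aa = NA_character_,
                   aa_pos = NA_integer_, nt_pos = 5L, nt_ref = "C",
                   nt_alt = "T", year = 2012L, class_label = "LoF",
                   start = 1L, end = 1L, span = "", stringsAsFactors = FALSE)
  v <- backmap_nt_substitution(mn, toy_plus_tx(), toy_plus_genome)
  expect_identical(v$aa_pos, 2L)
  expect_identical(v$ref_codon, "GCA")
  expect_identical(v$alt_codon, "GTA")
  expect_identical(v$genomic_pos, 7L)
  mn$nt_ref <- "A"
  expect_error(backmap_nt_substitution(mn, toy_plus_tx(), toy_plus_genome),
               class = "lofgof_reference_mismatch")
  mn$nt_pos <- 99L
  expect_error(backmap_nt_substitution(mn, toy_plus_tx(), toy_plus_genome),
               class = "lofgof_position_out_of_range")
})

test_that("back-mapping round-trips against forward annotation", {
  co <- generate_corpus(simulation_config(
    seed = 23, n_lof = 120L, n_gof = 80L,
    subtype_probs_per_class = list(
      LoF = c(missense = 0.7, nonsense = 0.3, deletion = 0, indel = 0,
              duplication = 0, frameshift = 0),
      GoF = c(missense = 0.9, nonsense = 0.1, deletion = 0, indel = 0,
              duplication = 0, frameshift = 0)
    )))
  mentions <- extract_mentions_table(co$sentences)
  variants <- map_mentions(mentions, co$transcripts, co$genome)
  expect_true(all(variants$status == "ok"))
  expect_true(all(variants$n_edits == 1L))
  strands <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    tx <- co$transcripts[[v$gene]]
    strands[i] <- tx$strand
    fw <- oracle_forward_annotate(tx, co$genome, v$genomic_pos,
                                  v$alt_base_genome)
    if (v$subtype == "nonsense") {
      expect_identical(fw$alt_aa[1], "*")
      expect_identical(fw$aa_pos[1], v$aa_pos)
      expect_identical(fw$ref_aa[1], v$ref_aa)
    } else {
      expect_identical(fw$aa_pos, v$aa_pos)
      expect_identical(fw$ref_aa, v$ref_aa)
      expect_identical(fw$alt_aa, v$alt_aa)
    }
    # coding-strand alleles of minus-strand variants complement the
    # plus-strand alleles
    if (tx$strand == "-") {
      expect_identical(complement_base(v$ref_base_genome), v$ref_base_coding)
      expect_identical(complement_base(v$alt_base_genome), v$alt_base_coding)
    } else {
      expect_identical(v$ref_base_genome, v$ref_base_coding)
    }
    # chosen alt codon is Hamming-minimal among the residue's codons
    d_chosen <- sum(strsplit(v$ref_codon, "")[[1]] !=
                      strsplit(v$alt_codon, "")[[1]])
    d_all <- vapply(codons_for_aa(v$alt_aa), function(cc) {
      sum(strsplit(v$ref_codon, "")[[1]] != strsplit(cc, "")[[1]])
    }, 1)
    expect_equal(d_chosen, min(d_all))
  }
  expect_setequal(unique(strands), c("+", "-"))
})

test_that("preprocessing filters remove year, mismatch and silent records", {
  clean <- function(year) {
    data.frame(year = year, status = "ok", subtype = "missense",
               stringsAsFactors = FALSE)
  }
  toy <- rbind(
    clean(2008L),                                     # pre-cutoff year
    data.frame(year = 2012L, status = "reference_mismatch",
               subtype = NA_character_, stringsAsFactors = FALSE),
    data.frame(year = 2012L, status = "ok", subtype = "silent",
               stringsAsFactors = FALSE),
    clean(2011L), clean(2012L), clean(2013L)
  )
  res <- apply_filters(toy, min_year = 2010L)
  expect_identical(res$report$input, 6L)
  expect_identical(res$report$removed,
                   c(year = 1L, reference = 1L, silent = 1L))
  expect_identical(res$report$retained, 3L)
  expect_identical(nrow(res$retained), 3L)
  # conservation: input = retained + removed
  expect_identical(res$report$input,
                   res$report$retained + sum(res$report$removed))
  # a record violating several rules counts once, under the first rule
  multi <- data.frame(year = 2005L, status = "reference_mismatch",
                      subtype = "silent", stringsAsFactors = FALSE)
  res2 <- apply_filters(rbind(toy, multi), min_year = 2010L)
  expect_identical(res2$report$removed,
                   c(year = 2L, reference = 1L, silent = 1L))
  # min_year 0 with clean records is the identity
  res3 <- apply_filters(toy[4:6, ], min_year = 0L)
  expect_identical(res3$report$retained, 3L)
  expect_identical(sum(res3$report$removed), 0L)
})

test_that("VCF output re-parses with an independent reader", {
  skip_if_not_installed("VariantAnnotation")
  co <- generate_corpus(simulation_config(
    seed = 29, n_lof = 20L, n_gof = 15L,
    subtype_probs_per_class = list(
      LoF = c(missense = 1, nonsense = 0, deletion = 0, indel = 0,
              duplication = 0, frameshift = 0),
      GoF = c(missense = 1, nonsense = 0, deletion = 0, indel = 0,
              duplication = 0, frameshift = 0)
    )))
  mentions <- extract_mentions_table(co$sentences)
  variants <- map_mentions(mentions, co$transcripts, co$genome)
  path <- tempfile(fileext = ".vcf")
  write_variants_vcf(variants, co$genome, path)
  vcf <- VariantAnnotation::readVcf(path)
  expect_identical(nrow(vcf), nrow(variants))
  # REF alleles in the file match the plus-strand genome
  ref <- as.character(VariantAnnotation::ref(vcf))
  pos <- BiocGenerics::start(SummarizedExperiment::rowRanges(vcf))
  chr <- as.character(GenomicRanges::seqnames(
    SummarizedExperiment::rowRanges(vcf)))
  for (i in seq_along(ref)) {
    expect_identical(substr(co$genome[[chr[i]]], pos[i], pos[i]), ref[i])
  }
})
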