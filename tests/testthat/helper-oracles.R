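# Shared fixtures and independent oracles.
#
# The forward-annotation oracle edits the genome at the reported position,
# re-extracts the CDS with Biostrings primitives (independently of the
# package's coordinate arithmetic) and re-translates it, returning the
# residue change actually induced by the genomic edit.

toy_plus_tx <- function() {
  transcript_model("TXP", "TOYP", "chrT", "+", 3L, 11L)
}
toy_plus_genome <- c(chrT = "AAATGGCATAGCCC")

toy_minus_tx <- function() {
  transcript_model("TXM", "TOYM", "chrT", "-", 3L, 11L)
}
toy_minus_genome <- c(chrT = "AACTATGCCATCCC")

# CDS extraction with Biostrings only (no package coordinate code).
oracle_cds <- function(transcript, genome) {
  chrom <- Biostrings::DNAString(genome[[transcript$chrom]])
  ex <- transcript$coding_exons[order(transcript$coding_exons$start), ,
                                drop = FALSE]
  pieces <- lapply(seq_len(nrow(ex)), function(i) {
    chrom[ex$start[i]:ex$end[i]]
  })
  cds <- do.call(Biostrings::xscat, pieces)
  if (transcript$strand == "-") cds <- Biostrings::reverseComplement(cds)
  cds
}

# Apply a plus-strand single-base edit and report the induced residue change.
oracle_forward_annotate <- function(transcript, genome, genomic_pos,
                                    alt_base_genome) {
  ref_cds <- oracle_cds(transcript, genome)
  g2 <- genome
  s <- g2[[transcript$chrom]]
  substr(s, genomic_pos, genomic_pos) <- alt_base_genome
  g2[[transcript$chrom]] <- s
  alt_cds <- oracle_cds(transcript, g2)
  ref_aa <- strsplit(as.character(
    Biostrings::translate(ref_cds, no.init.codon = TRUE)), "")[[1]]
  alt_aa <- strsplit(as.character(
    Biostrings::translate(alt_cds, no.init.codon = TRUE)), "")[[1]]
  changed <- which(ref_aa != alt_aa)
  list(aa_pos = changed, ref_aa = ref_aa[changed], alt_aa = alt_aa[changed],
       silent = length(changed) == 0L)
}

# Tiny feature table with known counts for classifier unit tests.
make_separable_features <- function(n_per_class = 20L) {
  data.frame(
    REF = rep(c("A", "C"), each = n_per_class),
    SUB = rep(c("G", "T"), each = n_per_class),
    TYPE = rep(c("missense", "deletion"), each = n_per_class),
    SCORE = c(rnorm(n_per_class, 3), rnorm(n_per_class, -3)),
    GRADE = NA_character_,
    SL = rep(c("Nucleus", "Cell membrane"), each = n_per_class),
    PD = rep(c("Kinase", "Cadherin"), each = n_per_class),
    Class = rep(c("LoF", "GoF"), each = n_per_class),
    stringsAsFactors = FALSE
  )
}
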