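## One-row data-frame skeleton for a mapped variant.
.empty_variant <- function() {
  data.frame(
    gene = NA_character_, transcript_id = NA_character_,
    chrom = NA_character_, strand = NA_character_,
    genomic_pos = NA_integer_,
    ref_base_genome = NA_character_, alt_base_genome = NA_character_,
    ref_base_coding = NA_character_, alt_base_coding = NA_character_,
    ref_codon = NA_character_, alt_codon = NA_character_,
    codon_positions = NA_character_,
    aa_pos = NA_integer_, ref_aa = NA_character_, alt_aa = NA_character_,
    subtype = NA_character_, n_edits = NA_integer_,
    year = NA_integer_, class_label = NA_character_,
    status = NA_character_, stringsAsFactors = FALSE
  )
}

#' Back-map a protein substitution onto the genome
#'
#' Converts a protein-level substitution mention (reference residue, 1-based
#' residue position, alternate residue) into a genomic variant with
#' codon-level alleles. The reference codon is read from the transcript via
#' [codon_at()] and validated against the stated reference residue; a
#' mismatch raises a `lofgof_reference_mismatch` condition (the removal rule
#' for mutations whose stated reference disagrees with the reference
#' genome). The alternate codon is the codon of the alternate residue with
#' minimal Hamming distance to the reference codon, ties broken by
#' lexicographic order of the codon string. The subtype is `nonsense` when
#' the alternate residue is a stop, `silent` when it equals the reference,
#' and `missense` otherwise. For single-edit codon changes the genomic
#' position and plus-strand alleles of the edited base are reported
#' (complemented on minus-strand transcripts); multi-edit changes keep the
#' codon-level description only.
#'
#' @param mention one-row mention data frame (as from [extract_mentions()])
#'   or a list with `ref_aa`, `alt_aa`, `aa_pos`, and optionally `year`,
#'   `class_label`.
#' @param transcript the gene's [transcript_model()].
#' @param genome named character vector or `DNAStringSet`.
#' @return one-row data frame describing the mapped variant.
#' @export
backmap_substitution <- function(mention, transcript, genome) {
  ref_aa <- mention$ref_aa
  alt_aa <- mention$alt_aa
  aa_pos <- mention$aa_pos
  stopifnot(!is.na(ref_aa), !is.na(alt_aa), !is.na(aa_pos), aa_pos >= 1L)
  at <- codon_at(transcript, genome, aa_pos)
  ref_codon <- at$codon
  if (translate_codon(ref_codon) != ref_aa) {
    stop(.cond("lofgof_reference_mismatch",
               sprintf("%s p.%s%d%s: codon %s translates to %s, not %s",
                       transcript$gene, ref_aa, aa_pos, alt_aa, ref_codon,
                       translate_codon(ref_codon), ref_aa)))
  }
  cands <- codons_for_aa(alt_aa) # sorted, so first minimal = lexicographic tie-break
  d <- vapply(cands, function(cc) .hamming(ref_codon, cc), 1)
  alt_codon <- cands[which.min(d)]
  .finish_variant(mention, transcript, at$positions, ref_codon, alt_codon,
                  aa_pos)
}

.finish_variant <- function(mention, transcript, positions, ref_codon,
                            alt_codon, aa_pos) {
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  v <- .empty_variant()
  v$gene <- transcript$gene
  v$transcript_id <- transcript$transcript_id
  v$chrom <- transcript$chrom
  v$strand <- transcript$strand
  v$ref_codon <- ref_codon
  v$alt_codon <- alt_codon
  v$codon_positions <- paste(positions, collapse = ",")
  v$aa_pos <- aa_pos
  v$ref_aa <- ref_aa
  v$alt_aa <- alt_aa
  v$subtype <- if (alt_aa == "*") "nonsense"
               else if (alt_aa == ref_aa) "silent" else "missense"
  rb <- strsplit(ref_codon, "")[[1]]
  ab <- strsplit(alt_codon, "")[[1]]
  edits <- which(rb != ab)
  v$n_edits <- length(edits)
  if (length(edits) == 1L) {
    i <- edits
    v$genomic_pos <- positions[i]
    v$ref_base_coding <- rb[i]
    v$alt_base_coding <- ab[i]
    if (transcript$strand == "+") {
      v$ref_base_genome <- rb[i]; v$alt_base_genome <- ab[i]
    } else {
      v$ref_base_genome <- complement_base(rb[i])
      v$alt_base_genome <- complement_base(ab[i])
    }
  }
  v$year <- if (!is.null(mention$year)) mention$year else NA_integer_
  v$class_label <- if (!is.null(mention$class_label)) mention$class_label
                   else NA_character_
  v$status <- "ok"
  v
}

#' Map a cDNA substitution mention onto the genome
#'
#' A `c.<pos><ref>><alt>` mention addresses a CDS base directly; the stated
#' reference base is validated against the transcript CDS
#' (`lofgof_reference_mismatch` on disagreement) and the alternate codon is
#' the reference codon with that single base replaced.
#'
#' @inheritParams backmap_substitution
#' @return one-row mapped-variant data frame.
#' @export
backmap_nt_substitution <- function(mention, transcript, genome) {
  nt_pos <- mention$nt_pos
  stopifnot(!is.na(nt_pos), nt_pos >= 1L)
  if (nt_pos > transcript$cds_length) {
    stop(.cond("lofgof_position_out_of_range",
               sprintf("c.%d beyond CDS of %s (length %d)",
                       nt_pos, transcript$transcript_id,
                       transcript$cds_length)))
  }
  aa_pos <- (nt_pos - 1L) %/% 3L + 1L
  at <- codon_at(transcript, genome, aa_pos)
  i <- (nt_pos - 1L) %% 3L + 1L
  ref_base <- substr(at$codon, i, i)
  if (ref_base != mention$nt_ref) {
    stop(.cond("lofgof_reference_mismatch",
               sprintf("%s c.%d%s>%s: CDS base is %s, not %s",
                       transcript$gene, nt_pos, mention$nt_ref,
                       mention$nt_alt, ref_base, mention$nt_ref)))
  }
  alt_codon <- at$codon
  substr(alt_codon, i, i) <- mention$nt_alt
  .finish_variant(mention, transcript, at$positions, at$codon, alt_codon,
                  aa_pos)
}

#' Map a mention table to genomic variants
#'
#' Dispatches each mention to [backmap_substitution()] (protein
#' substitutions), [backmap_nt_substitution()] (cDNA substitutions), or a
#' pass-through for non-substitution kinds (deletion, indel, duplication,
#' frameshift), whose subtype comes from [classify_mention_kind()] and whose
#' residue anchor is taken from the mention (`aa_pos`, or the codon
#' containing `nt_pos`). Mapping failures are recorded per row in the
#' `status` column (`reference_mismatch`, `position_out_of_range`) rather
#' than aborting. When a gene has several transcripts the first in input
#' order is used.
#'
#' @param mentions mention data frame.
#' @param transcripts list of [transcript_model()] objects.
#' @param genome named character vector or `DNAStringSet`.
#' @return data frame with one row per mention.
#' @export
map_mentions <- function(mentions, transcripts, genome) {
  by_gene <- list()
  for (tx in transcripts) {
    if (is.null(by_gene[[tx$gene]])) by_gene[[tx$gene]] <- tx
  }
  rows <- vector("list", nrow(mentions))
  for (i in seq_len(nrow(mentions))) {
    mn <- mentions[i, ]
    tx <- by_gene[[mn$gene]]
    if (is.null(tx)) {
      v <- .empty_variant()
      v$gene <- mn$gene; v$year <- mn$year; v$class_label <- mn$class_label
      v$status <- "unknown_gene"
      rows[[i]] <- v
      next
    }
    rows[[i]] <- tryCatch({
      if (mn$kind %in% c("substitution_protein", "nonsense") &&
          !is.na(mn$aa_pos) && !is.na(mn$ref_aa) && !is.na(mn$alt_aa)) {
        backmap_substitution(mn, tx, genome)
      } else if (mn$kind == "substitution_nucleotide") {
        backmap_nt_substitution(mn, tx, genome)
      } else {
        .passthrough_variant(mn, tx, genome)
      }
    },
    lofgof_reference_mismatch = function(e) {
      v <- .variant_stub(mn, tx); v$status <- "reference_mismatch"; v
    },
    lofgof_position_out_of_range = function(e) {
      v <- .variant_stub(mn, tx); v$status <- "position_out_of_range"; v
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.variant_stub <- function(mn, tx) {
  v <- .empty_variant()
  v$gene <- mn$gene; v$transcript_id <- tx$transcript_id
  v$chrom <- tx$chrom; v$strand <- tx$strand
  v$aa_pos <- mn$aa_pos; v$ref_aa <- mn$ref_aa; v$alt_aa <- mn$alt_aa
  v$year <- mn$year; v$class_label <- mn$class_label
  v
}

## Non-substitution mentions keep their subtype and residue anchor; no
## allele derivation is attempted.
.passthrough_variant <- function(mn, tx, genome) {
  aa_pos <- mn$aa_pos
  if (is.na(aa_pos) && !is.na(mn$nt_pos)) {
    if (mn$nt_pos > tx$cds_length) {
      stop(.cond("lofgof_position_out_of_range",
                 sprintf("c.%d beyond CDS of %s", mn$nt_pos,
                         tx$transcript_id)))
    }
    aa_pos <- (mn$nt_pos - 1L) %/% 3L + 1L
  }
  v <- .variant_stub(mn, tx)
  if (!is.na(aa_pos)) {
    at <- codon_at(tx, genome, aa_pos)
    v$aa_pos <- aa_pos
    v$ref_aa <- translate_codon(at$codon)
    v$ref_codon <- at$codon
    v$codon_positions <- paste(at$positions, collapse = ",")
    v$genomic_pos <- at$positions[1]
  }
  v$subtype <- classify_mention_kind(mn$kind)
  v$status <- "ok"
  v
}

#' Apply the preprocessing filters
#'
#' Removes records published before `min_year`, records whose stated
#' reference disagrees with the reference genome (or that could not be
#' mapped), and silent substitutions — in that order, each record counted
#' once under the first rule it violates.
#'
#' @param variants mapped-variant data frame from [map_mentions()].
#' @param min_year publication-year cutoff (records with `year < min_year`
#'   are removed); default 2010.
#' @return list with `retained` (data frame) and `report` (list with
#'   `input`, `removed` = named vector `year`/`reference`/`silent`,
#'   `retained`).
#' @export
apply_filters <- function(variants, min_year = 2010L) {
  n <- nrow(variants)
  hit_year <- !is.na(variants$year) & variants$year < min_year
  bad_status <- variants$status != "ok"
  hit_ref <- !hit_year & bad_status
  hit_silent <- !hit_year & !hit_ref &
    !is.na(variants$subtype) & variants$subtype == "silent"
  keep <- !(hit_year | hit_ref | hit_silent)
  list(
    retained = variants[keep, , drop = FALSE],
    report = list(
      input = n,
      removed = c(year = sum(hit_year), reference = sum(hit_ref),
                  silent = sum(hit_silent)),
      retained = sum(keep)
    )
  )
}

#' Write mapped variants as VCF
#'
#' Emits single-base substitution variants (plus-strand `REF`/`ALT`) as
#' VCF 4.2 with `INFO` keys for gene, transcript, codon change, residue
#' change and subtype. Records without a single genomic position
#' (non-substitutions, multi-edit codon changes) are skipped.
#'
#' @param variants mapped-variant data frame.
#' @param genome named character vector (for contig lengths).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, genome, path) {
  if (!is.character(genome)) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  for (nm in names(genome)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", nm, nchar(genome[[nm]])),
               con)
  }
  info_defs <- c(
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
    '##INFO=<ID=TX,Number=1,Type=String,Description="Transcript id">',
    '##INFO=<ID=CODON,Number=1,Type=String,Description="Ref>Alt codon on the coding strand">',
    '##INFO=<ID=AA,Number=1,Type=String,Description="Residue change">',
    '##INFO=<ID=SUBTYPE,Number=1,Type=String,Description="Mutation subtype">'
  )
  writeLines(info_defs, con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO"), collapse = "\t"), con)
  sel <- !is.na(variants$genomic_pos) & !is.na(variants$ref_base_genome)
  v <- variants[sel, , drop = FALSE]
  if (nrow(v)) {
    v <- v[order(v$chrom, v$genomic_pos), , drop = FALSE]
    info <- sprintf("GENE=%s;TX=%s;CODON=%s>%s;AA=p.%s%d%s;SUBTYPE=%s",
                    v$gene, v$transcript_id, v$ref_codon, v$alt_codon,
                    v$ref_aa, v$aa_pos, v$alt_aa, v$subtype)
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                       v$chrom, v$genomic_pos,
                       sprintf("%s_p.%s%d%s", v$gene, v$ref_aa, v$aa_pos,
                               v$alt_aa),
                       v$ref_base_genome, v$alt_base_genome, info), con)
  }
  invisible(path)
}

#' Write mapped variants as TSV
#' @param variants mapped-variant data frame.
#' @param path output file.
#' @param header optional comment lines.
#' @export
write_variants_tsv <- function(variants, path, header = character(0)) {
  .write_tsv_with_header(variants, path, header)
}
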