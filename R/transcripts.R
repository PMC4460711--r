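#' Construct a transcript model
#'
#' A transcript model is the coordinate frame for back-mapping: an ordered set
#' of coding-exon intervals (1-based, inclusive, genomic plus-strand
#' coordinates) given in transcription order. On the minus strand
#' transcription order means descending genomic coordinates.
#'
#' @param transcript_id,gene identifiers.
#' @param chrom chromosome / sequence name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of equal length, 1-based
#'   inclusive, in transcription order.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, chrom, strand,
                             exon_starts, exon_ends) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends))
  exons <- data.frame(start = as.integer(exon_starts),
                      end = as.integer(exon_ends))
  ## transcription order: ascending starts on +, descending on -
  if (nrow(exons) > 1L) {
    ord <- order(exons$start, decreasing = (strand == "-"))
    if (!identical(ord, seq_len(nrow(exons)))) exons <- exons[ord, ]
  }
  ## non-overlap check in genomic order
  g <- exons[order(exons$start), , drop = FALSE]
  if (nrow(g) > 1L && any(g$start[-1] <= g$end[-nrow(g)])) {
    stop("transcript ", transcript_id, ": overlapping coding exons")
  }
  len <- sum(exons$end - exons$start + 1L)
  if (len %% 3L != 0L) {
    stop("transcript ", transcript_id, ": coding length ", len,
         " not divisible by 3")
  }
  structure(
    list(transcript_id = transcript_id, gene = gene, chrom = chrom,
         strand = strand, coding_exons = exons, cds_length = len),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s%s, %d coding exon(s), CDS %d nt\n",
              x$transcript_id, x$gene, x$chrom, x$strand,
              nrow(x$coding_exons), x$cds_length))
  invisible(x)
}

## Genomic positions of every CDS base, in coding (transcription) order.
## On the minus strand positions run downwards within each exon.
.cds_positions <- function(transcript) {
  ex <- transcript$coding_exons
  pos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    if (transcript$strand == "+") ex$start[i]:ex$end[i] else ex$end[i]:ex$start[i]
  }))
  as.integer(pos)
}

.chrom_seq <- function(genome, chrom) {
  if (is.character(genome)) {
    if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
    return(genome[[chrom]])
  }
  if (!chrom %in% names(genome)) stop("chromosome ", chrom, " not in genome")
  as.character(genome[[chrom]])
}

#' Extract the coding sequence of a transcript
#'
#' Concatenates the exon subsequences in transcription order,
#' reverse-complementing minus-strand segments, so the result always reads
#' 5'\eqn{\to}3' on the coding strand.
#'
#' @param transcript a [transcript_model()].
#' @param genome named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @return the CDS as a single character string.
#' @export
cds_sequence <- function(transcript, genome) {
  chrom <- .chrom_seq(genome, transcript$chrom)
  ex <- transcript$coding_exons
  if (any(ex$start < 1L) || any(ex$end > nchar(chrom))) {
    bad <- which(ex$start < 1L | ex$end > nchar(chrom))[1]
    stop("transcript ", transcript$transcript_id, ": exon interval [",
         ex$start[bad], ", ", ex$end[bad], "] outside chromosome ",
         transcript$chrom, " (length ", nchar(chrom), ")")
  }
  pieces <- substring(chrom, ex$start, ex$end)
  if (transcript$strand == "-") pieces <- reverse_complement(pieces)
  paste(pieces, collapse = "")
}

#' Validate a transcript's CDS
#'
#' Warns (does not fail) when the CDS does not start with `ATG` or contains an
#' internal stop codon; such transcripts remain usable.
#'
#' @inheritParams cds_sequence
#' @return `TRUE` (invisibly) if clean, `FALSE` if a warning was raised.
#' @export
validate_transcript <- function(transcript, genome) {
  cds <- cds_sequence(transcript, genome)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- translate_codon(codons)
  ok <- TRUE
  if (aa[1] != "M") {
    warning("transcript ", transcript$transcript_id,
            ": CDS does not begin with a start codon")
    ok <- FALSE
  }
  if (any(aa[-length(aa)] == "*")) {
    warning("transcript ", transcript$transcript_id,
            ": CDS contains an internal stop codon")
    ok <- FALSE
  }
  invisible(ok)
}

#' Genomic codon lookup for a residue position
#'
#' Returns the three genomic positions (in coding order; descending on the
#' minus strand) and the reference codon, read on the coding strand, for a
#' 1-based residue index.
#'
#' @inheritParams cds_sequence
#' @param aa_pos 1-based residue index.
#' @return list with `positions` (integer 3-vector, genomic, coding order) and
#'   `codon` (3-mer on the coding strand).
#' @export
codon_at <- function(transcript, genome, aa_pos) {
  n_codon <- transcript$cds_length %/% 3L
  if (aa_pos < 1L || aa_pos > n_codon) {
    stop(.cond("lofgof_position_out_of_range",
               sprintf("residue %d outside 1..%d of transcript %s",
                       aa_pos, n_codon, transcript$transcript_id)))
  }
  offsets <- (3L * (aa_pos - 1L) + 1L):(3L * aa_pos)
  pos <- .cds_positions(transcript)[offsets]
  chrom <- .chrom_seq(genome, transcript$chrom)
  bases <- substring(chrom, pos, pos)
  if (transcript$strand == "-") bases <- complement_base(bases)
  list(positions = pos, codon = paste(bases, collapse = ""))
}

## condition constructor shared by mapping errors
.cond <- function(class, msg, ...) {
  structure(class = c(class, "lofgof_error", "error", "condition"),
            list(message = msg, call = sys.call(-1), ...))
}

#' Write transcript models as GFF3
#'
#' One `CDS` feature per coding exon, 1-based inclusive, with `ID` and
#' `Parent` attributes; written through \pkg{rtracklayer}.
#'
#' @param transcripts list of [transcript_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcripts_gff3 <- function(transcripts, path) {
  rows <- do.call(rbind, lapply(transcripts, function(tx) {
    ex <- tx$coding_exons # transcription order
    lens <- ex$end - ex$start + 1L
    before <- cumsum(c(0L, lens[-length(lens)]))
    phase <- (3L - before %% 3L) %% 3L # bases to skip to the next codon start
    df <- data.frame(chrom = tx$chrom, start = ex$start, end = ex$end,
                     strand = tx$strand, phase = phase,
                     id = sprintf("cds-%s-%d", tx$transcript_id,
                                  seq_len(nrow(ex))),
                     parent = tx$transcript_id, gene = tx$gene,
                     stringsAsFactors = FALSE)
    df[order(df$start), , drop = FALSE]
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "lofgof"
  S4Vectors::mcols(gr)$phase <- rows$phase
  S4Vectors::mcols(gr)$ID <- rows$id
  S4Vectors::mcols(gr)$Parent <- rows$parent
  S4Vectors::mcols(gr)$gene <- rows$gene
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' Expects `CDS` features carrying `Parent` (transcript id) and `gene`
#' attributes, as written by [write_transcripts_gff3()].
#'
#' @param path GFF3 file.
#' @return list of [transcript_model()] objects, in order of first appearance.
#' @export
read_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  gene <- as.character(S4Vectors::mcols(gr)$gene)
  ids <- unique(parent)
  lapply(ids, function(id) {
    sel <- parent == id
    transcript_model(
      transcript_id = id, gene = gene[sel][1],
      chrom = as.character(GenomicRanges::seqnames(gr)[sel][1]),
      strand = as.character(GenomicRanges::strand(gr)[sel][1]),
      exon_starts = GenomicRanges::start(gr)[sel],
      exon_ends = GenomicRanges::end(gr)[sel]
    )
  })
}

#' Read/write transcripts in a CCDS-like TSV dialect
#'
#' Columns: `transcript_id`, `gene`, `chrom`, `strand`, `exons` where `exons`
#' is a comma-separated list of `start-end` intervals (1-based inclusive, in
#' transcription order).
#'
#' @param path TSV file.
#' @return for the reader, a list of [transcript_model()] objects.
#' @export
read_transcripts_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    iv <- strsplit(strsplit(df$exons[i], ",")[[1]], "-")
    transcript_model(df$transcript_id[i], df$gene[i], df$chrom[i],
                     df$strand[i],
                     exon_starts = as.integer(vapply(iv, `[`, "", 1)),
                     exon_ends = as.integer(vapply(iv, `[`, "", 2)))
  })
}

#' @rdname read_transcripts_tsv
#' @param transcripts list of [transcript_model()] objects.
#' @export
write_transcripts_tsv <- function(transcripts, path) {
  df <- do.call(rbind, lapply(transcripts, function(tx) {
    data.frame(
      transcript_id = tx$transcript_id, gene = tx$gene, chrom = tx$chrom,
      strand = tx$strand,
      exons = paste(sprintf("%d-%d", tx$coding_exons$start,
                            tx$coding_exons$end), collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
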