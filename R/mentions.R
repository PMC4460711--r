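## Deterministic mention grammar. Three-letter codes are listed before
## one-letter codes inside each residue group so the longer spelling wins.
.AA3_REF <- "Ala|Arg|Asn|Asp|Cys|Gln|Glu|Gly|His|Ile|Leu|Lys|Met|Phe|Pro|Ser|Thr|Trp|Tyr|Val"
.AA1 <- "[ARNDCQEGHILKMFPSTWYV]"
.B_L <- "(?<![A-Za-z0-9])" # left boundary
.B_R <- "(?![A-Za-z0-9])"  # right boundary

.grammar <- function() {
  ref <- sprintf("((?:%s)|%s)", .AA3_REF, .AA1)
  alt <- sprintf("((?:%s|Ter)|[ARNDCQEGHILKMFPSTWYVX*])", .AA3_REF)
  list(
    list(kind = "indel",
         pattern = "c\\.(\\d+)(?:_(\\d+))?delins([ACGT]+)"),
    list(kind = "insertion",
         pattern = "c\\.(\\d+)_(\\d+)ins([ACGT]+)"),
    list(kind = "deletion_nt",
         pattern = "c\\.(\\d+)(?:_(\\d+))?del(?!ins)([ACGT]*)"),
    list(kind = "duplication_nt",
         pattern = "c\\.(\\d+)(?:_(\\d+))?dup"),
    list(kind = "substitution_nucleotide",
         pattern = "c\\.(\\d+)([ACGT])>([ACGT])"),
    list(kind = "frameshift",
         pattern = paste0(.B_L, ref, "(\\d+)fs", .B_R)),
    list(kind = "deletion_aa",
         pattern = paste0(.B_L, ref, "(\\d+)del(?!ins)", .B_R)),
    list(kind = "duplication_aa",
         pattern = paste0(.B_L, ref, "(\\d+)dup", .B_R)),
    list(kind = "substitution_protein",
         pattern = paste0(.B_L, ref, "(\\d+)", alt, .B_R))
  )
}

.safe_int <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  ifelse(is.na(v) | v > .Machine$integer.max, NA_integer_, as.integer(v))
}

#' Extract mutation mentions from a sentence
#'
#' Scans a sentence with a deterministic regular-expression grammar for
#' mutation mentions: protein substitutions in one-letter (`R132H`,
#' `R132*`/`R132X`) or three-letter (`Arg132His`, `Trp26Ter`) notation, cDNA
#' substitutions (`c.76A>T`), deletions (`c.123delA`, `Leu45del`),
#' insertions and deletion-insertions (`c.12_13insCA`, `c.12_13delinsTT`),
#' duplications (`c.10_12dup`, `Ala45dup`) and frameshifts (`L99fs`).
#' Matches are taken left to right, longest match first, without overlap.
#' Residue codes are normalised to one-letter form and `Ter`/`X`/`*` to the
#' stop symbol `*`; a protein substitution to a stop is reported with kind
#' `nonsense`. Numeric fields that overflow the integer range cause the
#' mention to be skipped with a warning.
#'
#' @param sentence a single sentence.
#' @param gene gene symbol associated with the sentence (from the input
#'   table; no gene-name recognition is attempted).
#' @param year publication year.
#' @param class_label `"LoF"` or `"GoF"`.
#' @return data frame with one row per mention: `gene`, `kind` (one of
#'   `substitution_protein`, `substitution_nucleotide`, `nonsense`,
#'   `deletion`, `insertion`, `indel`, `duplication`, `frameshift`),
#'   `ref_aa`, `alt_aa`, `aa_pos`, `nt_pos`, `nt_ref`, `nt_alt`, `year`,
#'   `class_label`, `start`, `end`, `span`.
#' @export
extract_mentions <- function(sentence, gene, year = NA_integer_,
                             class_label = NA_character_) {
  stopifnot(length(sentence) == 1L, nzchar(sentence))
  cands <- list()
  for (pi in seq_along(.grammar())) {
    rule <- .grammar()[[pi]]
    m <- gregexec(rule$pattern, sentence, perl = TRUE)[[1]]
    if (length(m) == 1L && m[1] == -1L) next
    groups <- regmatches(sentence, gregexec(rule$pattern, sentence,
                                            perl = TRUE))[[1]]
    starts <- m[1, ]
    lens <- attr(m, "match.length")[1, ]
    for (j in seq_along(starts)) {
      cands[[length(cands) + 1L]] <- list(
        kind = rule$kind, priority = pi, start = starts[j],
        len = lens[j], groups = groups[-1, j]
      )
    }
  }
  if (!length(cands)) return(.empty_mentions())
  ord <- order(vapply(cands, `[[`, 1, "start"),
               -vapply(cands, `[[`, 1, "len"),
               vapply(cands, `[[`, 1, "priority"))
  cands <- cands[ord]
  rows <- list()
  last_end <- 0L
  for (cd in cands) {
    if (cd$start <= last_end) next
    row <- .normalize_candidate(cd, sentence, gene, year, class_label)
    if (is.null(row)) next # skipped (e.g. numeric overflow), warned
    last_end <- cd$start + cd$len - 1L
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(.empty_mentions())
  do.call(rbind, rows)
}

.empty_mentions <- function() {
  data.frame(gene = character(0), kind = character(0),
             ref_aa = character(0), alt_aa = character(0),
             aa_pos = integer(0), nt_pos = integer(0),
             nt_ref = character(0), nt_alt = character(0),
             year = integer(0), class_label = character(0),
             start = integer(0), end = integer(0), span = character(0),
             stringsAsFactors = FALSE)
}

.normalize_candidate <- function(cd, sentence, gene, year, class_label) {
  span <- substr(sentence, cd$start, cd$start + cd$len - 1L)
  g <- cd$groups
  base <- data.frame(gene = gene, kind = cd$kind,
                     ref_aa = NA_character_, alt_aa = NA_character_,
                     aa_pos = NA_integer_, nt_pos = NA_integer_,
                     nt_ref = NA_character_, nt_alt = NA_character_,
                     year = year, class_label = class_label,
                     start = cd$start, end = cd$start + cd$len - 1L,
                     span = span, stringsAsFactors = FALSE)
  overflow <- function(what) {
    warning("skipping mention '", span, "': unparseable ", what,
            " (integer overflow)", call. = FALSE)
    NULL
  }
  if (cd$kind == "substitution_protein") {
    pos <- .safe_int(g[2])
    if (is.na(pos)) return(overflow("residue position"))
    base$ref_aa <- normalize_aa(g[1])
    base$alt_aa <- normalize_aa(g[3])
    base$aa_pos <- pos
    if (base$alt_aa == "*") base$kind <- "nonsense"
  } else if (cd$kind == "substitution_nucleotide") {
    pos <- .safe_int(g[1])
    if (is.na(pos)) return(overflow("nucleotide position"))
    base$nt_pos <- pos
    base$nt_ref <- g[2]
    base$nt_alt <- g[3]
  } else if (cd$kind %in% c("frameshift", "deletion_aa", "duplication_aa")) {
    pos <- .safe_int(g[2])
    if (is.na(pos)) return(overflow("residue position"))
    base$ref_aa <- normalize_aa(g[1])
    base$aa_pos <- pos
    base$kind <- sub("_aa$", "", cd$kind)
  } else { # nucleotide-anchored deletion / duplication / insertion / indel
    pos <- .safe_int(g[1])
    if (is.na(pos)) return(overflow("nucleotide position"))
    base$nt_pos <- pos
    base$kind <- sub("_nt$", "", cd$kind)
  }
  base
}

#' Extract mentions from a sentence table
#'
#' Applies [extract_mentions()] to each row of a sentence table (columns
#' `text`, `gene`, `year`, `class`), as read by [read_sentences_tsv()].
#'
#' @param sentences data frame of sentences.
#' @return combined mention data frame with a `sentence_index` column.
#' @export
extract_mentions_table <- function(sentences) {
  out <- lapply(seq_len(nrow(sentences)), function(i) {
    m <- extract_mentions(sentences$text[i], sentences$gene[i],
                          sentences$year[i], sentences$class[i])
    if (nrow(m)) m$sentence_index <- i
    m
  })
  out <- out[vapply(out, nrow, 1L) > 0L]
  if (!length(out)) {
    e <- .empty_mentions(); e$sentence_index <- integer(0); return(e)
  }
  do.call(rbind, out)
}

#' Map a mention kind to the six mutation subtypes
#'
#' Total over the kind enumeration: `nonsense` stays `nonsense`; `deletion`
#' stays `deletion`; `insertion` and `indel` map to `indel`; `duplication`
#' stays `duplication`; `frameshift` stays `frameshift`. Substitution kinds
#' (`substitution_protein`, `substitution_nucleotide`) return `missense`
#' provisionally; the definitive missense/nonsense/silent call is made
#' during variant mapping from the codon change.
#'
#' @param kind mention kind (vectorised).
#' @return subtype label(s).
#' @export
classify_mention_kind <- function(kind) {
  map <- c(substitution_protein = "missense",
           substitution_nucleotide = "missense",
           nonsense = "nonsense", deletion = "deletion",
           insertion = "indel", indel = "indel",
           duplication = "duplication", frameshift = "frameshift")
  out <- map[kind]
  if (anyNA(out)) stop("unknown mention kind: ",
                       paste(unique(kind[is.na(out)]), collapse = ", "))
  unname(out)
}

#' Read a sentences TSV (text, gene, year, class)
#' @param path TSV file.
#' @return data frame.
#' @export
read_sentences_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a mentions table as TSV
#' @param mentions mention data frame.
#' @param path output file.
#' @param header optional comment lines (without `#`).
#' @export
write_mentions_tsv <- function(mentions, path, header = character(0)) {
  .write_tsv_with_header(mentions, path, header)
}

.write_tsv_with_header <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
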