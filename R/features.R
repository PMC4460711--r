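#' Bin an impact score into a grade
#'
#' Four grades by three ascending cut points: score below the first
#' threshold is `neutral`, then `low`, `medium`, and `high` (each bin closed
#' on the left, so a score exactly at a threshold takes the higher grade).
#' The defaults (0.8, 1.9, 3.5) follow the published functional-impact-score
#' convention.
#'
#' @param score numeric vector of impact scores (finite).
#' @param thresholds three strictly ascending cut points.
#' @return character vector of grades.
#' @examples
#' impact_grade(c(-1.505, 1.78, 3.62))
#' @export
impact_grade <- function(score, thresholds = c(0.8, 1.9, 3.5)) {
  stopifnot(length(thresholds) == 3L,
            !is.unsorted(thresholds, strictly = TRUE))
  if (any(!is.finite(score))) stop("impact_grade(): non-finite score")
  cut_levels <- c("neutral", "low", "medium", "high")
  cut_levels[findInterval(score, thresholds) + 1L]
}

#' Conservation-based impact score from an alignment column
#'
#' A simple evolutionary-conservation score for a residue substitution: the
#' log2 ratio of the (pseudocounted) reference and alternate residue counts
#' in an alignment column, \eqn{\log_2((f_{ref}+p)/(f_{alt}+p))}. Positive
#' when the reference residue is better conserved than the alternate;
#' antisymmetric under swapping the two residues.
#'
#' @param column_counts named numeric vector of residue counts for the
#'   alignment column (total > 0); absent residues count 0.
#' @param ref_aa,alt_aa one-letter residue codes; must differ.
#' @param pseudocount positive pseudocount.
#' @return numeric score.
#' @export
conservation_score <- function(column_counts, ref_aa, alt_aa,
                               pseudocount = 1) {
  if (ref_aa == alt_aa) {
    stop("conservation_score(): reference and alternate residues are ",
         "identical (silent change has no score)")
  }
  stopifnot(pseudocount > 0, sum(column_counts) > 0)
  f <- function(aa) if (aa %in% names(column_counts)) column_counts[[aa]] else 0
  log2((f(ref_aa) + pseudocount) / (f(alt_aa) + pseudocount))
}

#' Assemble the six-feature table
#'
#' Builds, for each retained variant, the six-feature record used throughout
#' the analysis: reference allele (`REF`), substituted allele (`SUB`),
#' mutation type (`TYPE`), impact score (`SCORE`) with its grade, subcellular
#' location (`SL`), protein domain (`PD`), and the class label. Alleles are
#' reported on the coding strand by default (directional pairs such as
#' A\eqn{\to}G and T\eqn{\to}C are strand-dependent; the reading frame lives
#' on the coding strand), or on the genomic plus strand with
#' `allele_strand = "plus"`. Only single-edit substitutions carry alleles.
#' The location is looked up by gene (`unknown` when the gene is absent,
#' with a warning); the domain is the annotated interval containing the
#' residue position (`none` when no interval overlaps; the first interval by
#' start when several do). Scores are looked up by (gene, residue position,
#' reference residue, alternate residue) — by (gene, residue position,
#' subtype) for non-substitutions — and are `NA` when absent; records
#' without a score stay in the table (they are excluded later from
#' classification but kept for subtype/allele analyses).
#'
#' @param variants retained variants from [apply_filters()].
#' @param location_table data frame `gene`, `location`.
#' @param domain_table data frame `gene`, `domain`, `aa_start`, `aa_end`
#'   (1-based inclusive residue intervals).
#' @param scores optional score table: `gene`, `aa_pos`, `ref_aa`, `alt_aa`,
#'   optionally `subtype`, and `score`.
#' @param thresholds grade cut points for [impact_grade()].
#' @param allele_strand `"coding"` (default) or `"plus"`.
#' @return data frame with columns `REF`, `SUB`, `TYPE`, `SCORE`, `GRADE`,
#'   `SL`, `PD`, `Class` (plus `gene`, `aa_pos` for traceability).
#' @export
assemble_features <- function(variants, location_table, domain_table,
                              scores = NULL,
                              thresholds = c(0.8, 1.9, 3.5),
                              allele_strand = c("coding", "plus")) {
  allele_strand <- match.arg(allele_strand)
  n <- nrow(variants)
  loc <- location_table$location[match(variants$gene, location_table$gene)]
  if (anyNA(loc)) {
    warning("gene(s) absent from the location table: ",
            paste(unique(variants$gene[is.na(loc)]), collapse = ", "),
            "; location set to 'unknown'")
    loc[is.na(loc)] <- "unknown"
  }
  pd <- vapply(seq_len(n), function(i) {
    .domain_lookup(domain_table, variants$gene[i], variants$aa_pos[i])
  }, "")
  sc <- rep(NA_real_, n)
  if (!is.null(scores)) {
    is_sub <- !is.na(variants$alt_aa)
    key_var <- ifelse(is_sub,
                      paste(variants$gene, variants$aa_pos, variants$ref_aa,
                            variants$alt_aa, sep = "|"),
                      paste(variants$gene, variants$aa_pos, variants$subtype,
                            sep = "|"))
    sub_tab <- !is.na(scores$alt_aa)
    key_tab <- ifelse(sub_tab,
                      paste(scores$gene, scores$aa_pos, scores$ref_aa,
                            scores$alt_aa, sep = "|"),
                      paste(scores$gene, scores$aa_pos,
                            if (!is.null(scores$subtype)) scores$subtype
                            else NA, sep = "|"))
    sc <- scores$score[match(key_var, key_tab)]
  }
  single <- !is.na(variants$n_edits) & variants$n_edits == 1L
  if (allele_strand == "coding") {
    ref <- ifelse(single, variants$ref_base_coding, NA_character_)
    sub <- ifelse(single, variants$alt_base_coding, NA_character_)
  } else {
    ref <- ifelse(single, variants$ref_base_genome, NA_character_)
    sub <- ifelse(single, variants$alt_base_genome, NA_character_)
  }
  grade <- rep(NA_character_, n)
  grade[!is.na(sc)] <- impact_grade(sc[!is.na(sc)], thresholds)
  data.frame(
    REF = ref, SUB = sub, TYPE = variants$subtype, SCORE = sc,
    GRADE = grade, SL = loc, PD = pd, Class = variants$class_label,
    gene = variants$gene, aa_pos = variants$aa_pos,
    stringsAsFactors = FALSE
  )
}

## First domain (by interval start) whose residue interval contains aa_pos.
.domain_lookup <- function(domain_table, gene, aa_pos) {
  if (is.na(aa_pos)) return("none")
  rows <- domain_table[domain_table$gene == gene, , drop = FALSE]
  hit <- rows[rows$aa_start <= aa_pos & aa_pos <= rows$aa_end, , drop = FALSE]
  if (!nrow(hit)) return("none")
  hit$domain[order(hit$aa_start)][1]
}

#' Write the feature table TSV
#'
#' Columns in the canonical order `REF`, `SUB`, `TYPE`, `SCORE`, `SL`, `PD`,
#' `Class`.
#'
#' @param features feature data frame from [assemble_features()].
#' @param path output file.
#' @param header optional comment lines.
#' @export
write_feature_table <- function(features, path, header = character(0)) {
  .write_tsv_with_header(
    features[, c("REF", "SUB", "TYPE", "SCORE", "SL", "PD", "Class")],
    path, header
  )
}

#' Read a feature table TSV
#' @param path TSV file.
#' @return data frame.
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
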