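#' Pipeline run configuration
#'
#' Collects input paths, filter and feature parameters, enrichment
#' backgrounds, the resampling plan and the master seed for a full run of
#' the extract \eqn{\to} map \eqn{\to} filter \eqn{\to} assemble \eqn{\to}
#' enrich \eqn{\to} classify pipeline.
#'
#' @param genome_fa FASTA of the reference (toy or real) genome.
#' @param transcripts_gff3 GFF3 of coding-exon models (or `transcripts_tsv`
#'   for the CCDS-like TSV dialect; exactly one must be given).
#' @param transcripts_tsv see above.
#' @param sentences_tsv sentences TSV (`text`, `gene`, `year`, `class`).
#' @param locations_tsv gene \eqn{\to} subcellular location TSV.
#' @param domains_tsv gene/domain/interval TSV.
#' @param scores_tsv optional precomputed impact-score TSV.
#' @param out_dir output directory.
#' @param min_year publication-year cutoff for [apply_filters()].
#' @param grade_thresholds cut points for [impact_grade()].
#' @param allele_strand `"coding"` or `"plus"` allele convention.
#' @param location_background,domain_background optional named background
#'   count vectors for the enrichment tests; when `NULL` the pooled
#'   annotation tables of the run are used as background. For real human
#'   data these should be genome-wide annotation histograms (on the order
#'   of 22119 subcellular-location and 55931 protein-domain annotations).
#' @param plan a [resampling_plan()]; `NULL` skips classification.
#' @param classifiers classifiers to evaluate.
#' @param seed master seed, recorded in every output header.
#' @return object of class `run_config`.
#' @export
run_config <- function(genome_fa, transcripts_gff3 = NULL,
                       transcripts_tsv = NULL, sentences_tsv,
                       locations_tsv, domains_tsv, scores_tsv = NULL,
                       out_dir, min_year = 2010L,
                       grade_thresholds = c(0.8, 1.9, 3.5),
                       allele_strand = c("coding", "plus"),
                       location_background = NULL,
                       domain_background = NULL,
                       plan = resampling_plan(),
                       classifiers = c("logistic", "random_forest", "svm"),
                       seed = 1L) {
  allele_strand <- match.arg(allele_strand)
  if (is.null(transcripts_gff3) == is.null(transcripts_tsv)) {
    stop("give exactly one of transcripts_gff3 / transcripts_tsv")
  }
  inputs <- c(genome_fa, transcripts_gff3, transcripts_tsv, sentences_tsv,
              locations_tsv, domains_tsv, scores_tsv)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(
    genome_fa = genome_fa, transcripts_gff3 = transcripts_gff3,
    transcripts_tsv = transcripts_tsv, sentences_tsv = sentences_tsv,
    locations_tsv = locations_tsv, domains_tsv = domains_tsv,
    scores_tsv = scores_tsv, out_dir = out_dir,
    min_year = as.integer(min_year), grade_thresholds = grade_thresholds,
    allele_strand = allele_strand,
    location_background = location_background,
    domain_background = domain_background,
    plan = plan, classifiers = classifiers, seed = as.integer(seed)
  ), class = "run_config")
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(config[setdiff(names(config), "out_dir")], file = f)
  unname(tools::md5sum(f))
}

#' Gene-set overlap between the two classes
#'
#' @param lof_genes,gof_genes character vectors of gene symbols (upper-cased
#'   before comparison).
#' @return list with `n_lof`, `n_gof`, `overlap`.
#' @export
gene_overlap <- function(lof_genes, gof_genes) {
  a <- unique(toupper(lof_genes)); b <- unique(toupper(gof_genes))
  list(n_lof = length(a), n_gof = length(b),
       overlap = length(intersect(a, b)))
}

## Long-format category/class count tables mirroring the distribution
## figures (subtype, location, domain, grade, Ti/Tv).
.distribution_table <- function(features, column) {
  out <- list()
  for (cls in c("LoF", "GoF")) {
    v <- features[[column]][features$Class == cls]
    v <- v[!is.na(v)]
    if (!length(v)) next
    tab <- table(v)
    out[[cls]] <- data.frame(category = names(tab), class = cls,
                             count = as.integer(tab),
                             percent = round(100 * as.integer(tab) / sum(tab),
                                             2),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Run the full pipeline
#'
#' Executes mention extraction, variant mapping, filtering, feature
#' assembly, the enrichment and allele-pair tests, and (when a plan is
#' configured) the balanced-resampling classification, writing every stage
#' output under `config$out_dir` with a header recording the seed and a
#' hash of the configuration.
#'
#' @param config a [run_config()].
#' @return a funnel report (list): per-stage record counts (sentences,
#'   mentions, mapped, removed per filter rule, feature records, records
#'   entering classification), per-class gene counts with their overlap,
#'   and the classifier aggregates (when run), plus paths of the written
#'   outputs.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("seed=%d", config$seed),
           sprintf("config_md5=%s", .config_hash(config)))
  genome_set <- Biostrings::readDNAStringSet(config$genome_fa)
  genome <- stats::setNames(as.character(genome_set),
                            sub("\\s.*", "", names(genome_set)))
  transcripts <- if (!is.null(config$transcripts_gff3)) {
    read_transcripts_gff3(config$transcripts_gff3)
  } else {
    read_transcripts_tsv(config$transcripts_tsv)
  }
  sentences <- read_sentences_tsv(config$sentences_tsv)
  locations <- utils::read.delim(config$locations_tsv, comment.char = "#",
                                 stringsAsFactors = FALSE)
  domains <- utils::read.delim(config$domains_tsv, comment.char = "#",
                               stringsAsFactors = FALSE)
  scores <- if (!is.null(config$scores_tsv)) {
    utils::read.delim(config$scores_tsv, comment.char = "#",
                      stringsAsFactors = FALSE)
  } else NULL

  paths <- list()
  ## 1. extraction
  mentions <- extract_mentions_table(sentences)
  paths$mentions <- file.path(config$out_dir, "mentions.tsv")
  write_mentions_tsv(mentions, paths$mentions, hdr)

  if (!nrow(mentions)) {
    report <- list(sentences = nrow(sentences), mentions = 0L, mapped = 0L,
                   removed = c(year = 0L, reference = 0L, silent = 0L),
                   features = 0L, classified = 0L,
                   genes = list(n_lof = 0L, n_gof = 0L, overlap = 0L),
                   aggregates = NULL, paths = paths)
    return(report)
  }

  ## 2. mapping + 3. filters
  variants <- map_mentions(mentions, transcripts, genome)
  paths$variants_tsv <- file.path(config$out_dir, "variants.tsv")
  write_variants_tsv(variants, paths$variants_tsv, hdr)
  paths$variants_vcf <- file.path(config$out_dir, "variants.vcf")
  write_variants_vcf(variants, genome, paths$variants_vcf)
  filt <- apply_filters(variants, config$min_year)
  retained <- filt$retained

  ## 4. features
  features <- assemble_features(retained, locations, domains, scores,
                                thresholds = config$grade_thresholds,
                                allele_strand = config$allele_strand)
  paths$features <- file.path(config$out_dir, "features.tsv")
  write_feature_table(features, paths$features, hdr)
  for (col in c("TYPE", "SL", "PD", "GRADE")) {
    tab <- .distribution_table(features, col)
    p <- file.path(config$out_dir,
                   sprintf("distribution_%s.tsv", tolower(col)))
    .write_tsv_with_header(tab, p, hdr)
    paths[[paste0("distribution_", tolower(col))]] <- p
  }

  ## 5. enrichment + allele tests
  ## enrichment is gene-level: each mutated gene counts once per class, so
  ## the sample is a draw from the annotation background (one entry per
  ## gene, or per gene-domain annotation instance)
  loc_bg <- config$location_background
  if (is.null(loc_bg)) loc_bg <- table(locations$location)
  dom_bg <- config$domain_background
  if (is.null(dom_bg)) dom_bg <- table(domains$domain)
  for (cls in c("LoF", "GoF")) {
    fsub <- features[features$Class == cls, , drop = FALSE]
    if (!nrow(fsub)) next
    gene_loc <- fsub[!duplicated(fsub$gene), c("gene", "SL")]
    hit_dom <- fsub[fsub$PD != "none", c("gene", "PD")]
    hit_dom <- hit_dom[!duplicated(hit_dom), , drop = FALSE]
    enr_loc <- enrich_categories(table(gene_loc$SL), loc_bg, bh = TRUE)
    enr_dom <- if (nrow(hit_dom)) {
      enrich_categories(table(hit_dom$PD), dom_bg, bh = TRUE)
    } else NULL
    p1 <- file.path(config$out_dir,
                    sprintf("enrichment_location_%s.tsv", tolower(cls)))
    .write_tsv_with_header(enr_loc, p1, hdr)
    paths[[sprintf("enrichment_location_%s", tolower(cls))]] <- p1
    if (!is.null(enr_dom)) {
      p2 <- file.path(config$out_dir,
                      sprintf("enrichment_domain_%s.tsv", tolower(cls)))
      .write_tsv_with_header(enr_dom, p2, hdr)
      paths[[sprintf("enrichment_domain_%s", tolower(cls))]] <- p2
    }
  }
  allele <- allele_pair_tests(features, verbose = TRUE)
  paths$allele_tests <- file.path(config$out_dir, "allele_tests.tsv")
  .write_tsv_with_header(allele, paths$allele_tests, hdr)

  ## 6. classification
  aggregates <- NULL
  n_classified <- 0L
  if (!is.null(config$plan)) {
    scored <- features[!is.na(features$SCORE), , drop = FALSE]
    n_classified <- nrow(scored)
    exp <- run_experiment(features, config$plan,
                          classifiers = config$classifiers)
    aggregates <- exp$aggregates
    paths$cv_folds <- file.path(config$out_dir, "cv_folds.tsv")
    .write_tsv_with_header(exp$fold_results, paths$cv_folds, hdr)
    paths$cv_aggregate <- file.path(config$out_dir, "cv_aggregate.tsv")
    .write_tsv_with_header(aggregates, paths$cv_aggregate, hdr)
  }

  genes <- gene_overlap(retained$gene[retained$class_label == "LoF"],
                        retained$gene[retained$class_label == "GoF"])
  report <- list(
    sentences = nrow(sentences),
    mentions = nrow(mentions),
    mapped = sum(variants$status == "ok"),
    removed = filt$report$removed,
    features = nrow(features),
    classified = n_classified,
    genes = genes,
    aggregates = aggregates,
    paths = paths
  )
  paths$funnel <- file.path(config$out_dir, "funnel.tsv")
  funnel_df <- data.frame(
    stage = c("sentences", "mentions", "mapped", "removed_year",
              "removed_reference", "removed_silent", "features",
              "classified", "genes_lof", "genes_gof", "genes_overlap"),
    count = c(report$sentences, report$mentions, report$mapped,
              report$removed[["year"]], report$removed[["reference"]],
              report$removed[["silent"]], report$features,
              report$classified, genes$n_lof, genes$n_gof, genes$overlap),
    stringsAsFactors = FALSE
  )
  .write_tsv_with_header(funnel_df, paths$funnel, hdr)
  report$paths <- paths
  report
}
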