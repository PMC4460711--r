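#' Simulation configuration for a synthetic LoF/GoF study
#'
#' Bundles every generative knob of the synthetic corpus: genome and
#' transcript geometry, per-class mutation-subtype mix, per-class ordered
#' allele-pair mix (missense/nonsense substitutions only), per-class
#' subcellular-location and protein-domain mixes, class-conditional Gaussian
#' impact scores, and the publication-year window. The class-conditional
#' probability vectors are the ground truth against which every downstream
#' stage is verified.
#'
#' @param seed integer master seed; the corpus is a deterministic function of
#'   the full configuration.
#' @param n_genes number of genes (each on its own toy chromosome). Must be at
#'   least `n_locations * n_domains` so that every location/domain
#'   combination is represented.
#' @param n_lof,n_gof number of mutations per class.
#' @param exons_per_transcript integer range `c(min, max)` of coding exons.
#' @param cds_length_range range of CDS lengths in codons (including the stop
#'   codon); minimum 3.
#' @param strand_fraction_minus proportion of minus-strand transcripts.
#' @param subtype_probs_per_class named list `LoF`/`GoF` of probability
#'   vectors over the six subtypes `missense`, `nonsense`, `deletion`,
#'   `indel`, `duplication`, `frameshift`.
#' @param allele_pair_probs_per_class named list of probability vectors over
#'   the 12 ordered pairs of [allele_pairs()]; applies to substitutions. For
#'   nonsense substitutions the vector is restricted (and renormalised) to
#'   pairs that can reach a stop codon by a single edit.
#' @param location_probs_per_class named list of probability vectors over the
#'   subcellular-location vocabulary (names define the vocabulary).
#' @param domain_probs_per_class named list of probability vectors over the
#'   protein-domain vocabulary; a `none` entry stands for positions outside
#'   any annotated domain.
#' @param impact_mean_sd_per_class named list of `c(mean, sd)` for the
#'   class-conditional Gaussian impact score.
#' @param year_range inclusive range of publication years.
#' @return object of class `simulation_config`.
#' @seealso [generate_corpus()], [bayes_accuracy()], [preset_config()]
#' @export
simulation_config <- function(seed = 1L,
                              n_genes = 40L,
                              n_lof = 258L,
                              n_gof = 129L,
                              exons_per_transcript = c(2L, 4L),
                              cds_length_range = c(60L, 120L),
                              strand_fraction_minus = 0.5,
                              subtype_probs_per_class = NULL,
                              allele_pair_probs_per_class = NULL,
                              location_probs_per_class = NULL,
                              domain_probs_per_class = NULL,
                              impact_mean_sd_per_class = NULL,
                              year_range = c(2011L, 2014L)) {
  if (is.null(subtype_probs_per_class)) {
    subtype_probs_per_class <- list(
      LoF = c(missense = 0.55, nonsense = 0.25, deletion = 0.08,
              indel = 0.04, duplication = 0.03, frameshift = 0.05),
      GoF = c(missense = 0.65, nonsense = 0.02, deletion = 0.15,
              indel = 0.06, duplication = 0.05, frameshift = 0.07)
    )
  }
  if (is.null(allele_pair_probs_per_class)) {
    allele_pair_probs_per_class <- list(
      LoF = c(AG = 0.17, GA = 0.14, CT = 0.17, TC = 0.12,
              AC = 0.04, AT = 0.06, CA = 0.04, CG = 0.04,
              GC = 0.05, GT = 0.07, TA = 0.05, TG = 0.05),
      GoF = c(AG = 0.09, GA = 0.11, CT = 0.09, TC = 0.11,
              AC = 0.07, AT = 0.08, CA = 0.07, CG = 0.06,
              GC = 0.07, GT = 0.09, TA = 0.08, TG = 0.08)
    )
  }
  if (is.null(location_probs_per_class)) {
    location_probs_per_class <- list(
      LoF = c(Nucleus = 0.30, `Cell membrane` = 0.15, Cytoplasm = 0.25,
              Membrane = 0.15, Secreted = 0.15),
      GoF = c(Nucleus = 0.15, `Cell membrane` = 0.35, Cytoplasm = 0.15,
              Membrane = 0.25, Secreted = 0.10)
    )
  }
  if (is.null(domain_probs_per_class)) {
    domain_probs_per_class <- list(
      LoF = c(Kinase = 0.30, Cadherin = 0.10, SelR = 0.20,
              ASC = 0.15, none = 0.25),
      GoF = c(Kinase = 0.10, Cadherin = 0.30, SelR = 0.10,
              ASC = 0.20, none = 0.30)
    )
  }
  if (is.null(impact_mean_sd_per_class)) {
    impact_mean_sd_per_class <- list(LoF = c(mean = 2.2, sd = 1.2),
                                     GoF = c(mean = 1.2, sd = 1.2))
  }
  cfg <- structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    n_lof = as.integer(n_lof), n_gof = as.integer(n_gof),
    exons_per_transcript = as.integer(exons_per_transcript),
    cds_length_range = as.integer(cds_length_range),
    strand_fraction_minus = strand_fraction_minus,
    subtype_probs_per_class = subtype_probs_per_class,
    allele_pair_probs_per_class = allele_pair_probs_per_class,
    location_probs_per_class = location_probs_per_class,
    domain_probs_per_class = domain_probs_per_class,
    impact_mean_sd_per_class = impact_mean_sd_per_class,
    year_range = as.integer(year_range)
  ), class = "simulation_config")
  .validate_config(cfg)
  cfg
}

.SUBTYPES <- c("missense", "nonsense", "deletion", "indel",
               "duplication", "frameshift")

.validate_config <- function(cfg) {
  stopifnot(cfg$n_lof >= 1L, cfg$n_gof >= 1L, cfg$n_genes >= 1L,
            cfg$cds_length_range[1] >= 3L,
            cfg$strand_fraction_minus >= 0, cfg$strand_fraction_minus <= 1,
            diff(cfg$exons_per_transcript) >= 0,
            diff(cfg$cds_length_range) >= 0,
            diff(cfg$year_range) >= 0)
  check_probs <- function(p, what, vocab = NULL) {
    for (cls in c("LoF", "GoF")) {
      v <- p[[cls]]
      if (abs(sum(v) - 1) > 1e-9) {
        stop(what, " probabilities for ", cls, " sum to ", sum(v), ", not 1")
      }
      if (any(v < 0)) stop(what, " probabilities for ", cls, " negative")
      if (!is.null(vocab) && !setequal(names(v), vocab)) {
        stop(what, " probabilities for ", cls, " must be named over {",
             paste(vocab, collapse = ", "), "}")
      }
    }
  }
  check_probs(cfg$subtype_probs_per_class, "subtype", .SUBTYPES)
  check_probs(cfg$allele_pair_probs_per_class, "allele-pair", .ALLELE_PAIRS)
  check_probs(cfg$location_probs_per_class, "location")
  check_probs(cfg$domain_probs_per_class, "domain")
  if (!identical(names(cfg$location_probs_per_class$LoF),
                 names(cfg$location_probs_per_class$GoF)) ||
      !identical(names(cfg$domain_probs_per_class$LoF),
                 names(cfg$domain_probs_per_class$GoF))) {
    stop("location/domain vocabularies must match across classes")
  }
  for (cls in c("LoF", "GoF")) {
    ms <- cfg$impact_mean_sd_per_class[[cls]]
    if (!all(is.finite(ms)) || ms[["sd"]] <= 0) {
      stop("impact mean/sd for ", cls, " invalid")
    }
  }
  n_loc <- length(cfg$location_probs_per_class$LoF)
  n_dom <- sum(names(cfg$domain_probs_per_class$LoF) != "none")
  if (cfg$n_genes < n_loc * n_dom) {
    stop("n_genes must be >= ", n_loc * n_dom,
         " to cover every location/domain combination")
  }
  invisible(cfg)
}

#' Preset simulation configurations
#'
#' Three ready-made study conditions: `"paperlike"` (the default of
#' [simulation_config()]: 258 LoF + 129 GoF mutations with moderate,
#' realistic class differences in subtype mix, transition/transversion
#' balance, locations, domains and impact scores), `"strong"` (400 + 400
#' mutations with large class separations, used to compare classifiers
#' against the closed-form Bayes accuracy), and `"null"` (300 + 300 with
#' identical class-conditional distributions, so no classifier can beat
#' chance).
#'
#' @param preset one of `"paperlike"`, `"strong"`, `"null"`.
#' @param seed master seed.
#' @return a [simulation_config()].
#' @export
preset_config <- function(preset = c("paperlike", "strong", "null"),
                          seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paperlike") return(simulation_config(seed = seed))
  if (preset == "strong") {
    return(simulation_config(
      seed = seed, n_lof = 400L, n_gof = 400L,
      subtype_probs_per_class = list(
        LoF = c(missense = 0.60, nonsense = 0.30, deletion = 0.04,
                indel = 0.02, duplication = 0.02, frameshift = 0.02),
        GoF = c(missense = 0.60, nonsense = 0.01, deletion = 0.25,
                indel = 0.06, duplication = 0.04, frameshift = 0.04)
      ),
      allele_pair_probs_per_class = list(
        LoF = c(AG = 0.25, GA = 0.20, CT = 0.18, TC = 0.12,
                AC = 0.03, AT = 0.03, CA = 0.03, CG = 0.03,
                GC = 0.03, GT = 0.04, TA = 0.03, TG = 0.03),
        GoF = c(AG = 0.07, GA = 0.06, CT = 0.06, TC = 0.06,
                AC = 0.09, AT = 0.10, CA = 0.09, CG = 0.09,
                GC = 0.09, GT = 0.10, TA = 0.10, TG = 0.09)
      ),
      location_probs_per_class = list(
        LoF = c(Nucleus = 0.55, `Cell membrane` = 0.10, Cytoplasm = 0.20,
                Membrane = 0.10, Secreted = 0.05),
        GoF = c(Nucleus = 0.10, `Cell membrane` = 0.50, Cytoplasm = 0.10,
                Membrane = 0.20, Secreted = 0.10)
      ),
      domain_probs_per_class = list(
        LoF = c(Kinase = 0.50, Cadherin = 0.05, SelR = 0.20,
                ASC = 0.10, none = 0.15),
        GoF = c(Kinase = 0.05, Cadherin = 0.45, SelR = 0.10,
                ASC = 0.15, none = 0.25)
      ),
      impact_mean_sd_per_class = list(LoF = c(mean = 2.5, sd = 1.2),
                                      GoF = c(mean = 1.0, sd = 1.2))
    ))
  }
  ## null: GoF distributions copied from LoF, equal class sizes
  base <- simulation_config(seed = seed)
  simulation_config(
    seed = seed, n_lof = 300L, n_gof = 300L,
    subtype_probs_per_class = list(LoF = base$subtype_probs_per_class$LoF,
                                   GoF = base$subtype_probs_per_class$LoF),
    allele_pair_probs_per_class = list(
      LoF = base$allele_pair_probs_per_class$LoF,
      GoF = base$allele_pair_probs_per_class$LoF),
    location_probs_per_class = list(LoF = base$location_probs_per_class$LoF,
                                    GoF = base$location_probs_per_class$LoF),
    domain_probs_per_class = list(LoF = base$domain_probs_per_class$LoF,
                                  GoF = base$domain_probs_per_class$LoF),
    impact_mean_sd_per_class = list(LoF = c(mean = 1.5, sd = 1.2),
                                    GoF = c(mean = 1.5, sd = 1.2))
  )
}

## Ordered pairs (ref->alt, coding strand) for which at least one sense codon
## reaches a stop codon by a single edit. Enumerated from the genetic code.
.nonsense_reachable_pairs <- function() {
  if (is.null(.CODE)) .CODE <<- .genetic_code()
  sense <- names(.CODE)[.CODE != "*"]
  bases <- c("A", "C", "G", "T")
  found <- character(0)
  for (cod in sense) {
    for (i in 1:3) {
      r <- substr(cod, i, i)
      for (b in setdiff(bases, r)) {
        alt <- cod
        substr(alt, i, i) <- b
        if (.CODE[[alt]] == "*") found <- c(found, paste0(r, b))
      }
    }
  }
  intersect(.ALLELE_PAIRS, unique(found))
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Random CDS of n_codons codons: ATG + sense codons + one stop.
.random_cds <- function(n_codons) {
  if (is.null(.CODE)) .CODE <<- .genetic_code()
  sense <- names(.CODE)[.CODE != "*"]
  stops <- names(.CODE)[.CODE == "*"]
  mid <- if (n_codons > 2L) {
    sample(setdiff(sense, "ATG"), n_codons - 2L, replace = TRUE)
  } else character(0)
  paste(c("ATG", mid, stops[sample.int(length(stops), 1L)]), collapse = "")
}

#' Generate a synthetic LoF/GoF corpus
#'
#' Builds a complete toy study with known ground truth: one toy chromosome
#' per gene carrying a multi-exon transcript (plus or minus strand), a
#' subcellular-location and protein-domain annotation per gene, and
#' class-conditional mutations rendered as literature-like sentences in
#' rotating notations (one-letter `R132H`, three-letter `Arg132His` /
#' `Trp26Ter`, and cDNA `c.76A>T`; deletions, insertion/deletions,
#' duplications and frameshifts use `del`/`delins`/`ins`/`dup`/`fs`
#' notation).
#'
#' Substitution sites are chosen so that the sampled coding-strand allele
#' pair is achievable by a single codon edit producing the intended subtype;
#' when a sampled gene region offers no such site, the gene and then the
#' allele pair are resampled up to a bounded number of attempts.
#'
#' @param config a [simulation_config()].
#' @return an object of class `synthetic_corpus`: a list with `genome`
#'   (named character vector of chromosomes), `transcripts` (list of
#'   [transcript_model()], named by gene), `location_table`, `domain_table`,
#'   `sentences`, `truth` (data frames), `scores` (deduplicated per-variant
#'   impact-score table) and `config`.
#' @export
generate_corpus <- function(config) {
  .validate_config(config)
  set.seed(config$seed)

  locations <- names(config$location_probs_per_class$LoF)
  domains_all <- names(config$domain_probs_per_class$LoF)
  domains <- setdiff(domains_all, "none")
  has_none_domain <- "none" %in% domains_all

  ## --- genes, chromosomes, transcripts -------------------------------
  n_genes <- config$n_genes
  gene_ids <- sprintf("GENE%03d", seq_len(n_genes))
  combos <- expand.grid(location = locations, domain = domains,
                        stringsAsFactors = FALSE)
  combo_idx <- ((seq_len(n_genes) - 1L) %% nrow(combos)) + 1L

  genome <- character(0)
  transcripts <- list()
  gene_meta <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    n_codons <- sample(config$cds_length_range[1]:config$cds_length_range[2], 1L)
    cds <- .random_cds(n_codons)
    len <- nchar(cds)
    k <- sample(config$exons_per_transcript[1]:config$exons_per_transcript[2], 1L)
    k <- min(k, len - 1L)
    cuts <- if (k > 1L) sort(sample(seq_len(len - 1L), k - 1L)) else integer(0)
    chunk_bounds <- cbind(c(1L, cuts + 1L), c(cuts, len))
    chunks <- substring(cds, chunk_bounds[, 1], chunk_bounds[, 2])
    strand <- if (stats::runif(1) < config$strand_fraction_minus) "-" else "+"
    introns <- if (k > 1L) sample(20:50, k - 1L, replace = TRUE) else integer(0)
    flank <- 25L
    ## left-to-right exon contents on the plus strand of the chromosome
    plus_chunks <- if (strand == "+") chunks else rev(reverse_complement(chunks))
    seqs <- character(2L * k + 1L)
    seqs[1] <- .random_dna(flank)
    starts <- integer(k); ends <- integer(k)
    cursor <- flank
    for (j in seq_len(k)) {
      starts[j] <- cursor + 1L
      ends[j] <- cursor + nchar(plus_chunks[j])
      seqs[2L * j] <- plus_chunks[j]
      cursor <- ends[j]
      gap <- if (j < k) introns[j] else flank
      seqs[2L * j + 1L] <- .random_dna(gap)
      cursor <- cursor + gap
    }
    chrom_name <- sprintf("chr%03d", i)
    genome[chrom_name] <- paste(seqs, collapse = "")
    ## transcription order: + ascending, - descending
    ord <- if (strand == "+") seq_len(k) else rev(seq_len(k))
    tx <- transcript_model(sprintf("TX%03d", i), gene_ids[i], chrom_name,
                           strand, starts[ord], ends[ord])
    transcripts[[gene_ids[i]]] <- tx
    n_aa <- n_codons - 1L # residues, excluding the stop
    dom_start <- max(2L, as.integer(ceiling(n_aa * 0.3)))
    dom_end <- max(dom_start, as.integer(floor(n_aa * 0.7)))
    gene_meta[[i]] <- list(
      gene = gene_ids[i], cds = cds, n_aa = n_aa,
      location = combos$location[combo_idx[i]],
      domain = combos$domain[combo_idx[i]],
      dom_start = dom_start, dom_end = dom_end
    )
  }
  names(gene_meta) <- gene_ids
  meta_loc <- vapply(gene_meta, `[[`, "", "location")
  meta_dom <- vapply(gene_meta, `[[`, "", "domain")

  location_table <- data.frame(gene = gene_ids, location = unname(meta_loc),
                               stringsAsFactors = FALSE)
  domain_table <- data.frame(
    gene = gene_ids, domain = unname(meta_dom),
    aa_start = vapply(gene_meta, function(m) m$dom_start, 1L),
    aa_end = vapply(gene_meta, function(m) m$dom_end, 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )

  ## --- mutations ------------------------------------------------------
  nonsense_pairs <- .nonsense_reachable_pairs()
  classes <- c(rep("LoF", config$n_lof), rep("GoF", config$n_gof))
  n_mut <- length(classes)
  truth <- vector("list", n_mut)
  sentences <- vector("list", n_mut)
  style_counter <- c(LoF = 0L, GoF = 0L)

  region_positions <- function(m, in_domain) {
    if (in_domain) m$dom_start:m$dom_end
    else setdiff(2:m$n_aa, m$dom_start:m$dom_end)
  }

  for (idx in seq_len(n_mut)) {
    cls <- classes[idx]
    subtype <- sample(.SUBTYPES, 1L,
                      prob = config$subtype_probs_per_class[[cls]])
    loc <- sample(locations, 1L,
                  prob = config$location_probs_per_class[[cls]])
    dom <- sample(domains_all, 1L,
                  prob = config$domain_probs_per_class[[cls]])
    pool <- if (dom == "none") gene_ids[meta_loc == loc]
            else gene_ids[meta_loc == loc & meta_dom == dom]
    if (!length(pool)) stop("no gene available for location ", loc,
                            " and domain ", dom)
    in_domain <- dom != "none"

    if (subtype %in% c("missense", "nonsense")) {
      pair_p <- config$allele_pair_probs_per_class[[cls]]
      if (subtype == "nonsense") {
        pair_p <- pair_p[nonsense_pairs]
        if (sum(pair_p) <= 0) {
          stop("nonsense requested but all stop-reachable allele pairs have ",
               "probability 0 for class ", cls)
        }
        pair_p <- pair_p / sum(pair_p)
      }
      hit <- NULL
      for (attempt in 1:60) {
        pair <- names(pair_p)[sample.int(length(pair_p), 1L, prob = pair_p)]
        r <- substr(pair, 1, 1); a <- substr(pair, 2, 2)
        g <- pool[sample.int(length(pool), 1L)]
        m <- gene_meta[[g]]
        aas <- region_positions(m, in_domain)
        offs <- as.vector(outer(-2:0, 3L * aas, `+`)) # CDS offsets of region codons
        offs <- offs[substring(m$cds, offs, offs) == r]
        if (length(offs)) {
          ref_codon_of <- function(o) {
            s <- 3L * ((o - 1L) %/% 3L) + 1L
            substring(m$cds, s, s + 2L)
          }
          ## a site qualifies when the edit yields the intended subtype AND
          ## the edited codon is the one back-mapping would reconstruct from
          ## the residue change (minimal Hamming distance, lexicographic
          ## tie-break), so protein-notation mentions round-trip exactly
          ok <- vapply(offs, function(o) {
            s <- 3L * ((o - 1L) %/% 3L) + 1L
            rc <- substring(m$cds, s, s + 2L)
            ac <- rc; substr(ac, o - s + 1L, o - s + 1L) <- a
            ref_aa <- translate_codon(rc); alt_aa <- translate_codon(ac)
            good <- if (subtype == "nonsense") alt_aa == "*" && ref_aa != "*"
                    else alt_aa != ref_aa && alt_aa != "*" && ref_aa != "*"
            if (!good) return(FALSE)
            cands <- codons_for_aa(alt_aa)
            d <- vapply(cands, function(cc) .hamming(rc, cc), 1)
            identical(cands[which.min(d)], ac)
          }, TRUE)
          offs <- offs[ok]
          if (length(offs)) {
            o <- offs[sample.int(length(offs), 1L)]
            hit <- list(gene = g, cds_pos = o, pair = pair)
            break
          }
        }
      }
      if (is.null(hit)) {
        stop("could not place a ", subtype, " mutation for class ", cls,
             " with the configured allele-pair distribution after 60 attempts",
             " (location ", loc, ", domain ", dom, ")")
      }
      m <- gene_meta[[hit$gene]]
      o <- hit$cds_pos
      s <- 3L * ((o - 1L) %/% 3L) + 1L
      aa_pos <- (o - 1L) %/% 3L + 1L
      ref_codon <- substring(m$cds, s, s + 2L)
      alt_codon <- ref_codon
      substr(alt_codon, o - s + 1L, o - s + 1L) <- substr(hit$pair, 2, 2)
      rec <- list(gene = hit$gene, class = cls, subtype = subtype,
                  aa_pos = aa_pos,
                  ref_aa = translate_codon(ref_codon),
                  alt_aa = translate_codon(alt_codon),
                  ref_base = substr(hit$pair, 1, 1),
                  alt_base = substr(hit$pair, 2, 2),
                  cds_pos = o)
      style_counter[cls] <- style_counter[cls] + 1L
      style <- ((style_counter[cls] - 1L) %% 3L) + 1L
    } else {
      g <- pool[sample.int(length(pool), 1L)]
      m <- gene_meta[[g]]
      aas <- region_positions(m, in_domain)
      aa_pos <- aas[sample.int(length(aas), 1L)]
      s <- 3L * (aa_pos - 1L) + 1L
      rec <- list(gene = g, class = cls, subtype = subtype,
                  aa_pos = aa_pos,
                  ref_aa = translate_codon(substring(m$cds, s, s + 2L)),
                  alt_aa = NA_character_,
                  ref_base = NA_character_, alt_base = NA_character_,
                  cds_pos = s)
      style <- (idx %% 2L) + 1L
    }

    year <- sample(config$year_range[1]:config$year_range[2], 1L)
    ms <- config$impact_mean_sd_per_class[[cls]]
    score <- round(stats::rnorm(1L, ms[["mean"]], ms[["sd"]]), 3L)
    txt <- .render_sentence(rec, style, gene_meta[[rec$gene]])
    truth[[idx]] <- data.frame(
      gene = rec$gene,
      transcript_id = transcripts[[rec$gene]]$transcript_id,
      class = cls, subtype = subtype, aa_pos = rec$aa_pos,
      ref_aa = rec$ref_aa, alt_aa = rec$alt_aa,
      ref_base = rec$ref_base, alt_base = rec$alt_base,
      cds_pos = rec$cds_pos, year = year, score = score,
      location = meta_loc[[rec$gene]],
      domain = {
        md <- gene_meta[[rec$gene]]
        if (rec$aa_pos >= md$dom_start && rec$aa_pos <= md$dom_end)
          md$domain else "none"
      },
      style = style, stringsAsFactors = FALSE
    )
    sentences[[idx]] <- data.frame(text = txt, gene = rec$gene, year = year,
                                   class = cls, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  sentences <- do.call(rbind, sentences)

  ## deduplicated per-variant impact-score table: a real impact scorer is a
  ## deterministic function of the variant, so repeated draws of the same
  ## variant share the first sampled score
  key <- ifelse(is.na(truth$alt_aa),
                paste(truth$gene, truth$aa_pos, truth$subtype, sep = "|"),
                paste(truth$gene, truth$aa_pos, truth$ref_aa, truth$alt_aa,
                      sep = "|"))
  first <- !duplicated(key)
  score_map <- truth$score[first]
  names(score_map) <- key[first]
  truth$score <- unname(score_map[key])
  scores <- data.frame(
    gene = truth$gene[first], aa_pos = truth$aa_pos[first],
    ref_aa = truth$ref_aa[first], alt_aa = truth$alt_aa[first],
    subtype = truth$subtype[first], score = truth$score[first],
    stringsAsFactors = FALSE
  )

  structure(list(genome = genome, transcripts = transcripts,
                 location_table = location_table, domain_table = domain_table,
                 sentences = sentences, truth = truth, scores = scores,
                 config = config),
            class = "synthetic_corpus")
}

## Sentence templates are fixed so that the extractor contract is stable:
## each sentence contains exactly one parseable mention.
.render_sentence <- function(rec, style, meta) {
  g <- rec$gene
  if (rec$subtype %in% c("missense", "nonsense")) {
    alt1 <- rec$alt_aa # "*" for stop
    if (style == 1L) {
      sprintf("In %s, the %s%d%s mutation altered protein activity.",
              g, rec$ref_aa, rec$aa_pos, alt1)
    } else if (style == 2L) {
      sprintf("A %s%d%s substitution in %s was characterized in patients.",
              .AA1TO3[[rec$ref_aa]], rec$aa_pos, .AA1TO3[[alt1]], g)
    } else {
      sprintf("Tumor samples carrying c.%d%s>%s in %s were identified.",
              rec$cds_pos, rec$ref_base, rec$alt_base, g)
    }
  } else if (rec$subtype == "deletion") {
    if (style == 1L) {
      base <- substr(.codon_of_meta(meta, rec$aa_pos), 1, 1)
      sprintf("The c.%ddel%s variant of %s was reported in one family.",
              rec$cds_pos, base, g)
    } else {
      sprintf("The %s%ddel variant of %s was reported in one family.",
              .AA1TO3[[rec$ref_aa]], rec$aa_pos, g)
    }
  } else if (rec$subtype == "indel") {
    if (style == 1L) {
      sprintf("The c.%d_%ddelinsTT allele of %s emerged under treatment.",
              rec$cds_pos, rec$cds_pos + 1L, g)
    } else {
      sprintf("An insertion c.%d_%dinsCA in %s was found in the cohort.",
              rec$cds_pos, rec$cds_pos + 1L, g)
    }
  } else if (rec$subtype == "duplication") {
    if (style == 1L) {
      sprintf("The c.%d_%ddup variant in %s was described previously.",
              rec$cds_pos, rec$cds_pos + 2L, g)
    } else {
      sprintf("The %s%ddup variant in %s was described previously.",
              .AA1TO3[[rec$ref_aa]], rec$aa_pos, g)
    }
  } else { # frameshift
    if (style == 1L) {
      sprintf("The %s%dfs mutation in %s truncated the protein.",
              rec$ref_aa, rec$aa_pos, g)
    } else {
      sprintf("The %s%dfs mutation in %s truncated the protein.",
              .AA1TO3[[rec$ref_aa]], rec$aa_pos, g)
    }
  }
}

.codon_of_meta <- function(meta, aa_pos) {
  s <- 3L * (aa_pos - 1L) + 1L
  substring(meta$cds, s, s + 2L)
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_corpus> %d genes, %d sentences ",
                     "(%d LoF / %d GoF), seed %d\n"),
              length(x$transcripts), nrow(x$sentences),
              sum(x$truth$class == "LoF"), sum(x$truth$class == "GoF"),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits the genome as FASTA, transcripts as GFF3 (and the CCDS-like TSV
#' dialect), and the location, domain, sentence, truth and score tables as
#' TSV.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    gff3 = file.path(dir, "transcripts.gff3"),
    transcripts_tsv = file.path(dir, "transcripts.tsv"),
    locations = file.path(dir, "locations.tsv"),
    domains = file.path(dir, "domains.tsv"),
    sentences = file.path(dir, "sentences.tsv"),
    truth = file.path(dir, "truth.tsv"),
    scores = file.path(dir, "scores.tsv")
  )
  dna <- Biostrings::DNAStringSet(corpus$genome)
  Biostrings::writeXStringSet(dna, paths[["genome"]])
  write_transcripts_gff3(corpus$transcripts, paths[["gff3"]])
  write_transcripts_tsv(corpus$transcripts, paths[["transcripts_tsv"]])
  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(corpus$location_table, paths[["locations"]])
  wt(corpus$domain_table, paths[["domains"]])
  wt(corpus$sentences, paths[["sentences"]])
  wt(corpus$truth, paths[["truth"]])
  wt(corpus$scores, paths[["scores"]])
  invisible(paths)
}

#' Closed-form Bayes accuracy of a simulation configuration
#'
#' The best achievable classification accuracy under the generative model,
#' computed by exact summation over the finite feature space: mutation type
#' \eqn{\times} ordered allele pair (for substitutions; `none` otherwise)
#' \eqn{\times} impact grade (the Gaussian score discretized at the grade
#' thresholds) \eqn{\times} subcellular location \eqn{\times} protein
#' domain, with class priors proportional to `n_lof` and `n_gof`. For
#' nonsense substitutions the allele-pair distribution is restricted, as in
#' the generator, to pairs that can reach a stop codon by a single edit.
#'
#' @param config a [simulation_config()].
#' @param thresholds ascending grade cut points, as in [impact_grade()].
#' @return \eqn{\sum_x \max_c \pi_c\, p(x \mid c)}, a proportion.
#' @export
bayes_accuracy <- function(config, thresholds = c(0.8, 1.9, 3.5)) {
  .validate_config(config)
  stopifnot(length(thresholds) == 3L, !is.unsorted(thresholds, strictly = TRUE))
  priors <- c(LoF = config$n_lof, GoF = config$n_gof)
  priors <- priors / sum(priors)
  nonsense_pairs <- .nonsense_reachable_pairs()

  grade_probs <- function(cls) {
    ms <- config$impact_mean_sd_per_class[[cls]]
    cuts <- stats::pnorm(thresholds, ms[["mean"]], ms[["sd"]])
    c(neutral = cuts[1], low = cuts[2] - cuts[1],
      medium = cuts[3] - cuts[2], high = 1 - cuts[3])
  }
  type_pair_probs <- function(cls) {
    st <- config$subtype_probs_per_class[[cls]]
    pp <- config$allele_pair_probs_per_class[[cls]]
    ppn <- pp[nonsense_pairs]
    ppn <- if (sum(ppn) > 0) ppn / sum(ppn) else ppn
    out <- numeric(0)
    for (t in .SUBTYPES) {
      if (t == "missense") {
        v <- st[[t]] * pp
        names(v) <- paste("missense", names(pp), sep = "|")
      } else if (t == "nonsense") {
        v <- st[[t]] * ppn
        names(v) <- paste("nonsense", names(ppn), sep = "|")
      } else {
        v <- st[[t]]
        names(v) <- paste(t, "none", sep = "|")
      }
      out <- c(out, v)
    }
    out
  }
  cell_probs <- function(cls) {
    tp <- type_pair_probs(cls)
    gr <- grade_probs(cls)
    lo <- config$location_probs_per_class[[cls]]
    do <- config$domain_probs_per_class[[cls]]
    as.vector(outer(outer(outer(tp, gr), lo), do))
  }
  p_lof <- cell_probs("LoF")
  p_gof <- cell_probs("GoF")
  if (length(p_lof) != length(p_gof) || !all(is.finite(c(p_lof, p_gof)))) {
    stop("feature space is not finite/consistent across classes")
  }
  sum(pmax(priors[["LoF"]] * p_lof, priors[["GoF"]] * p_gof))
}
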