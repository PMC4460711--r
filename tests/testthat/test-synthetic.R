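test_that("corpus generation is deterministic given the seed", {
  cfg <- simulation_config(seed = 11, n_lof = 30L, n_gof = 20L)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a, b)
  # serialized corpora are byte-identical too
  fa <- tempfile(); fb <- tempfile()
  saveRDS(a, fa); saveRDS(b, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
  d <- generate_corpus(simulation_config(seed = 12, n_lof = 30L,
                                         n_gof = 20L))
  expect_false(identical(a$truth, d$truth))
})

test_that("degenerate subtype distribution is honoured exactly", {
  cfg <- simulation_config(
    seed = 3, n_lof = 40L, n_gof = 5L,
    subtype_probs_per_class = list(
      LoF = c(missense = 0, nonsense = 1, deletion = 0, indel = 0,
              duplication = 0, frameshift = 0),
      GoF = c(missense = 1, nonsense = 0, deletion = 0, indel = 0,
              duplication = 0, frameshift = 0)
    )
  )
  co <- generate_corpus(cfg)
  expect_true(all(co$truth$subtype[co$truth$class == "LoF"] == "nonsense"))
  expect_true(all(co$truth$alt_aa[co$truth$class == "LoF"] == "*"))
  expect_true(all(co$truth$subtype[co$truth$class == "GoF"] == "missense"))
})

test_that("configured allele-pair probability is recovered at n = 2000", {
  probs <- c(CT = 0.5, AG = 0.1, GA = 0.1, TC = 0.1,
             AC = 0.025, AT = 0.025, CA = 0.025, CG = 0.025,
             GC = 0.025, GT = 0.025, TA = 0.025, TG = 0.025)
  cfg <- simulation_config(
    seed = 21, n_lof = 2000L, n_gof = 2L,
    subtype_probs_per_class = list(
      LoF = c(missense = 1, nonsense = 0, deletion = 0, indel = 0,
              duplication = 0, frameshift = 0),
      GoF = c(missense = 1, nonsense = 0, deletion = 0, indel = 0,
              duplication = 0, frameshift = 0)
    ),
    allele_pair_probs_per_class = list(LoF = probs, GoF = probs)
  )
  co <- generate_corpus(cfg)
  lof <- co$truth[co$truth$class == "LoF", ]
  frac_ct <- mean(lof$ref_base == "C" & lof$alt_base == "T")
  # binomial 99% interval at n = 2000, p = 0.5 is about +/- 0.029
  expect_lt(abs(frac_ct - 0.5), 0.04)
})

test_that("class-conditional frequencies converge to the configuration", {
  cfg <- simulation_config(seed = 31, n_lof = 5000L, n_gof = 5000L)
  co <- generate_corpus(cfg)
  for (cls in c("LoF", "GoF")) {
    tr <- co$truth[co$truth$class == cls, ]
    # subtypes
    p <- cfg$subtype_probs_per_class[[cls]]
    obs <- table(factor(tr$subtype, levels = names(p)))
    expect_gt(stats::chisq.test(as.numeric(obs), p = as.numeric(p))$p.value,
              0.001)
    # locations
    p <- cfg$location_probs_per_class[[cls]]
    obs <- table(factor(tr$location, levels = names(p)))
    expect_gt(stats::chisq.test(as.numeric(obs), p = as.numeric(p))$p.value,
              0.001)
    # domains
    p <- cfg$domain_probs_per_class[[cls]]
    obs <- table(factor(tr$domain, levels = names(p)))
    expect_gt(stats::chisq.test(as.numeric(obs), p = as.numeric(p))$p.value,
              0.001)
    # missense allele pairs
    p <- cfg$allele_pair_probs_per_class[[cls]]
    mis <- tr[tr$subtype == "missense", ]
    obs <- table(factor(paste0(mis$ref_base, mis$alt_base),
                        levels = names(p)))
    expect_gt(stats::chisq.test(as.numeric(obs), p = as.numeric(p))$p.value,
              0.001)
  }
})

test_that("truth records agree with transcript codons and sentences parse", {
  co <- generate_corpus(simulation_config(seed = 8, n_lof = 60L,
                                          n_gof = 40L))
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    tx <- co$transcripts[[tr$gene]]
    expect_identical(
      translate_codon(codon_at(tx, co$genome, tr$aa_pos)$codon), tr$ref_aa)
  }
  # every sentence contains exactly one parseable mention
  for (i in seq_len(nrow(co$sentences))) {
    m <- extract_mentions(co$sentences$text[i], co$sentences$gene[i])
    expect_identical(nrow(m), 1L)
  }
})

test_that("probability vectors are validated", {
  expect_error(simulation_config(location_probs_per_class = list(
    LoF = c(A = 0.5, B = 0.4), GoF = c(A = 0.5, B = 0.5))), "sum to")
  expect_error(simulation_config(n_lof = 0L))
  expect_error(simulation_config(n_genes = 5L), "n_genes must be")
})

test_that("bayes accuracy: indistinguishable classes give 1/2", {
  expect_equal(bayes_accuracy(preset_config("null")), 0.5)
})

test_that("bayes accuracy: one informative binary feature gives its purity", {
  base <- preset_config("null")
  cfg <- simulation_config(
    seed = 1, n_lof = 300L, n_gof = 300L, n_genes = 40L,
    subtype_probs_per_class = base$subtype_probs_per_class,
    allele_pair_probs_per_class = base$allele_pair_probs_per_class,
    location_probs_per_class = list(
      LoF = c(Nucleus = 0.8, `Cell membrane` = 0.2, Cytoplasm = 0,
              Membrane = 0, Secreted = 0),
      GoF = c(Nucleus = 0.2, `Cell membrane` = 0.8, Cytoplasm = 0,
              Membrane = 0, Secreted = 0)
    ),
    domain_probs_per_class = base$domain_probs_per_class,
    impact_mean_sd_per_class = list(LoF = c(mean = 1.5, sd = 1.2),
                                    GoF = c(mean = 1.5, sd = 1.2))
  )
  expect_equal(bayes_accuracy(cfg), 0.8, tolerance = 1e-12)
})

test_that("bayes accuracy is bounded below by the larger prior", {
  for (p in list(preset_config("paperlike"), preset_config("strong"))) {
    prior_max <- max(p$n_lof, p$n_gof) / (p$n_lof + p$n_gof)
    expect_gte(bayes_accuracy(p), prior_max)
  }
  expect_gte(bayes_accuracy(preset_config("null")), 0.5)
})

test_that("written corpus files re-parse with independent readers", {
  co <- generate_corpus(simulation_config(seed = 13, n_lof = 15L,
                                          n_gof = 10L))
  dir <- tempfile()
  paths <- write_corpus(co, dir)
  # FASTA via Biostrings
  fa <- Biostrings::readDNAStringSet(paths[["genome"]])
  expect_identical(sort(names(fa)), sort(names(co$genome)))
  expect_identical(as.character(fa[["chr001"]]), co$genome[["chr001"]])
  # GFF3 via rtracklayer
  expect_silent(gr <- rtracklayer::import(paths[["gff3"]], format = "gff3"))
  expect_true(all(S4Vectors::mcols(gr)$type == "CDS"))
  # tables
  sent <- read_sentences_tsv(paths[["sentences"]])
  expect_identical(nrow(sent), nrow(co$sentences))
})
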