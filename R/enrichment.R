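#' Upper-tail hypergeometric probability
#'
#' Exact probability \eqn{P(X \ge k)} that a sample of size `n`, drawn
#' without replacement from a background of size `N` containing `K`
#' category members, contains at least `k` of them. This is the enrichment
#' p-value for annotation categories.
#'
#' @param k observed category count in the sample.
#' @param n sample size.
#' @param K category count in the background.
#' @param N background size.
#' @return upper-tail probability in (0, 1].
#' @examples
#' hypergeom_upper_tail(4, 4, 5, 10) # 5/210
#' @export
hypergeom_upper_tail <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, k >= 0, n >= 0, K >= 0, N >= 1,
            k <= n, n <= N, K <= N, k <= K)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of annotation categories
#'
#' One upper-tail hypergeometric test per category present in the sample,
#' against a background histogram (for example the subcellular locations or
#' protein-domain annotations of all human genes). Results are sorted by
#' increasing p-value; an optional Benjamini-Hochberg column is available.
#'
#' @param sample_counts named counts of categories in the sample (a table or
#'   named numeric vector).
#' @param background_counts named counts over the background vocabulary;
#'   every sample category must appear.
#' @param bh add a `q_value` Benjamini-Hochberg column (default `FALSE`; raw
#'   p-values are the primary output).
#' @param depletion also test the lower tail (off by default; the standard
#'   reading is enrichment).
#' @return data frame with `category`, `k`, `n`, `K`, `N`, `p_value`
#'   (and `p_depletion`, `q_value` when requested).
#' @export
enrich_categories <- function(sample_counts, background_counts,
                              bh = FALSE, depletion = FALSE) {
  sample_counts <- .as_counts(sample_counts)
  background_counts <- .as_counts(background_counts)
  missing <- setdiff(names(sample_counts), names(background_counts))
  if (length(missing)) {
    stop("sample categories absent from the background: ",
         paste(missing, collapse = ", "))
  }
  n <- sum(sample_counts)
  N <- sum(background_counts)
  res <- data.frame(
    category = names(sample_counts),
    k = as.integer(sample_counts),
    n = as.integer(n),
    K = as.integer(background_counts[names(sample_counts)]),
    N = as.integer(N),
    stringsAsFactors = FALSE
  )
  res$p_value <- vapply(seq_len(nrow(res)), function(i) {
    hypergeom_upper_tail(res$k[i], res$n[i], res$K[i], res$N[i])
  }, 1)
  if (depletion) {
    res$p_depletion <- stats::phyper(res$k, res$K, res$N - res$K, res$n)
  }
  if (bh) res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value), , drop = FALSE]
}

.as_counts <- function(x) {
  if (is.table(x)) x <- stats::setNames(as.numeric(x), names(x))
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("counts must be named by category")
  }
  if (any(x < 0)) stop("negative counts")
  x[x > 0]
}

#' Two-sample proportion test
#'
#' Compares a proportion between two groups with the pooled two-proportion
#' z-test (two-sided). When any expected cell count under the pooled
#' estimate is below 5 the exact conditional (Fisher) test is used instead,
#' flagged in `method`; with `verbose = TRUE` both p-values are always
#' reported.
#'
#' @param k1,n1 successes and size of group 1 (`n1 >= 1`).
#' @param k2,n2 successes and size of group 2 (`n2 >= 1`).
#' @param verbose return both the z-test and Fisher p-values.
#' @return list with `p_value`, `method` (`"z"` or `"fisher"`), `z`
#'   (pooled z statistic, `NA` for degenerate pooled proportions), and with
#'   `verbose` also `p_z` and `p_fisher`.
#' @examples
#' two_proportion_test(30, 100, 10, 100) # p ~ 4.07e-4
#' @export
two_proportion_test <- function(k1, n1, k2, n2, verbose = FALSE) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p_pool <- (k1 + k2) / (n1 + n2)
  if (p_pool %in% c(0, 1)) {
    z <- NA_real_
    p_z <- 1
  } else {
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    z <- (k1 / n1 - k2 / n2) / se
    p_z <- 2 * stats::pnorm(-abs(z))
  }
  expected <- c(n1 * p_pool, n1 * (1 - p_pool),
                n2 * p_pool, n2 * (1 - p_pool))
  use_fisher <- any(expected < 5)
  p_fisher <- if (use_fisher || verbose) {
    m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
    stats::fisher.test(m)$p.value
  } else NA_real_
  out <- list(p_value = if (use_fisher) p_fisher else p_z,
              method = if (use_fisher) "fisher" else "z",
              z = z)
  if (verbose) {
    out$p_z <- p_z
    out$p_fisher <- p_fisher
  }
  out
}

#' Allele-pair and Ti/Tv distribution of a feature table
#'
#' Counts the 12 ordered reference-to-substituted allele pairs over
#' single-edit missense/nonsense records and aggregates them into
#' transitions (A\eqn{\to}G, G\eqn{\to}A, C\eqn{\to}T, T\eqn{\to}C) and
#' transversions.
#'
#' @param features feature data frame (rows with `REF`/`SUB` present and
#'   `TYPE` missense or nonsense are used).
#' @return list with `pairs` (data frame `pair`, `count`, `proportion`),
#'   `ti` and `tv` counts, and `n` total records used.
#' @export
allele_pair_distribution <- function(features) {
  use <- !is.na(features$REF) & !is.na(features$SUB) &
    features$TYPE %in% c("missense", "nonsense")
  pair <- paste0(features$REF[use], features$SUB[use])
  counts <- vapply(.ALLELE_PAIRS, function(p) sum(pair == p), 1L)
  n <- sum(counts)
  ti <- sum(counts[c("AG", "GA", "CT", "TC")])
  list(
    pairs = data.frame(pair = .ALLELE_PAIRS, count = as.integer(counts),
                       proportion = if (n > 0) as.numeric(counts / n)
                                    else rep(0, length(counts)),
                       row.names = NULL, stringsAsFactors = FALSE),
    ti = as.integer(ti), tv = as.integer(n - ti), n = as.integer(n)
  )
}

#' Per-pair LoF vs GoF proportion tests
#'
#' For each of the 12 ordered allele pairs, and for the Ti and Tv
#' aggregates, compares the pair's proportion among LoF substitutions with
#' its proportion among GoF substitutions using [two_proportion_test()].
#'
#' @param features feature data frame with a `Class` column of
#'   `"LoF"`/`"GoF"`.
#' @param verbose report both z-test and Fisher p-values per row.
#' @return data frame `category`, `count_lof`, `total_lof`, `count_gof`,
#'   `total_gof`, `p_value`, `method` (rows: 12 pairs, `Ti`, `Tv`).
#' @export
allele_pair_tests <- function(features, verbose = FALSE) {
  d_lof <- allele_pair_distribution(features[features$Class == "LoF", ,
                                             drop = FALSE])
  d_gof <- allele_pair_distribution(features[features$Class == "GoF", ,
                                             drop = FALSE])
  cats <- c(.ALLELE_PAIRS, "Ti", "Tv")
  k1 <- c(d_lof$pairs$count, d_lof$ti, d_lof$tv)
  k2 <- c(d_gof$pairs$count, d_gof$ti, d_gof$tv)
  out <- data.frame(category = cats,
                    count_lof = k1, total_lof = d_lof$n,
                    count_gof = k2, total_gof = d_gof$n,
                    stringsAsFactors = FALSE)
  tests <- lapply(seq_len(nrow(out)), function(i) {
    two_proportion_test(out$count_lof[i], out$total_lof[i],
                        out$count_gof[i], out$total_gof[i],
                        verbose = verbose)
  })
  out$p_value <- vapply(tests, `[[`, 1, "p_value")
  out$method <- vapply(tests, `[[`, "", "method")
  if (verbose) {
    out$p_z <- vapply(tests, `[[`, 1, "p_z")
    out$p_fisher <- vapply(tests, `[[`, 1, "p_fisher")
  }
  out
}
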