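#' Balanced-resampling cross-validation plan
#'
#' The evaluation protocol: `n_sets` balanced datasets of `per_class`
#' records per class are drawn, and each dataset is evaluated by
#' stratified `folds`-fold cross-validation repeated `repeats` times. The
#' defaults (100 per class, 50 sets, 5 folds, 100 repeats) yield
#' `n_sets * repeats` = 5,000 cross-validation runs and
#' `n_sets * repeats * folds` = 25,000 fold-level results per classifier,
#' each fold training on 160 and testing on 40 instances.
#'
#' @param per_class records drawn per class in each dataset; must be
#'   divisible by `folds` so every fold is exactly class-balanced.
#' @param n_sets number of balanced datasets.
#' @param folds folds per cross-validation run.
#' @param repeats repetitions of the cross-validation per dataset.
#' @param seed master seed; expanded deterministically into per-dataset and
#'   per-repeat streams, so any fold is reproducible in isolation.
#' @return object of class `resampling_plan`.
#' @export
resampling_plan <- function(per_class = 100L, n_sets = 50L, folds = 5L,
                            repeats = 100L, seed = 1L) {
  stopifnot(per_class >= 1L, n_sets >= 1L, folds >= 1L, repeats >= 1L)
  if (per_class %% folds != 0L) {
    stop("per_class (", per_class, ") must be divisible by folds (", folds,
         ") for exactly balanced folds")
  }
  structure(list(per_class = as.integer(per_class),
                 n_sets = as.integer(n_sets), folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "resampling_plan")
}

## Deterministic sub-seed streams from a master seed. `salt` separates
## purposes so e.g. subset composition and fold shuffles are independent.
.derive_seeds <- function(seed, n, salt = 0L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed((as.numeric(seed) + 1000003 * salt) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw balanced datasets from a feature table
#'
#' Samples `plan$per_class` records per class, without replacement within a
#' dataset and independently across the `plan$n_sets` datasets, removing
#' the class-imbalance bias before cross-validation.
#'
#' @param features feature data frame with a `Class` column (`LoF`/`GoF`).
#' @param plan a [resampling_plan()].
#' @return list of `plan$n_sets` balanced data frames.
#' @export
balanced_subsets <- function(features, plan) {
  idx_lof <- which(features$Class == "LoF")
  idx_gof <- which(features$Class == "GoF")
  for (cls in c("LoF", "GoF")) {
    have <- if (cls == "LoF") length(idx_lof) else length(idx_gof)
    if (have < plan$per_class) {
      stop("insufficient ", cls, " records: need ", plan$per_class,
           ", have ", have, " (deficit ", plan$per_class - have, ")")
    }
  }
  seeds <- .derive_seeds(plan$seed, plan$n_sets, salt = 1L)
  lapply(seq_len(plan$n_sets), function(i) {
    set.seed(seeds[i])
    take <- c(idx_lof[sample.int(length(idx_lof), plan$per_class)],
              idx_gof[sample.int(length(idx_gof), plan$per_class)])
    features[take, , drop = FALSE]
  })
}

.NOMINAL_FEATURES <- c("REF", "SUB", "TYPE", "SL", "PD")

#' Collect the one-hot vocabulary of a feature table
#'
#' The vocabulary must come from the full input, not from individual folds,
#' so that train and test folds share an encoding.
#'
#' @param features feature data frame.
#' @return named list of sorted category vectors per nominal feature.
#' @export
encoding_vocabulary <- function(features) {
  lapply(stats::setNames(nm = .NOMINAL_FEATURES), function(f) {
    v <- as.character(features[[f]])
    v[is.na(v)] <- "none"
    sort(unique(v))
  })
}

#' One-hot encode feature records
#'
#' One binary column per (feature, category) for the five nominal features
#' (`REF`, `SUB`, `TYPE`, `SL`, `PD`; missing alleles are the category
#' `none`), plus the continuous `SCORE` column passed through.
#'
#' @param records feature data frame.
#' @param vocab vocabulary from [encoding_vocabulary()]; defaults to the
#'   vocabulary of `records` itself.
#' @return numeric matrix with named columns.
#' @export
one_hot_encode <- function(records, vocab = NULL) {
  if (is.null(vocab)) vocab <- encoding_vocabulary(records)
  blocks <- lapply(.NOMINAL_FEATURES, function(f) {
    v <- as.character(records[[f]])
    v[is.na(v)] <- "none"
    m <- matrix(0, nrow(records), length(vocab[[f]]),
                dimnames = list(NULL, paste(f, vocab[[f]], sep = ".")))
    hit <- match(v, vocab[[f]])
    known <- !is.na(hit)
    m[cbind(which(known), hit[known])] <- 1
    m
  })
  x <- do.call(cbind, blocks)
  cbind(x, SCORE = as.numeric(records$SCORE))
}

## ---- classifiers ----------------------------------------------------

.fit_predict <- function(classifier, x_train, y_train, x_test, seed,
                         rf_trees = 100L, svm_exponent = 1L, svm_cost = 1) {
  if (classifier == "logistic") {
    y01 <- as.integer(y_train == "LoF")
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x_train), y01, family = stats::binomial())
    )
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    score <- as.vector(stats::plogis(cbind(1, x_test) %*% beta))
    list(pred = ifelse(score > 0.5, "LoF", "GoF"), score = score)
  } else if (classifier == "random_forest") {
    fit <- ranger::ranger(x = as.data.frame(x_train),
                          y = factor(y_train, levels = c("GoF", "LoF")),
                          num.trees = rf_trees, probability = TRUE,
                          seed = seed, num.threads = 1L)
    p <- stats::predict(fit, as.data.frame(x_test),
                        num.threads = 1L)$predictions[, "LoF"]
    list(pred = ifelse(p > 0.5, "LoF", "GoF"), score = as.numeric(p))
  } else if (classifier == "svm") {
    ## normalized polynomial kernel: poly kernel on L2-normalised rows
    norm_rows <- function(m) {
      nrm <- sqrt(rowSums(m^2)); nrm[nrm == 0] <- 1
      m / nrm
    }
    xt <- norm_rows(x_train); xe <- norm_rows(x_test)
    yf <- factor(y_train, levels = c("GoF", "LoF"))
    fit <- e1071::svm(xt, yf, kernel = "polynomial",
                      degree = svm_exponent, gamma = 1, coef0 = 0,
                      cost = svm_cost, scale = FALSE)
    pr <- stats::predict(fit, xe, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    score <- as.numeric(dv[, 1])
    if (!grepl("^LoF", colnames(dv)[1])) score <- -score
    list(pred = as.character(pr), score = score)
  } else {
    stop("unknown classifier: ", classifier)
  }
}

## Rank-based AUC with LoF as the positive class; ties count half.
.rank_auc <- function(score, label) {
  pos <- label == "LoF"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified cross-validation of one classifier on one dataset
#'
#' Runs `plan$repeats` repetitions of stratified `plan$folds`-fold
#' cross-validation. Folds are exactly class-balanced; fold assignment is
#' reshuffled every repetition; models are fit strictly on training folds
#' with the one-hot vocabulary fixed up front.
#'
#' @param dataset balanced feature data frame (as from [balanced_subsets()]).
#' @param classifier `"logistic"`, `"random_forest"` (100 trees by default)
#'   or `"svm"` (normalized polynomial kernel, exponent 1 by default —
#'   a linear decision boundary; exponent 2 available via `svm_exponent`).
#' @param plan a [resampling_plan()].
#' @param seed seed for this dataset's fold shuffles and forests.
#' @param vocab one-hot vocabulary from the full input
#'   ([encoding_vocabulary()]); defaults to the dataset's own.
#' @param dataset_index index recorded in the results.
#' @param rf_trees,svm_exponent,svm_cost classifier hyperparameters.
#' @return data frame of fold results: `dataset_index`, `repeat_index`,
#'   `fold_index`, `classifier`, `tp`, `fn`, `tn`, `fp` (LoF as positive),
#'   `auc`.
#' @export
run_cv <- function(dataset, classifier, plan, seed = plan$seed,
                   vocab = NULL, dataset_index = 1L,
                   rf_trees = 100L, svm_exponent = 1L, svm_cost = 1) {
  x <- one_hot_encode(dataset, vocab)
  y <- as.character(dataset$Class)
  idx_lof <- which(y == "LoF"); idx_gof <- which(y == "GoF")
  stopifnot(length(idx_lof) == plan$per_class,
            length(idx_gof) == plan$per_class)
  per_fold <- plan$per_class %/% plan$folds
  rep_seeds <- .derive_seeds(seed, plan$repeats, salt = 2L)
  fit_seeds <- .derive_seeds(seed, plan$repeats * plan$folds, salt = 3L)
  out <- vector("list", plan$repeats * plan$folds)
  k <- 0L
  for (r in seq_len(plan$repeats)) {
    set.seed(rep_seeds[r])
    fold_of <- integer(length(y))
    fold_of[idx_lof[sample.int(plan$per_class)]] <-
      rep(seq_len(plan$folds), each = per_fold)
    fold_of[idx_gof[sample.int(plan$per_class)]] <-
      rep(seq_len(plan$folds), each = per_fold)
    for (f in seq_len(plan$folds)) {
      test <- fold_of == f
      ytr <- y[!test]
      stopifnot(length(unique(ytr)) == 2L) # stratification guarantee
      k <- k + 1L
      fp <- .fit_predict(classifier, x[!test, , drop = FALSE], ytr,
                         x[test, , drop = FALSE], seed = fit_seeds[k],
                         rf_trees = rf_trees, svm_exponent = svm_exponent,
                         svm_cost = svm_cost)
      yte <- y[test]
      out[[k]] <- data.frame(
        dataset_index = dataset_index, repeat_index = r, fold_index = f,
        classifier = classifier,
        tp = sum(fp$pred == "LoF" & yte == "LoF"),
        fn = sum(fp$pred == "GoF" & yte == "LoF"),
        tn = sum(fp$pred == "GoF" & yte == "GoF"),
        fp = sum(fp$pred == "LoF" & yte == "GoF"),
        auc = .rank_auc(fp$score, yte),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Aggregate fold-level results
#'
#' Per-fold means of accuracy, sensitivity (LoF correctly called LoF),
#' specificity (GoF correctly called GoF) and rank-based AUC.
#'
#' @param fold_results data frame from [run_cv()].
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auc`,
#'   `n_fold_results`.
#' @export
aggregate_metrics <- function(fold_results) {
  if (!nrow(fold_results)) stop("no fold results to aggregate")
  with(fold_results, list(
    accuracy = mean((tp + tn) / (tp + tn + fp + fn)),
    sensitivity = mean(tp / (tp + fn)),
    specificity = mean(tn / (tn + fp)),
    auc = mean(auc),
    n_fold_results = nrow(fold_results)
  ))
}

#' Full balanced-resampling evaluation of the classifiers
#'
#' Draws the balanced datasets, fixes the one-hot vocabulary on the full
#' input, and runs the repeated stratified cross-validation of each
#' requested classifier on every dataset. Records without a score are
#' excluded up front (with a message). All classifiers see identical
#' datasets and fold assignments.
#'
#' @param features feature data frame.
#' @param plan a [resampling_plan()].
#' @param classifiers subset of `c("logistic", "random_forest", "svm")`.
#' @param rf_trees,svm_exponent,svm_cost hyperparameters passed to
#'   [run_cv()].
#' @return list with `fold_results` (one data frame) and `aggregates`
#'   (data frame with one row per classifier: accuracy, sensitivity,
#'   specificity, auc, n_fold_results).
#' @export
run_experiment <- function(features, plan,
                           classifiers = c("logistic", "random_forest",
                                           "svm"),
                           rf_trees = 100L, svm_exponent = 1L,
                           svm_cost = 1) {
  miss <- is.na(features$SCORE)
  if (any(miss)) {
    message(sum(miss), " record(s) without an impact score excluded from ",
            "classification")
    features <- features[!miss, , drop = FALSE]
  }
  vocab <- encoding_vocabulary(features)
  datasets <- balanced_subsets(features, plan)
  cv_seeds <- .derive_seeds(plan$seed, plan$n_sets, salt = 4L)
  all_res <- vector("list", length(datasets) * length(classifiers))
  k <- 0L
  for (d in seq_along(datasets)) {
    for (cl in classifiers) {
      k <- k + 1L
      all_res[[k]] <- run_cv(datasets[[d]], cl, plan, seed = cv_seeds[d],
                             vocab = vocab, dataset_index = d,
                             rf_trees = rf_trees,
                             svm_exponent = svm_exponent,
                             svm_cost = svm_cost)
    }
  }
  fold_results <- do.call(rbind, all_res)
  aggregates <- do.call(rbind, lapply(classifiers, function(cl) {
    m <- aggregate_metrics(
      fold_results[fold_results$classifier == cl, , drop = FALSE])
    data.frame(classifier = cl, accuracy = m$accuracy,
               sensitivity = m$sensitivity, specificity = m$specificity,
               auc = m$auc, n_fold_results = m$n_fold_results,
               stringsAsFactors = FALSE)
  }))
  list(fold_results = fold_results, aggregates = aggregates)
}
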