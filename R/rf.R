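# Random-forest species classification with repeated out-of-bag (OOB)
# evaluation. Each repeat fits an independent forest (bootstrap per tree,
# m_try random parameters per split, majority vote over trees for the OOB
# prediction of each click); correct-classification rates are summarized
# over repeats by their median and 5th/95th quantiles.

#' Random-forest configuration
#'
#' @param n_tree trees per forest (default 3000).
#' @param m_try candidate parameters per split; default `floor(sqrt(M))`
#'   with M = 8 parameters, i.e. 2.
#' @param n_repeats independent forest fits (default 100).
#' @param seed base seed; repeat r uses `seed + r - 1`.
#' @return an `RFConfig` list.
#' @export
rf_config <- function(n_tree = 3000, m_try = floor(sqrt(length(click_parameters()))),
                      n_repeats = 100, seed = 1) {
  stopifnot(n_tree >= 1, m_try >= 1, m_try <= length(click_parameters()),
            n_repeats >= 1)
  structure(list(n_tree = as.integer(n_tree), m_try = as.integer(m_try),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed)),
            class = "RFConfig")
}

#' Expected per-class chance rate, percent
#'
#' The correct-classification rate a no-skill classifier matching the class
#' priors would achieve per class: the class relative frequency, in percent.
#' Rates sum to 100 across classes.
#'
#' @param labels vector or factor of class labels.
#' @return named numeric vector of percentages.
#' @export
expected_chance_rate <- function(labels) {
  if (!length(labels)) stop("empty labels")
  tab <- table(labels)
  r <- 100 * as.numeric(tab) / sum(tab)
  names(r) <- names(tab)
  r
}

#' Expected out-of-bag fraction for a bootstrap of size n
#'
#' Each tree's bootstrap draws n samples with replacement; the expected
#' fraction of samples left out ("out of bag") is `(1 - 1/n)^n`,
#' approaching `exp(-1)` (about 37%) for large n.
#'
#' @param n sample count (>= 1).
#' @return expected OOB fraction in `[0, 1)`.
#' @export
oob_fraction <- function(n) {
  stopifnot(n >= 1)
  (1 - 1 / n)^n
}

#' Fit and evaluate the species classifier
#'
#' For each of `n_repeats` seeds, fits a random forest on the eight click
#' parameters and records the overall and per-class OOB correct-
#' classification rates (percent) plus the permutation importance (mean
#' decrease in accuracy) of each parameter. Rates are reported as the
#' median with 5th and 95th quantiles over repeats; importance is averaged
#' over repeats. Class imbalance is left unweighted, so the majority class
#' is favoured by the majority vote — with strongly overlapping classes the
#' minority-class rate can sit near its prior.
#'
#' @param features per-click feature table: `species` column plus the eight
#'   [click_parameters()] columns, no missing values.
#' @param cfg an [rf_config()].
#' @param quantile_source `"repeats"` (default) — quantiles of the per-repeat
#'   forest OOB rates; `"trees"` — quantiles of per-tree OOB error within a
#'   single forest (one fit, first seed).
#' @return an `RFResult`: list with `overall` and `per_class` (each giving
#'   `median`, `q5`, `q95` in percent), `chance` (per-class prior rates, %),
#'   `importance` (named mean decrease in accuracy), `ranking` (parameters
#'   by decreasing importance, see [importance_ranking()]), `confusion`
#'   (mean OOB confusion counts, true class in rows), `rates_by_repeat`,
#'   `n`, `cfg`.
#' @export
fit_evaluate <- function(features, cfg = rf_config(),
                         quantile_source = c("repeats", "trees")) {
  quantile_source <- match.arg(quantile_source)
  params <- click_parameters()
  missing <- setdiff(params, names(features))
  if (length(missing))
    stop("missing parameter columns: ", paste(missing, collapse = ", "))
  if (!"species" %in% names(features)) stop("missing species column")
  x <- features[params]
  y <- factor(features$species)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (anyNA(x) || anyNA(y)) stop("missing values in features")
  classes <- levels(y)

  one_fit <- function(seed, keep_inbag = FALSE) {
    with_local_seed(seed,
      randomForest::randomForest(x, y, ntree = cfg$n_tree, mtry = cfg$m_try,
                                 importance = TRUE, keep.inbag = keep_inbag))
  }

  overall <- numeric(cfg$n_repeats)
  per_class <- matrix(NA_real_, cfg$n_repeats, length(classes),
                      dimnames = list(NULL, classes))
  imp <- matrix(0, cfg$n_repeats, length(params),
                dimnames = list(NULL, params))
  confusion <- matrix(0, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  first_fit <- NULL
  for (r in seq_len(cfg$n_repeats)) {
    rf <- one_fit(cfg$seed + r - 1, keep_inbag = (r == 1))
    if (r == 1) first_fit <- rf
    pred <- rf$predicted                     # OOB majority-vote predictions
    overall[r] <- 100 * mean(pred == y)
    for (cl in classes)
      per_class[r, cl] <- 100 * mean(pred[y == cl] == cl)
    imp[r, ] <- randomForest::importance(rf, type = 1)[params, 1]
    confusion <- confusion + table(y, pred)[classes, classes]
  }
  confusion <- confusion / cfg$n_repeats

  q3 <- function(v) {
    q <- stats::quantile(v, c(0.5, 0.05, 0.95), type = 7, names = FALSE)
    c(median = q[1], q5 = q[2], q95 = q[3])
  }
  if (quantile_source == "trees") {
    err <- per_tree_oob_error(first_fit, x, y)
    overall_sum <- q3(100 * (1 - err$overall))
    per_class_sum <- t(apply(100 * (1 - err$per_class), 2, q3))
  } else {
    overall_sum <- q3(overall)
    per_class_sum <- t(apply(per_class, 2, q3))
  }

  res <- list(overall = overall_sum, per_class = per_class_sum,
              chance = expected_chance_rate(y),
              importance = colMeans(imp),
              confusion = confusion,
              rates_by_repeat = list(overall = overall, per_class = per_class),
              n = as.integer(table(y)), cfg = cfg,
              quantile_source = quantile_source)
  names(res$n) <- classes
  res$ranking <- importance_ranking(res$importance)
  class(res) <- "RFResult"
  res
}

# Per-tree OOB error rates of a single forest fitted with keep.inbag = TRUE.
per_tree_oob_error <- function(rf, x, y) {
  pred <- stats::predict(rf, x, predict.all = TRUE)$individual
  oob <- rf$inbag == 0
  classes <- levels(y)
  ntree <- ncol(pred)
  overall <- numeric(ntree)
  per_class <- matrix(NA_real_, ntree, length(classes),
                      dimnames = list(NULL, classes))
  for (t in seq_len(ntree)) {
    sel <- oob[, t]
    overall[t] <- mean(pred[sel, t] != y[sel])
    for (cl in classes) {
      s <- sel & y == cl
      per_class[t, cl] <- if (any(s)) mean(pred[s, t] != cl) else NA_real_
    }
  }
  list(overall = overall, per_class = per_class)
}

#' Parameter importance ranking
#'
#' Parameters ordered by decreasing mean permutation importance (mean
#' decrease in accuracy). Exact ties are broken alphabetically and the
#' result carries a `ties` attribute naming the tied parameters.
#'
#' @param result an `RFResult`, or a named importance vector.
#' @return character vector of the 8 parameter names, most important first,
#'   with attribute `ties`.
#' @export
importance_ranking <- function(result) {
  imp <- if (inherits(result, "RFResult")) result$importance else result
  tol <- 1e-10 * max(1, max(abs(imp)))
  ord <- order(-imp, names(imp))
  ranked <- names(imp)[ord]
  sorted <- imp[ord]
  tied <- ranked[c(abs(diff(sorted)) <= tol, FALSE) |
                 c(FALSE, abs(diff(sorted)) <= tol)]
  attr(ranked, "ties") <- tied
  ranked
}

#' @export
print.RFResult <- function(x, ...) {
  cat(sprintf("Random forest (%d trees, m_try %d, %d repeats, %s quantiles)\n",
              x$cfg$n_tree, x$cfg$m_try, x$cfg$n_repeats, x$quantile_source))
  cat(sprintf("Overall OOB correct rate: %.1f%% (5th-95th: %.1f%%-%.1f%%)\n",
              x$overall["median"], x$overall["q5"], x$overall["q95"]))
  for (cl in rownames(x$per_class))
    cat(sprintf("  %-14s %.1f%% (%.1f%%-%.1f%%), chance %.1f%%, n = %d\n", cl,
                x$per_class[cl, "median"], x$per_class[cl, "q5"],
                x$per_class[cl, "q95"], x$chance[cl], x$n[cl]))
  cat("Importance (mean decrease in accuracy):",
      paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
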