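# Descriptive statistics and nonparametric species comparisons of the
# per-click parameter table.

#' Median and 5th/95th percentiles per species and parameter
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param features per-click feature table with a `species` column and the
#'   [click_parameters()] columns.
#' @param parameters parameter columns to summarize (default all eight).
#' @return data frame: `parameter`, `species`, `median`, `p5`, `p95`, `n`.
#' @export
summarize_features <- function(features, parameters = click_parameters()) {
  stopifnot(nrow(features) > 0, "species" %in% names(features))
  missing <- setdiff(parameters, names(features))
  if (length(missing))
    stop("missing parameter columns: ", paste(missing, collapse = ", "))
  out <- expand.grid(parameter = parameters,
                     species = unique(features$species),
                     stringsAsFactors = FALSE)
  stats_for <- function(p, sp) {
    x <- features[[p]][features$species == sp]
    q <- stats::quantile(x, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
    c(median = q[2], p5 = q[1], p95 = q[3], n = length(x))
  }
  m <- t(mapply(stats_for, out$parameter, out$species))
  cbind(out, as.data.frame(m))
}

#' Mann-Whitney U comparison of one parameter between two species
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test. Exact p-values are
#' used for small tie-free samples (both groups at or under 20);
#' otherwise the normal approximation with tie correction.
#'
#' @param features per-click feature table (exactly two species).
#' @param parameter one of [click_parameters()].
#' @param alpha significance level (default 0.05).
#' @return list: `U` (wins of the first species over the second), `p_value`,
#'   `n1`, `n2`, `exact`, `significant`, `species` (the two labels, first =
#'   reference group of `U`).
#' @export
compare_species <- function(features, parameter, alpha = 0.05) {
  sp <- sort(unique(features$species))
  if (length(sp) != 2) stop("need exactly two species, got ", length(sp))
  x <- features[[parameter]][features$species == sp[1]]
  y <- features[[parameter]][features$species == sp[2]]
  if (length(x) < 3 || length(y) < 3) stop("need n >= 3 per species")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 20 && length(y) <= 20
  ht <- stats::wilcox.test(x, y, alternative = "two.sided",
                           exact = exact, correct = !exact)
  list(U = unname(ht$statistic), p_value = ht$p.value,
       n1 = length(x), n2 = length(y), exact = exact,
       significant = ht$p.value < alpha, species = sp)
}

#' Mann-Whitney tests for all eight parameters
#'
#' @inheritParams compare_species
#' @param parameters parameter columns to test.
#' @return data frame: `parameter`, `U`, `p_value`, `significant`.
#' @export
compare_all_parameters <- function(features, parameters = click_parameters(),
                                   alpha = 0.05) {
  res <- lapply(parameters, function(p) {
    r <- compare_species(features, p, alpha)
    data.frame(parameter = p, U = r$U, p_value = r$p_value,
               significant = r$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Normality, equal-variance and log-normality checks for one parameter
#'
#' Mirrors the screening that motivates nonparametric comparison:
#' one-sample Kolmogorov-Smirnov tests against a normal fitted to each
#' group (note the fitted-parameter caveat — with estimated mean and sd the
#' plain KS test is conservative; a Lilliefors correction would reject more
#' often), Levene's test of equal variances across groups, and the KS tests
#' repeated on log-transformed values.
#'
#' @param features per-click feature table.
#' @param parameter one of [click_parameters()].
#' @param alpha significance level (default 0.05).
#' @return list: `ks_p` (named per species), `levene_p`, `ks_log_p`,
#'   `normal_ok`, `equal_variance_ok`, `lognormal_ok`.
#' @export
distribution_checks <- function(features, parameter, alpha = 0.05) {
  sp <- sort(unique(features$species))
  groups <- lapply(sp, function(s) features[[parameter]][features$species == s])
  if (any(vapply(groups, length, 1L) < 8)) stop("need n >= 8 per group")
  ks_one <- function(x) {
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
  }
  ks_p <- vapply(groups, ks_one, 1)
  ks_log_p <- vapply(groups, function(x) ks_one(log(x)), 1)
  names(ks_p) <- names(ks_log_p) <- sp
  lev <- car::leveneTest(features[[parameter]],
                         factor(features$species), center = "mean")
  levene_p <- lev[["Pr(>F)"]][1]
  list(ks_p = ks_p, levene_p = levene_p, ks_log_p = ks_log_p,
       normal_ok = all(ks_p > alpha),
       equal_variance_ok = levene_p > alpha,
       lognormal_ok = all(ks_log_p > alpha))
}
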