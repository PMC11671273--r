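## Nonparametric statistics battery: Kruskal-Wallis with Dunn's post-hoc and
## one-sided rank-sum confirmation for independent groups; Friedman with
## Tukey-Kramer- (or Bonferroni-) corrected signed-rank tests for paired
## conditions; rank-sum poolability check; Pearson correlations with
## Bonferroni correction.

## Dunn's test: pairwise rank-based z statistics on the pooled ranks, with a
## tie correction; two-sided normal p-values, significance at alpha.
dunnTest <- function(samples, alpha = 0.05) {
  g <- factor(rep(names(samples), lengths(samples)),
              levels = names(samples))
  x <- unlist(samples)
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tieCorr
  pairs <- utils::combn(names(samples), 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    z <- (rbar[pr[1L]] - rbar[pr[2L]]) /
      sqrt(v * (1 / n[pr[1L]] + 1 / n[pr[2L]]))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(pair = paste(pr, collapse = " vs "), z = as.numeric(z),
               p = as.numeric(p), significant = p < alpha,
               stringsAsFactors = FALSE)
  }))
}

newStatsResult <- function(test, statistic, df, p, posthoc = NULL, n = NULL) {
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 posthoc = posthoc, n = n), class = "StatsResult")
}

#' @export
print.StatsResult <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test,
              x$statistic, paste(x$df, collapse = ","), x$p))
  if (!is.null(x$posthoc) && nrow(x$posthoc)) {
    cat("post-hoc:\n"); print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

#' Compare independent groups (Kruskal-Wallis / Dunn / rank-sum)
#'
#' Kruskal-Wallis omnibus at p < 0.05; when significant, Dunn's pairwise
#' tests at alpha = 0.05; for Dunn-significant pairs a one-sided Wilcoxon
#' rank-sum test (direction from the group medians). With exactly two
#' groups the procedure reduces to the rank-sum path.
#'
#' @param samples named list of numeric vectors (one per group)
#' @param alpha significance level for the omnibus/Dunn gates (default 0.05)
#' @return a "StatsResult" list (test, statistic, df, p, posthoc, n)
#' @export
compareIndependentGroups <- function(samples, alpha = 0.05) {
  stopifnot(length(samples) >= 2L)
  if (any(lengths(samples) < 2L)) stop("every group needs at least 2 values")
  if (is.null(names(samples)))
    names(samples) <- paste0("g", seq_along(samples))
  if (length(samples) == 2L) {
    wt <- stats::wilcox.test(samples[[1L]], samples[[2L]], exact = FALSE,
                             correct = FALSE)
    return(newStatsResult("wilcoxon_rank_sum", wt$statistic, NA_real_,
                          wt$p.value, n = lengths(samples)))
  }
  kw <- stats::kruskal.test(samples)
  posthoc <- NULL
  if (kw$p.value < alpha) {
    dn <- dunnTest(samples, alpha)
    med <- vapply(samples, stats::median, numeric(1))
    extra <- do.call(rbind, lapply(which(dn$significant), function(i) {
      pr <- strsplit(dn$pair[i], " vs ", fixed = TRUE)[[1L]]
      hi <- pr[order(-med[pr])][1L]; lo <- setdiff(pr, hi)
      wt <- stats::wilcox.test(samples[[hi]], samples[[lo]],
                               alternative = "greater", exact = FALSE,
                               correct = FALSE)
      data.frame(pair = dn$pair[i], test = "rank_sum_one_sided",
                 direction = paste(hi, ">", lo),
                 statistic = as.numeric(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
    posthoc <- list(dunn = dn, ranksum = extra)
  }
  newStatsResult("kruskal_wallis", as.numeric(kw$statistic),
                 as.numeric(kw$parameter), kw$p.value, posthoc,
                 lengths(samples))
}

## Tukey-Kramer family correction of two-sided p-values: map each p to |z|
## and refer sqrt(2)|z| to the studentized range with k groups.
tukeyKramerCorrect <- function(p, k) {
  z <- stats::qnorm(1 - pmin(p, 1 - 1e-16) / 2)
  stats::ptukey(sqrt(2) * z, nmeans = k, df = Inf, lower.tail = FALSE)
}

#' Compare paired conditions (Friedman / signed-rank)
#'
#' Friedman omnibus over matched samples (complete cases); when significant,
#' two-sided Wilcoxon signed-rank tests for every condition pair with
#' Tukey-Kramer (default) or Bonferroni correction.
#'
#' @param data matrix or data.frame, rows = matched units, columns =
#'   conditions
#' @param correction "tukey-kramer" or "bonferroni"
#' @param alpha omnibus gate (default 0.05)
#' @return a "StatsResult" list
#' @export
comparePairedConditions <- function(data, correction = c("tukey-kramer",
                                                         "bonferroni"),
                                    alpha = 0.05) {
  correction <- match.arg(correction)
  m <- as.matrix(data)
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) < 2L) stop("need at least 2 conditions")
  fr <- stats::friedman.test(m)
  stat <- as.numeric(fr$statistic)
  pOmni <- fr$p.value
  if (!is.finite(stat)) { stat <- 0; pOmni <- 1 }   # complete ties
  posthoc <- NULL
  if (pOmni < alpha) {
    prs <- utils::combn(colnames(m), 2, simplify = FALSE)
    tab <- do.call(rbind, lapply(prs, function(pr) {
      wt <- stats::wilcox.test(m[, pr[1L]], m[, pr[2L]], paired = TRUE)
      data.frame(pair = paste(pr, collapse = " vs "),
                 statistic = as.numeric(wt$statistic), p = wt$p.value,
                 stringsAsFactors = FALSE)
    }))
    tab$pCorrected <- if (correction == "bonferroni")
      pmin(1, tab$p * nrow(tab)) else tukeyKramerCorrect(tab$p, ncol(m))
    tab$pCorrected <- pmax(tab$pCorrected, tab$p)   # corrected p >= raw p
    tab$correction <- correction
    posthoc <- tab
  }
  newStatsResult("friedman", stat, as.numeric(fr$parameter), pOmni,
                 posthoc, nrow(m))
}

#' Poolability check between two animals
#'
#' Two-sided Wilcoxon rank-sum test; the two groups are considered poolable
#' iff p > 0.05.
#'
#' @param groupA,groupB numeric vectors
#' @return list(poolable, result) where result is a "StatsResult"
#' @export
checkPoolability <- function(groupA, groupB) {
  if (length(groupA) == 0L || length(groupB) == 0L) stop("empty group")
  wt <- stats::wilcox.test(groupA, groupB, exact = FALSE, correct = FALSE)
  if (!is.finite(wt$p.value)) wt$p.value <- 1    # complete ties
  list(poolable = wt$p.value > 0.05,
       result = newStatsResult("wilcoxon_rank_sum", as.numeric(wt$statistic),
                               NA_real_, wt$p.value,
                               n = c(length(groupA), length(groupB))))
}

#' Pearson correlation of per-session values
#'
#' Pearson r with a Bonferroni-corrected p-value (default factor 3, the
#' number of domain pairs compared).
#'
#' @param x,y paired per-session values (n >= 3)
#' @param nComparisons Bonferroni factor (default 3)
#' @return list(r, p, pCorrected, n)
#' @export
correlateSessionValues <- function(x, y, nComparisons = 3) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = as.numeric(ct$estimate), p = ct$p.value,
       pCorrected = min(1, ct$p.value * nComparisons), n = length(x))
}
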