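# Inferential screening: Pearson feature-outcome correlations,
# Kruskal-Wallis with Dunn's post-hoc comparisons, Benjamini-Hochberg
# multiplicity correction, and an OLS R^2 helper.

#' Pearson screen of features against an outcome
#'
#' Per-feature Pearson correlation with the stress z-score, complete-case,
#' with the p value from the t transform on n - 2 degrees of freedom and a
#' Benjamini-Hochberg adjustment across features.
#'
#' @param features data.frame of numeric feature columns (non-numeric
#'   columns such as `user_id` are ignored).
#' @param outcome numeric outcome vector, same length as `nrow(features)`.
#' @return data.frame `feature, n, r, p, p_adj`.
#' @export
pearson_screen <- function(features, outcome) {
  num <- names(features)[vapply(features, is.numeric, TRUE)]
  rows <- lapply(num, function(nm) {
    x <- features[[nm]]
    ok <- stats::complete.cases(x, outcome)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
      return(data.frame(feature = nm, n = sum(ok), r = NA_real_,
                        p = NA_real_))
    }
    ct <- stats::cor.test(x[ok], outcome[ok], method = "pearson")
    data.frame(feature = nm, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic with k - 1 degrees of freedom and the
#' chi-square approximation for the p value.
#'
#' @param groups a list of numeric vectors, or a numeric vector `x` with a
#'   grouping factor `g`.
#' @param g grouping factor when `groups` is a vector.
#' @return list `statistic` (H), `df`, `p`.
#' @export
kruskal_wallis <- function(groups, g = NULL) {
  kt <- if (is.null(g)) stats::kruskal.test(groups) else
    stats::kruskal.test(groups, g)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Standard Dunn z statistics on the pooled ranks with the tie correction,
#' two-sided p values from the normal approximation, and a
#' Benjamini-Hochberg adjustment within the pairwise family.
#'
#' @inheritParams kruskal_wallis
#' @return data.frame `comparison, z, p, p_adj`, one row per unordered
#'   group pair.
#' @export
dunn_posthoc <- function(groups, g = NULL) {
  if (!is.null(g)) {
    groups <- split(groups, g)
  }
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  labels <- names(groups) %||% as.character(seq_len(k))
  if (is.null(names(groups))) names(groups) <- labels
  x <- unlist(groups, use.names = FALSE)
  gidx <- rep(seq_len(k), lengths(groups))
  n <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_rank <- tapply(r, gidx, mean)
  ni <- lengths(groups)
  pairs <- utils::combn(k, 2)
  zs <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    if (se == 0) return(0)
    (mean_rank[i] - mean_rank[j]) / se
  })
  p <- 2 * stats::pnorm(-abs(zs))
  data.frame(
    comparison = apply(pairs, 2, function(pr)
      paste(labels[pr[1]], labels[pr[2]], sep = " - ")),
    z = as.numeric(zs),
    p = p,
    p_adj = bh_adjust(p),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p values are clipped at 1, preserve the order of the raw p
#' values, and are never smaller than them.
#'
#' @param p numeric vector of raw p values.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' R^2 of a simple linear regression
#'
#' Ordinary-least-squares fit of `y ~ x` reporting the coefficient of
#' determination, overall F statistic and p value — the companion check to
#' [pearson_screen()] for a single predictor.
#'
#' @param x predictor; @param y response.
#' @return list `r2, f, p, n`.
#' @export
linear_fit_r2 <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  fit <- stats::lm(y[ok] ~ x[ok])
  s <- summary(fit)
  list(r2 = unname(s$r.squared),
       f = unname(s$fstatistic[1]),
       p = unname(stats::pf(s$fstatistic[1], s$fstatistic[2],
                            s$fstatistic[3], lower.tail = FALSE)),
       n = sum(ok))
}

#' Three-group screening report for a feature table
#'
#' For every numeric feature: the Pearson correlation with the continuous
#' z outcome, the Kruskal-Wallis test across severity classes, and Dunn's
#' pairwise comparisons (BH-adjusted within each feature's pairwise
#' family). Tidy output, one row per feature x comparison.
#'
#' @param features feature data.frame (numeric columns screened).
#' @param z continuous outcome.
#' @param class group labels (e.g. from [discretize_stress()]); rows
#'   labelled `excluded` or `NA` are dropped.
#' @return data.frame `feature, comparison, statistic, df, p, p_adj, r`.
#' @export
stats_report <- function(features, z, class) {
  keep <- !is.na(class) & class != "excluded"
  features <- features[keep, , drop = FALSE]
  z <- z[keep]; class <- factor(class[keep])
  pear <- pearson_screen(features, z)
  num <- pear$feature
  rows <- list()
  for (nm in num) {
    x <- features[[nm]]
    ok <- stats::complete.cases(x) & !is.na(class)
    r_row <- pear[pear$feature == nm, ]
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, comparison = "pearson(z)", statistic = r_row$r,
      df = r_row$n - 2, p = r_row$p, p_adj = r_row$p_adj, r = r_row$r,
      stringsAsFactors = FALSE)
    if (nlevels(droplevels(class[ok])) >= 2 && stats::sd(x[ok]) > 0) {
      kw <- kruskal_wallis(x[ok], droplevels(class[ok]))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = nm, comparison = "kruskal-wallis", statistic = kw$statistic,
        df = kw$df, p = kw$p, p_adj = NA_real_, r = NA_real_,
        stringsAsFactors = FALSE)
      dn <- dunn_posthoc(x[ok], droplevels(class[ok]))
      rows[[length(rows) + 1L]] <- data.frame(
        feature = nm, comparison = paste("dunn:", dn$comparison),
        statistic = dn$z, df = NA_real_, p = dn$p, p_adj = dn$p_adj,
        r = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
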