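# Per-feature association screening: Kruskal-Wallis across groups, Spearman
# rank correlation with the ordinal group index, Holm-Bonferroni correction,
# and per-group median/IQR summaries.

#' Kruskal-Wallis test for one feature
#'
#' Rank-based k-sample test of location, with the standard tie correction
#' and the chi-square approximation on k - 1 degrees of freedom (via
#' [stats::kruskal.test()]). Degenerate inputs — a single group, or all
#' values identical — return `H = 0, p = 1` with a warning rather than
#' failing, so a constant feature column does not abort a screen.
#'
#' @param values numeric vector, one value per patient.
#' @param groups group labels (any type with >= 2 distinct values).
#' @return List with elements `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (length(unique(groups)) < 2L || length(unique(values)) < 2L) {
    warning("degenerate Kruskal-Wallis input (single group or constant ",
            "values); returning H = 0, p = 1")
    return(list(H = 0, p = 1))
  }
  kt <- kruskal.test(values, factor(groups))
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Spearman rank correlation between a feature and the group index
#'
#' Spearman's rho with average ranks for ties (group labels are heavily
#' tied by construction) and the large-sample t approximation for the
#' p-value, testing the null of no correlation (via [stats::cor.test()]
#' with `exact = FALSE`). Zero variance in either variable returns
#' `rho = 0, p = 1` with a warning.
#'
#' @param values numeric vector, one value per patient.
#' @param groups ordinal group labels (1 < 2 < 3, or 1..5).
#' @return List with elements `rho` and `p`.
#' @export
spearman_vs_group <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  if (length(values) < 3L) stop("need at least 3 observations")
  groups <- as.numeric(groups)
  if (length(unique(values)) < 2L || length(unique(groups)) < 2L) {
    warning("zero variance in Spearman input; returning rho = 0, p = 1")
    return(list(rho = 0, p = 1))
  }
  ct <- suppressWarnings(
    cor.test(values, groups, method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = unname(ct$p.value))
}

#' Holm-Bonferroni step-down correction
#'
#' Adjusts a family of p-values by the step-down Holm procedure (adjusted
#' `p_(k) = max_{j<=k} min(1, (m - j + 1) p_(j))` in ascending order,
#' restored to input positions) and flags rejections at level `alpha`.
#' Holm controls the family-wise error rate at `alpha` and is uniformly
#' more powerful than plain Bonferroni.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @param alpha significance level (default 0.05).
#' @return List with `adjusted` (same order as input) and `reject`
#'   (logical).
#' @export
holm_bonferroni <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adjusted <- p.adjust(p, method = "holm")
  list(adjusted = adjusted, reject = adjusted < alpha)
}

#' Univariate feature screen
#'
#' Applies [kruskal_wallis()] and [spearman_vs_group()] to every feature
#' column of a cohort table, Holm-corrects the two families of p-values
#' separately (41 tests each, mirroring two independent analyses; set
#' `single_family = TRUE` to correct all tests as one family), and computes
#' per-group median and interquartile range for every feature.
#'
#' @param tab a `feature_table` from [cohort_features()].
#' @param alpha family-wise significance level (default 0.05).
#' @param single_family correct KW and Spearman p-values as one family?
#' @return An object of class `radiomic_screen`: list with
#'   \describe{
#'     \item{table}{data.frame per feature: `H`, `p_kw`, `p_kw_adj`,
#'       `sig_kw`, `rho`, `p_rho`, `p_rho_adj`, `sig_rho`,
#'       `neglog10_p_kw`.}
#'     \item{group_summary}{data.frame per feature per group: `median`,
#'       `iqr` (Q3 - Q1, linear-interpolation quantiles).}
#'     \item{alpha, n, groups}{screen metadata.}
#'   }
#' @export
screen_features <- function(tab, alpha = 0.05, single_family = FALSE) {
  stopifnot(inherits(tab, "feature_table"))
  m <- feature_matrix(tab)
  groups <- tab$group

  kw <- apply(m, 2, function(v) unlist(kruskal_wallis(v, groups)))
  sp <- apply(m, 2, function(v) unlist(spearman_vs_group(v, groups)))
  if (single_family) {
    adj <- holm_bonferroni(c(kw["p", ], sp["p", ]), alpha)
    nfeat <- ncol(m)
    kw_adj <- adj$adjusted[seq_len(nfeat)]
    sp_adj <- adj$adjusted[nfeat + seq_len(nfeat)]
    kw_rej <- adj$reject[seq_len(nfeat)]
    sp_rej <- adj$reject[nfeat + seq_len(nfeat)]
  } else {
    a1 <- holm_bonferroni(kw["p", ], alpha)
    a2 <- holm_bonferroni(sp["p", ], alpha)
    kw_adj <- a1$adjusted; kw_rej <- a1$reject
    sp_adj <- a2$adjusted; sp_rej <- a2$reject
  }

  res <- data.frame(
    feature = colnames(m),
    H = kw["H", ],
    p_kw = kw["p", ],
    p_kw_adj = kw_adj,
    sig_kw = kw_rej,
    rho = sp["rho", ],
    p_rho = sp["p", ],
    p_rho_adj = sp_adj,
    sig_rho = sp_rej,
    neglog10_p_kw = -log10(pmax(kw["p", ], .Machine$double.xmin)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  gl <- sort(unique(groups))
  group_summary <- do.call(rbind, lapply(gl, function(g) {
    sub <- m[groups == g, , drop = FALSE]
    data.frame(feature = colnames(m), group = g,
               median = apply(sub, 2, median),
               iqr = apply(sub, 2, function(v) {
                 q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
                 q[2] - q[1]
               }),
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  structure(
    list(table = res, group_summary = group_summary, alpha = alpha,
         n = nrow(tab), groups = table(groups)),
    class = "radiomic_screen"
  )
}

#' @export
print.radiomic_screen <- function(x, ...) {
  cat(sprintf(
    "Univariate radiomic screen: %d features, %d patients (groups: %s)\n",
    nrow(x$table), x$n, paste(x$groups, collapse = "/")))
  sig <- x$table[x$table$sig_kw | x$table$sig_rho, ]
  if (nrow(sig) == 0) {
    cat(sprintf("No feature significant after Holm-Bonferroni at alpha = %g\n",
                x$alpha))
  } else {
    cat(sprintf("Significant after Holm-Bonferroni (alpha = %g):\n", x$alpha))
    for (r in seq_len(nrow(sig))) {
      cat(sprintf("  %-38s H = %6.2f  p_adj = %.2e%s  rho = %+.2f  p_adj = %.2e%s\n",
                  sig$feature[r], sig$H[r], sig$p_kw_adj[r],
                  ifelse(sig$sig_kw[r], "*", " "),
                  sig$rho[r], sig$p_rho_adj[r],
                  ifelse(sig$sig_rho[r], "*", " ")))
    }
  }
  invisible(x)
}

#' Plot a univariate screen
#'
#' Two-panel base-graphics rendering of the screen: Kruskal-Wallis
#' `-log10(p)` per feature (corrected-significance threshold marked) and the
#' Spearman correlation profile.
#'
#' @param x a `radiomic_screen`.
#' @param ... ignored.
#' @export
plot.radiomic_screen <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(8, 4, 2, 1))
  on.exit(graphics::par(op))
  tab <- x$table
  cols <- ifelse(tab$sig_kw, "forestgreen", "grey40")
  graphics::barplot(tab$neglog10_p_kw, names.arg = tab$feature, las = 2,
                    cex.names = 0.45, col = cols, border = NA,
                    ylab = "-log10 p (KW)",
                    main = "Kruskal-Wallis screen")
  cols2 <- ifelse(tab$sig_rho, "forestgreen", "grey40")
  graphics::barplot(tab$rho, names.arg = tab$feature, las = 2,
                    cex.names = 0.45, col = cols2, border = NA,
                    ylab = expression(rho),
                    main = "Spearman correlation with group")
  invisible(x)
}
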