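# Strain-by-metric trait table, scaled PCA, and the comparative statistics
# used alongside the function-valued traits. The ordinary tests delegate to
# base R (aov / TukeyHSD / var.test / cor.test) behind a tidy surface.

#' Build the strain x metric trait table
#'
#' One row per strain; per temperature step, mean and SD of five locomotion
#' metrics (LI1, LI7, 1- and 7-frame displacement, proportion moving), plus
#' mean pixel area and the three logistic fit parameters with their SEs.
#' With 16 temperature steps this yields 16 * 5 * 2 + 1 + 3 + 3 = 167
#' columns. The assay ramp starts with an acclimation point at the initial
#' temperature; by default that first grid temperature is excluded from the
#' per-step columns.
#'
#' @param assay_table QC-filtered, normalized `thermal_assay` table.
#' @param fit_results Result of [fit_strains()] (or a data.frame like its
#'   `"summary"` attribute).
#' @param temps Temperature steps to tabulate; default all but the lowest
#'   assay temperature present.
#' @param moving_threshold Threshold for the proportion-moving metric.
#' @return `list(table, report)`: `table` is a numeric matrix with strain
#'   rownames; `report` lists strains dropped for missing fits or data and
#'   cells left `NA` (e.g. unconverged fits).
#' @export
build_trait_table <- function(assay_table, fit_results,
                              temps = NULL, moving_threshold = 0.1) {
  fits <- if (is.data.frame(fit_results)) fit_results else
    attr(fit_results, "summary")
  if (is.null(temps)) {
    all_t <- sort(unique(assay_table$assay_temp))
    temps <- all_t[-1]
  }
  strains <- sort(intersect(unique(assay_table$strain), fits$strain))
  report <- character(0)
  dropped <- setdiff(union(unique(assay_table$strain), fits$strain), strains)
  if (length(dropped))
    report <- c(report, sprintf("strain %s missing from one input; dropped",
                                dropped))
  metric_cols <- c("li1", "li7", "disp1", "disp7")
  cols <- c(
    as.vector(t(outer(c(sprintf("%s_mean", metric_cols),
                        sprintf("%s_sd", metric_cols),
                        "pm_mean", "pm_sd"),
                      temps, paste, sep = "_"))),
    "area_mean", "alpha", "beta", "tau", "alpha_se", "beta_se", "tau_se")
  tab <- matrix(NA_real_, length(strains), length(cols),
                dimnames = list(strains, cols))
  for (s in strains) {
    sub <- assay_table[assay_table$strain == s, , drop = FALSE]
    for (tt in temps) {
      cell <- sub[sub$assay_temp == tt, , drop = FALSE]
      if (!nrow(cell)) next
      for (m in metric_cols) {
        tab[s, sprintf("%s_mean_%s", m, tt)] <- mean(cell[[m]])
        tab[s, sprintf("%s_sd_%s", m, tt)] <- stats::sd(cell[[m]])
      }
      pm <- proportion_moving(cell$li7, moving_threshold)
      tab[s, sprintf("pm_mean_%s", tt)] <- pm$mean
      tab[s, sprintf("pm_sd_%s", tt)] <- pm$sd
    }
    tab[s, "area_mean"] <- mean(sub$area)
    fr <- fits[fits$strain == s, , drop = FALSE]
    if (nrow(fr) && isTRUE(fr$converged[1])) {
      tab[s, c("alpha", "beta", "tau")] <-
        c(fr$alpha[1], fr$beta[1], fr$tau[1])
      tab[s, c("alpha_se", "beta_se", "tau_se")] <-
        c(fr$alpha_se[1], fr$beta_se[1], fr$tau_se[1])
    } else {
      report <- c(report,
                  sprintf("strain %s: fit unconverged, parameter cells NA", s))
    }
  }
  list(table = tab, report = report)
}

#' Scaled principal component analysis of a trait table
#'
#' Columns are centered and scaled to unit variance before
#' eigendecomposition (the correlation-matrix PCA a scaled redundancy
#' analysis reduces to without constraints). Missing cells are imputed by
#' the column mean; zero-variance columns are dropped with a warning.
#' Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param trait_table Numeric matrix (strains x metrics).
#' @param n_components Components to retain in `scores`/`loadings`
#'   (default 8); the full variance-explained spectrum is always returned.
#' @param scale Scale columns to unit variance (default TRUE; FALSE gives
#'   covariance-matrix PCA, whose spectrum is rotation invariant).
#' @return `list(scores, loadings, var_explained, sdev, dropped,
#'   n_imputed)`; `var_explained` fractions sum to 1 over all components.
#' @export
pca_scaled <- function(trait_table, n_components = 8, scale = TRUE) {
  x <- as.matrix(trait_table)
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 strains and 2 metrics", call. = FALSE)
  n_imputed <- sum(is.na(x))
  if (n_imputed) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  v <- apply(x, 2, stats::var)
  zero <- !is.finite(v) | v < .Machine$double.eps
  if (any(zero)) {
    warning(sprintf("dropping %d zero-variance column(s)", sum(zero)))
    x <- x[, !zero, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       var_explained = ev / sum(ev),
       sdev = pc$sdev,
       dropped = colnames(trait_table)[zero],
       n_imputed = n_imputed)
}

#' One-way ANOVA with Tukey HSD post-hoc decisions
#'
#' Classical one-way ANOVA (`aov`) with `(k - 1, N - k)` degrees of freedom,
#' followed by Tukey honest-significant-difference pairwise comparisons
#' using exact studentized-range quantiles.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor), >= 2 levels with >= 2
#'   values each.
#' @param conf_level Family-wise confidence level for Tukey (default 0.95).
#' @return `list(f, df, p, tukey)`; `tukey` is a data.frame of pairwise
#'   differences, adjusted p and a `different` decision at
#'   `1 - conf_level`.
#' @export
one_way_anova_tukey <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2))
    stop("every group needs at least 2 values", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$groups
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      different = tk[, "p adj"] < (1 - conf_level),
                      stringsAsFactors = FALSE, row.names = NULL)
  list(f = s["groups", "F value"],
       df = c(s["groups", "Df"], s["Residuals", "Df"]),
       p = s["groups", "Pr(>F)"],
       tukey = tukey)
}

#' Two-sided F-test comparing two sample variances
#'
#' `F = var(a) / var(b)` on `(n_a - 1, n_b - 1)` degrees of freedom.
#'
#' @param sample_a,sample_b Numeric vectors with >= 2 values each.
#' @return `list(f, df, p)`.
#' @export
variance_f_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("both samples need at least 2 values", call. = FALSE)
  if (stats::var(sample_b) == 0)
    stop("denominator variance is zero; F undefined", call. = FALSE)
  ft <- stats::var.test(sample_a, sample_b)
  list(f = unname(ft$statistic), df = unname(ft$parameter), p = ft$p.value)
}

#' Spearman rank correlation with midrank ties
#'
#' Rank correlation with the t-approximation p-value (standard software
#' default for the sample sizes used here).
#'
#' @param x,y Paired numeric vectors, n >= 3, neither constant.
#' @return `list(rho, p, n)`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired values", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}
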