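# Study-level statistics: two-way factorial ANOVA with Tukey HSD post-hoc
# (run on log10-transformed ratios where the data are lognormal), Wilcoxon
# rank-sum, and the label-free proteomics filtering/significance rules.

#' Two-way fixed-effects ANOVA
#'
#' Factorial ANOVA of `value ~ factor_a * factor_b`. Balanced designs reduce to
#' the classical sums of squares; unbalanced designs (group sizes of 8-10 are
#' typical in this assay) use Type II sums of squares, the standard choice for
#' factorial designs whose imbalance is not interaction-driven. The model is
#' fit with `lm()` and the Type II table computed by `car::Anova()`.
#'
#' @param data data.frame in long format.
#' @param response,factor_a,factor_b column names.
#' @param log10_transform apply log10 to the response before fitting (used for
#'   ratio data sampled from lognormal distributions).
#' @return an `anova_result` data.frame with rows `factor_a`, `factor_b`,
#'   `interaction`, `error` and columns `effect, ss, df, ms, f, p`.
#' @export
two_way_anova <- function(data, response = "value", factor_a = "genotype",
                          factor_b = "age_group", log10_transform = FALSE) {
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(data)) nt_design_error(sprintf("missing column '%s'", col))
  a <- factor(data[[factor_a]]); b <- factor(data[[factor_b]])
  y <- data[[response]]
  if (log10_transform) {
    if (any(y <= 0)) nt_design_error("log10 transform requires positive values")
    y <- log10(y)
  }
  if (nlevels(a) < 2 || nlevels(b) < 2)
    nt_design_error("each factor needs at least 2 levels")
  cells <- table(a, b)
  if (any(cells == 0))
    nt_design_error("every factor-level cell must contain at least one observation")
  df_err <- length(y) - nlevels(a) * nlevels(b)
  if (df_err < 1) nt_design_error("error degrees of freedom must be >= 1")

  fit <- stats::lm(y ~ a * b)
  ss_err <- sum(stats::residuals(fit)^2)
  if (!is.finite(ss_err) || ss_err <= 1e-10 * max(1, sum((y - mean(y))^2)))
    nt_error("zero error variance: F undefined", "noveltank_undefined_f_error")
  tab <- car::Anova(fit, type = 2)

  rows <- c("a", "b", "a:b", "Residuals")
  out <- data.frame(
    effect = c("factor_a", "factor_b", "interaction", "error"),
    ss = tab[rows, "Sum Sq"],
    df = tab[rows, "Df"],
    stringsAsFactors = FALSE)
  out$ms <- out$ss / out$df
  out$f <- c(out$ms[1:3] / out$ms[4], NA)
  out$p <- c(stats::pf(out$f[1:3], out$df[1:3], out$df[4], lower.tail = FALSE), NA)
  rownames(out) <- NULL
  structure(out, class = c("anova_result", "data.frame"),
            factor_a = factor_a, factor_b = factor_b,
            balanced = length(unique(as.vector(cells))) == 1L)
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise comparisons of cell means for one effect of a factorial design.
#' The studentized-range statistic is
#' `q = |mean_i - mean_j| / sqrt(MS_error/2 * (1/n_i + 1/n_j))` with `MS_error`
#' and its df taken from the full model, and adjusted p-values come from the
#' studentized-range distribution (`ptukey`).
#'
#' @param data data.frame in long format.
#' @param effect which cell means to compare: `"factor_a"`, `"factor_b"` or
#'   `"interaction"` (all factor-combination cells). When `factor_b` is `NULL`
#'   the design is one-way and `effect` is ignored.
#' @param response,factor_a,factor_b column names; `factor_b = NULL` for a
#'   one-way layout.
#' @param log10_transform apply log10 to the response first.
#' @return data.frame `group_i, group_j, diff, q, p_adj` (diff = mean_i - mean_j).
#' @export
tukey_hsd <- function(data, effect = c("factor_a", "factor_b", "interaction"),
                      response = "value", factor_a = "genotype",
                      factor_b = "age_group", log10_transform = FALSE) {
  effect <- match.arg(effect)
  y <- data[[response]]
  if (log10_transform) y <- log10(y)
  a <- factor(data[[factor_a]])
  if (is.null(factor_b)) {
    g <- a
    fit <- stats::lm(y ~ a)
  } else {
    b <- factor(data[[factor_b]])
    g <- switch(effect,
                factor_a = a, factor_b = b,
                interaction = interaction(a, b, sep = ":", drop = TRUE))
    fit <- stats::lm(y ~ a * b)
  }
  res <- stats::residuals(fit)
  df_err <- stats::df.residual(fit)
  if (df_err < 1) nt_design_error("error degrees of freedom must be >= 1")
  ms_err <- sum(res^2) / df_err
  if (ms_err <= 0) nt_error("zero error variance", "noveltank_undefined_f_error")

  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  k <- length(means)
  if (k < 2) nt_design_error("need at least two cells to compare")
  pairs <- utils::combn(names(means), 2)
  diff <- means[pairs[1, ]] - means[pairs[2, ]]
  se <- sqrt(ms_err / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  q <- abs(diff) / se
  p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
  data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
             diff = as.numeric(diff), q = as.numeric(q),
             p_adj = as.numeric(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Rank-sum statistic with midranks for ties. The p-value is exact (from the
#' null rank-sum distribution) when `n_a + n_b <= 12` and there are no ties;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. The two groups here are independent (knockout vs wild
#' type brains), hence rank-sum rather than signed-rank.
#'
#' @param a,b numeric vectors (each at least one value).
#' @return list with `W` (rank sum of `a`), `p`, and `method`.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1 || length(b) < 1)
    nt_input_error("both samples need at least one value")
  if (length(unique(c(a, b))) == 1L)
    nt_degenerate_data_error("all values identical across both samples")
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n_a)])
  ties <- any(duplicated(c(a, b)))

  if (!ties && n <= 12) {
    # exact: U = W - n_a(n_a+1)/2 follows the Mann-Whitney null distribution
    U <- W - n_a * (n_a + 1) / 2
    p <- 2 * min(stats::pwilcox(U, n_a, n_b),
                 stats::pwilcox(U - 1, n_a, n_b, lower.tail = FALSE))
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n_a * (n + 1) / 2
    tie_counts <- table(r)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(W = W, p = p, method = method)
}

#' Filter and call a label-free proteomics table
#'
#' Implements the quantitation inclusion rules for a 3 + 3 replicate design:
#' proteins flagged as contaminants or identified by fewer than two unique
#' peptides are removed; proteins not detected in all three knockout replicates
#' and not detected in all three wild-type replicates are removed. Proteins
#' complete in exactly one genotype are called `KO-only`/`WT-only` and tested
#' with a one-sample t test of that genotype's log2 abundances against the
#' across-table mean abundance (the table-wide mean of all retained log2
#' values; the natural "no regulation" reference when the other genotype gives
#' no signal). Proteins complete in both genotypes get a two-sample t test
#' (equal-variance) and a fold change `2^(mean log2 KO - mean log2 WT)`.
#'
#' @param table data.frame with columns `accession`, `gene`,
#'   `unique_peptide_count`, `contaminant` (logical), `ko1, ko2, ko3`,
#'   `wt1, wt2, wt3` (log2 abundances, `NA` = not detected).
#' @return data.frame `accession, status, p_value, fold_change` with one row
#'   per input protein; `status` is one of `both-detected`, `KO-only`,
#'   `WT-only`, `filtered-out`.
#' @export
filter_protein_table <- function(table) {
  need <- c("accession", "unique_peptide_count", "contaminant",
            "ko1", "ko2", "ko3", "wt1", "wt2", "wt3")
  if (!all(need %in% names(table)))
    nt_design_error(sprintf("protein table must have columns: %s",
                            paste(need, collapse = ", ")))
  ko <- as.matrix(table[, c("ko1", "ko2", "ko3")])
  wt <- as.matrix(table[, c("wt1", "wt2", "wt3")])
  eligible <- !table$contaminant & table$unique_peptide_count >= 2
  # across-table mean abundance over retained rows: the one-sample null value
  mu0 <- mean(c(ko[eligible, ], wt[eligible, ]), na.rm = TRUE)

  out <- data.frame(accession = table$accession,
                    status = "filtered-out",
                    p_value = NA_real_, fold_change = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(table))) {
    if (!eligible[i]) next
    ko_i <- ko[i, ]; wt_i <- wt[i, ]
    ko_full <- !anyNA(ko_i); wt_full <- !anyNA(wt_i)
    if (ko_full && wt_full) {
      out$status[i] <- "both-detected"
      out$p_value[i] <- stats::t.test(ko_i, wt_i, var.equal = TRUE)$p.value
      out$fold_change[i] <- fold_change(ko_i, wt_i)
    } else if (ko_full) {
      out$status[i] <- "KO-only"
      out$p_value[i] <- stats::t.test(ko_i, mu = mu0)$p.value
    } else if (wt_full) {
      out$status[i] <- "WT-only"
      out$p_value[i] <- stats::t.test(wt_i, mu = mu0)$p.value
    }
  }
  out
}

#' Fold change from log2 abundances
#'
#' `2^(mean(ko_log2) - mean(wt_log2))`: the knockout/wild-type abundance ratio
#' implied by mean log2 abundances.
#'
#' @param ko_log2,wt_log2 numeric vectors of log2 abundances.
#' @return the KO/WT ratio (> 0).
#' @export
#' @examples
#' fold_change(c(22.69), c(20.50)) # 2^2.19
fold_change <- function(ko_log2, wt_log2) {
  if (length(ko_log2) == 0 || length(wt_log2) == 0)
    nt_input_error("both abundance vectors must be non-empty")
  2^(mean(ko_log2) - mean(wt_log2))
}
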