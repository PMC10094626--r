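# Factorial ANOVA, Tukey HSD, Wilcoxon rank-sum, proteomics filtering.

test_that("balanced two-way ANOVA matches the cell-mean sums-of-squares oracle", {
  d <- balanced_fixture()
  res <- two_way_anova(d)
  want <- oracle_balanced_anova_ss(d$value, d$genotype, d$age_group)
  expect_equal(res$ss[res$effect == "factor_a"], want$ss_a, tolerance = 1e-9)
  expect_equal(res$ss[res$effect == "factor_b"], want$ss_b, tolerance = 1e-9)
  expect_equal(res$ss[res$effect == "interaction"], want$ss_ab, tolerance = 1e-9)
  expect_equal(res$ss[res$effect == "error"], want$ss_e, tolerance = 1e-9)
  # the decomposition is exhaustive for balanced data
  expect_equal(sum(res$ss), want$ss_total, tolerance = 1e-9)
  # and F/p agree with base R aov
  fit <- summary(stats::aov(value ~ genotype * age_group, data = d))[[1]]
  expect_equal(res$f[1:3], fit[["F value"]][1:3], tolerance = 1e-9)
  expect_equal(res$p[1:3], fit[["Pr(>F)"]][1:3], tolerance = 1e-9)
})

test_that("swapping the factors swaps the main-effect rows", {
  d <- balanced_fixture()
  r1 <- two_way_anova(d, factor_a = "genotype", factor_b = "age_group")
  r2 <- two_way_anova(d, factor_a = "age_group", factor_b = "genotype")
  expect_equal(r1$ss[r1$effect == "factor_a"], r2$ss[r2$effect == "factor_b"])
  expect_equal(r1$ss[r1$effect == "factor_b"], r2$ss[r2$effect == "factor_a"])
  expect_equal(r1$f[r1$effect == "interaction"], r2$f[r2$effect == "interaction"])
})

test_that("ANOVA sums of squares are translation invariant", {
  d <- balanced_fixture()
  d2 <- d; d2$value <- d$value + 1000
  expect_equal(two_way_anova(d)$ss, two_way_anova(d2)$ss, tolerance = 1e-8)
})

test_that("unbalanced designs use Type II sums of squares", {
  d <- balanced_fixture(n = 10)
  set.seed(3); d <- d[-sample(nrow(d), 7), ] # n = 8-10 per cell
  res <- two_way_anova(d)
  a <- factor(d$genotype); b <- factor(d$age_group); y <- d$value
  # Type II by explicit model comparison (residual-sum-of-squares drops)
  rss <- function(f) sum(stats::residuals(stats::lm(f))^2)
  expect_equal(res$ss[res$effect == "factor_a"], rss(y ~ b) - rss(y ~ a + b),
               tolerance = 1e-8)
  expect_equal(res$ss[res$effect == "factor_b"], rss(y ~ a) - rss(y ~ a + b),
               tolerance = 1e-8)
  expect_equal(res$ss[res$effect == "interaction"],
               rss(y ~ a + b) - rss(y ~ a * b), tolerance = 1e-8)
  expect_equal(res$ss[res$effect == "error"], rss(y ~ a * b), tolerance = 1e-8)
})

test_that("degenerate ANOVA designs are rejected", {
  d <- balanced_fixture()
  expect_error(two_way_anova(d[d$genotype == "WT", ]),
               class = "noveltank_design_error")
  empty_cell <- d[!(d$genotype == "KO" & d$age_group == "18m"), ]
  expect_error(two_way_anova(empty_cell), class = "noveltank_design_error")
  flat <- d; flat$value <- rep(1:6, length.out = nrow(d)) # exact cell fit
  flat$value <- ave(flat$value, flat$genotype, flat$age_group)
  expect_error(two_way_anova(flat), class = "noveltank_undefined_f_error")
})

test_that("the ANOVA result reports the reported-shape statistics", {
  # shape check: F(df_effect, df_error) as published figures quote it
  d <- balanced_fixture(n = 10) # 2 x 3 x 10 = 60 obs
  res <- two_way_anova(d)
  expect_equal(res$df[res$effect == "interaction"], 2)
  expect_equal(res$df[res$effect == "error"], 54)
  expect_true(all(res$f[1:3] >= 0))
})

test_that("identical cell means give Tukey p near 1", {
  d <- expand.grid(genotype = c("A", "B"), age_group = c("x", "y"),
                   rep = 1:5)
  set.seed(8)
  d$value <- 5 + rnorm(nrow(d), 0, 1e-3)
  d$value <- d$value - ave(d$value, d$genotype, d$age_group) + 5 # equal means
  tk <- tukey_hsd(d, "interaction")
  expect_true(all(tk$p_adj >= 0.999))
})

test_that("two-group Tukey equals the ordinary t test (q = t * sqrt(2))", {
  set.seed(15)
  d <- data.frame(genotype = rep(c("WT", "KO"), each = 8),
                  value = c(rnorm(8, 10), rnorm(8, 11)))
  tk <- tukey_hsd(d, effect = "factor_a", factor_b = NULL)
  tt <- stats::t.test(value ~ genotype, data = d, var.equal = TRUE)
  expect_equal(tk$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("Tukey agrees with base R TukeyHSD on a balanced factorial", {
  d <- balanced_fixture()
  tk <- tukey_hsd(d, effect = "factor_b")
  base_tk <- stats::TukeyHSD(stats::aov(value ~ genotype * age_group, data = d),
                             which = "age_group")$age_group
  # match pairs irrespective of ordering conventions
  key <- paste(tk$group_i, tk$group_j, sep = "-")
  base_key <- rownames(base_tk)
  flip <- !(key %in% base_key)
  key[flip] <- paste(tk$group_j[flip], tk$group_i[flip], sep = "-")
  expect_setequal(key, base_key)
  expect_equal(tk$p_adj[match(base_key, key)], unname(base_tk[, "p adj"]),
               tolerance = 1e-8)
})

test_that("reversing group order flips diffs but not adjusted p", {
  d <- balanced_fixture()
  d2 <- d; d2$genotype <- factor(d2$genotype, levels = rev(levels(factor(d$genotype))))
  t1 <- tukey_hsd(d, effect = "factor_a")
  t2 <- tukey_hsd(d2, effect = "factor_a")
  expect_equal(t1$diff, -t2$diff)
  expect_equal(t1$p_adj, t2$p_adj, tolerance = 1e-12)
})

test_that("Wilcoxon exact p matches the textbook extreme case", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p, 0.1, tolerance = 1e-12) # 2 / choose(6, 3)
  expect_equal(w$method, "exact")
  expect_equal(w$W, 6)
})

test_that("Wilcoxon exact p equals full enumeration for all small designs", {
  set.seed(23)
  for (n_a in 1:6) for (n_b in n_a:6) {
    a <- round(runif(n_a, 0, 100), 3)
    b <- round(runif(n_b, 0, 100) + 15, 3)
    got <- wilcoxon_rank_sum(a, b)
    expect_equal(got$method, "exact")
    expect_equal(got$p, oracle_wilcoxon_exact(a, b), tolerance = 1e-12,
                 info = sprintf("n_a=%d n_b=%d", n_a, n_b))
  }
})

test_that("Wilcoxon is symmetric and handles ties via the normal branch", {
  set.seed(9)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  expect_equal(wilcoxon_rank_sum(a, b)$p, wilcoxon_rank_sum(b, a)$p,
               tolerance = 1e-12)
  at <- c(1, 2, 2, 3, 5, 6, 7, 8); bt <- c(2, 3, 3, 4, 9, 10, 11, 12)
  got <- wilcoxon_rank_sum(at, bt)
  expect_equal(got$method, "normal-approximation")
  want <- stats::wilcox.test(at, bt, exact = FALSE, correct = TRUE)
  expect_equal(got$p, want$p.value, tolerance = 1e-9)
  expect_error(wilcoxon_rank_sum(c(2, 2), c(2, 2)),
               class = "noveltank_degenerate_data_error")
})

test_that("a self-comparison of a sample is non-significant", {
  set.seed(12)
  a <- rnorm(8)
  w <- wilcoxon_rank_sum(a, a + rnorm(8, 0, 1e-9))
  expect_gt(w$p, 0.8)
})

test_that("the proteomics filter keeps exactly the hand-counted survivors", {
  tab <- toy_protein_table()
  calls <- filter_protein_table(tab)
  expect_equal(nrow(calls), 6L)
  surv <- calls[calls$status != "filtered-out", ]
  expect_setequal(surv$accession, c("P4", "P5", "P6"))
  expect_equal(calls$status[calls$accession == "P1"], "filtered-out") # contaminant
  expect_equal(calls$status[calls$accession == "P2"], "filtered-out") # 1 peptide
  expect_equal(calls$status[calls$accession == "P3"], "filtered-out") # 2/3 KO, 0/3 WT
  expect_equal(calls$status[calls$accession == "P4"], "KO-only")
  expect_true(all(calls$status[calls$accession %in% c("P5", "P6")] == "both-detected"))
  # two-sample branches carry p and fold change; KO-only carries p only
  expect_true(all(is.finite(surv$p_value)))
  expect_true(is.na(calls$fold_change[calls$accession == "P4"]))
  expect_equal(calls$fold_change[calls$accession == "P5"],
               2^(mean(c(22.69, 22.70, 22.68)) - mean(c(20.50, 20.52, 20.48))),
               tolerance = 1e-12)
})

test_that("protein calls are invariant to row order", {
  tab <- toy_protein_table()
  set.seed(2)
  perm <- sample(nrow(tab))
  c1 <- filter_protein_table(tab)
  c2 <- filter_protein_table(tab[perm, ])
  c2 <- c2[match(c1$accession, c2$accession), ]
  expect_equal(c1$status, c2$status)
  expect_equal(c1$p_value, c2$p_value, tolerance = 1e-12)
  expect_equal(c1$fold_change, c2$fold_change, tolerance = 1e-12)
})

test_that("fold change is the exponentiated log2 mean difference", {
  expect_equal(fold_change(22.69, 20.50), 2^2.19, tolerance = 1e-12)
  expect_equal(fold_change(c(20, 21), c(20, 21)), 1)
  expect_equal(fold_change(c(18), c(21)), 1 / fold_change(c(21), c(18)),
               tolerance = 1e-12)
})
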