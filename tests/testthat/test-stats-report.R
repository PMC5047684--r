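test_that("ANOVA F matches the sum-of-squares oracle on random data", {
  withr::with_seed(51, {
    for (rep in 1:5) {
      groups <- lapply(1:4, function(k) rnorm(sample(3:8, 1), mean = k / 2))
      names(groups) <- paste0("g", 1:4)
      res <- oneway_anova_tukey(groups)
      expect_equal(res$statistic, oracle_anova_f(groups), tolerance = 1e-10)
    }
  })
})

test_that("Welch comparison matches stats::t.test and handles degeneracy", {
  withr::with_seed(52, {
    x <- rnorm(10); y <- rnorm(12, 1)
    res <- two_sample_ttest(x, y)
    ref <- t.test(x, y)
    expect_equal(res$p_value, ref$p.value)
    expect_equal(res$statistic, unname(ref$statistic))
  })
  same <- two_sample_ttest(c(1, 1, 1), c(1, 1))
  expect_identical(same$p_value, 1)
  diff <- two_sample_ttest(c(1, 1, 1), c(2, 2))
  expect_identical(diff$p_value, 0)
  expect_error(two_sample_ttest(1, c(1, 2)), class = "myospark_input_error")
})

test_that("Tukey-adjusted p-values are never below the unadjusted pairwise p", {
  fixtures <- list(
    list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)),
    list(a = c(0, 0.1, -0.1, 0.2), b = c(1, 1.2, 0.9), c = c(5, 5.5, 4.5)))
  for (groups in fixtures) {
    res <- oneway_anova_tukey(groups)
    df <- data.frame(value = unlist(groups),
                     group = rep(names(groups), lengths(groups)))
    raw <- pairwise.t.test(df$value, df$group, p.adjust.method = "none",
                           pool.sd = TRUE)$p.value
    for (i in seq_len(nrow(res$pairwise))) {
      a <- res$pairwise$group_a[i]; b <- res$pairwise$group_b[i]
      expect_gte(res$pairwise$adjusted_p[i] + 1e-12,
                 oracle_pairwise_p(raw, a, b))
    }
  }
})

test_that("-dCT is invariant to a constant shift of all C_T values", {
  withr::with_seed(53, {
    tab <- tibble::tibble(
      sample = rep(paste0("s", 1:4), each = 3),
      gene = rep(c("REF", "G1", "G2"), 4),
      ct = runif(12, 18, 28))
    a <- neg_delta_ct(tab, "REF")
    tab2 <- tab; tab2$ct <- tab2$ct + 1.7
    b <- neg_delta_ct(tab2, "REF")
    expect_equal(a$neg_delta_ct, b$neg_delta_ct)
  })
})

test_that("-dCT excludes samples missing the reference and rejects duplicates", {
  tab <- tibble::tibble(sample = c("s1", "s1", "s2"),
                        gene = c("REF", "G1", "G1"),
                        ct = c(20, 22, 23))
  expect_warning(out <- neg_delta_ct(tab, "REF"), "s2")
  expect_false("s2" %in% out$sample)
  dup <- tibble::tibble(sample = c("s1", "s1"), gene = c("G1", "G1"),
                        ct = c(1, 2))
  expect_error(neg_delta_ct(dup, "REF"), class = "myospark_input_error")
})

test_that("heat bins follow the supplied thresholds", {
  tab <- tibble::tibble(sample = paste0("s", 1:9), gene = "G1",
                        ct = 20 - (1:9))
  tab_ref <- tibble::tibble(sample = paste0("s", 1:9), gene = "REF", ct = 20)
  out <- neg_delta_ct(rbind(tab, tab_ref), "REF",
                      bin_thresholds = c(3.5, 6.5))
  g1 <- out[out$gene == "G1", ]
  expect_identical(as.character(g1$heat_bin[order(g1$neg_delta_ct)]),
                   rep(c("low", "medium", "high"), each = 3))
  # default thresholds are the table's own tertiles
  out2 <- neg_delta_ct(rbind(tab, tab_ref), "REF")
  qs <- unname(quantile(out2$neg_delta_ct, c(1 / 3, 2 / 3)))
  expect_identical(as.character(out2$heat_bin),
                   as.character(cut(out2$neg_delta_ct,
                                    c(-Inf, qs, Inf),
                                    labels = c("low", "medium", "high"))))
})

test_that("line pooling pools indistinguishable lines and splits distinct ones", {
  withr::with_seed(54, {
    tab <- tibble::tibble(
      cell_id = paste0("c", 1:40),
      line = rep(c("ctl_A", "ctl_B", "dis_A", "dis_B"), each = 10),
      condition = "baseline",
      variable = "leak",
      value = c(rnorm(10, 1, 0.1), rnorm(10, 1, 0.1),
                rnorm(10, 1, 0.1), rnorm(10, 5, 0.1)))
    res <- pool_lines(tab, "leak")
    dec <- res$decisions
    expect_true(dec$pooled[dec$group == "ctl"])
    expect_false(dec$pooled[dec$group == "dis"])
    expect_true(all(res$data$group_label[res$data$line == "ctl_A"] == "ctl"))
    expect_true(all(res$data$group_label[res$data$line == "dis_A"] == "dis_A"))
  })
})

test_that("compare_conditions picks the t-test for 2 conditions, ANOVA for more", {
  withr::with_seed(55, {
    mk <- function(conds) tibble::tibble(
      cell_id = seq_len(8 * length(conds)),
      line = rep(rep(c("g_A", "g_B"), each = 4), length(conds)),
      condition = rep(conds, each = 8),
      variable = "v",
      value = rnorm(8 * length(conds)))
    two <- compare_conditions(mk(c("a", "b")), "v")
    expect_true(all(two$test == "t_test"))
    four <- compare_conditions(mk(c("a", "b", "c", "d")), "v")
    expect_true(all(four$test == "anova_tukey"))
    expect_gt(nrow(four$pairwise[[1]]), 0)
  })
})

test_that("the report states the pooling decision and group means", {
  withr::with_seed(56, {
    tab <- tibble::tibble(
      cell_id = seq_len(24),
      line = rep(rep(c("ctl_A", "ctl_B"), each = 6), 2),
      condition = rep(c("baseline", "iso"), each = 12),
      variable = "leak",
      value = c(rnorm(12, 1, 0.1), rnorm(12, 2, 0.1)))
    rep_obj <- build_report(tab)
    expect_s3_class(rep_obj, "cohort_report")
    expect_true(all(c("variable", "test", "p_value", "pooled_lines") %in%
                      names(rep_obj$comparisons)))
    gm <- rep_obj$group_means
    expect_equal(gm$mean[gm$condition == "iso"],
                 mean(tab$value[tab$condition == "iso"]))
  })
})

test_that("condition presets encode the expected disease contrast", {
  ctl <- condition_presets("control", "baseline")
  iso <- condition_presets("cpvt", "iso")
  flec <- condition_presets("cpvt", "flec")
  expect_gt(iso$spark_rate, ctl$spark_rate)
  expect_gt(iso$leak_true, ctl$leak_true)
  expect_lt(iso$load_true, ctl$load_true)
  expect_lt(flec$wave_rate_per_s, iso$wave_rate_per_s)
})
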