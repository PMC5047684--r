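#' Test whether two sub-lines of a group can be pooled
#'
#' Mirrors the cohort workflow: within each group (e.g. control, disease)
#' the two derived cell lines are compared by Welch two-sample t-test; when
#' no significant difference is found (p >= alpha) their cells are combined
#' for downstream condition comparisons, otherwise comparisons run per line.
#'
#' @param table Measurement tibble with columns `cell_id`, `line`,
#'   `condition`, `variable`, `value`; the group of a line is its name with
#'   the trailing `_<suffix>` removed (e.g. `control_A` and `control_B`
#'   form group `control`).
#' @param variable Which variable to assess.
#' @param alpha Pooling significance level.
#' @return A list: `data` (the table with a `group_label` column: group
#'   name where pooled, line name where not) and `decisions` (per-group
#'   tibble `group`, `p_value`, `pooled`, `reason`).
#' @export
pool_lines <- function(table, variable, alpha = 0.05) {
  stopifnot(all(c("line", "variable", "value") %in% names(table)))
  tab <- dplyr::filter(table, .data$variable == !!variable)
  tab$group <- sub("_[^_]+$", "", tab$line)
  decisions <- tab |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      lines <- unique(d$line)
      if (length(lines) != 2) {
        return(tibble(p_value = NA_real_, pooled = FALSE,
                      reason = "group does not have exactly two lines"))
      }
      x <- d$value[d$line == lines[1]]
      y <- d$value[d$line == lines[2]]
      if (length(x) < 2 || length(y) < 2) {
        return(tibble(p_value = NA_real_, pooled = FALSE,
                      reason = "a sub-line has fewer than 2 cells"))
      }
      res <- safe_welch(x, y)
      tibble(p_value = res$p_value,
             pooled = res$p_value >= alpha,
             reason = if (res$p_value >= alpha)
               "no significant line difference" else
                 "significant line difference")
    }) |>
    dplyr::ungroup()
  tab <- dplyr::left_join(tab, decisions[, c("group", "pooled")],
                          by = "group")
  tab$group_label <- ifelse(tab$pooled, tab$group, tab$line)
  tab$pooled <- NULL
  list(data = tab, decisions = decisions)
}

safe_welch <- function(x, y) {
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) return(list(statistic = 0, p_value = 1))
    return(list(statistic = Inf * sign(mean(x) - mean(y)), p_value = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Welch two-sample t-test as a comparison result
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @return A `comparison_result`: `test`, `statistic`, `p_value`,
#'   `pairwise` (NULL for a t-test).
#' @export
two_sample_ttest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("need at least 2 values per group",
          class = "myospark_input_error")
  }
  res <- safe_welch(x, y)
  structure(list(test = "t_test", statistic = res$statistic,
                 p_value = res$p_value, pairwise = NULL),
            class = "comparison_result")
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups Named list of numeric vectors (>= 3 groups, >= 2 values
#'   each).
#' @return A `comparison_result` with the F statistic, its p-value, and a
#'   `pairwise` tibble of Tukey-adjusted comparisons.
#' @export
oneway_anova_tukey <- function(groups) {
  if (length(groups) < 3) abort("need at least 3 groups for Tukey HSD",
                                class = "myospark_input_error")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("every group needs at least 2 values",
          class = "myospark_input_error")
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- tibble(value = unlist(groups, use.names = FALSE),
               group = factor(rep(names(groups),
                                  vapply(groups, length, integer(1)))))
  fit <- aov(value ~ group, data = df)
  sm <- summary(fit)[[1]]
  f <- sm$`F value`[1]
  p <- sm$`Pr(>F)`[1]
  tk <- TukeyHSD(fit)$group
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- tibble(
    group_a = vapply(pairs, `[`, character(1), 1),
    group_b = vapply(pairs, `[`, character(1), 2),
    diff = unname(tk[, "diff"]),
    adjusted_p = unname(tk[, "p adj"]))
  structure(list(test = "anova_tukey", statistic = unname(f),
                 p_value = unname(p), pairwise = pairwise),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' @rdname two_sample_ttest
#' @param x A `comparison_result`.
#' @param ... Unused.
#' @method tidy comparison_result
#' @export
tidy.comparison_result <- function(x, ...) {
  if (is.null(x$pairwise)) {
    tibble(test = x$test, statistic = x$statistic, p_value = x$p_value)
  } else {
    dplyr::mutate(x$pairwise, test = x$test, .before = 1)
  }
}

#' @rdname two_sample_ttest
#' @method glance comparison_result
#' @export
glance.comparison_result <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n_pairwise = if (is.null(x$pairwise)) 0L else nrow(x$pairwise))
}

#' Normalize a C_T table to -dCT relative to a reference gene
#'
#' -dCT = -(C_T,gene - C_T,reference) per sample; higher values mean higher
#' relative expression.  Heatmap bins (low/medium/high) are assigned by
#' configurable thresholds, defaulting to the tertiles of the table.
#'
#' @param ct_table Tibble `sample`, `gene`, `ct`.
#' @param reference_gene Housekeeping gene name.
#' @param bin_thresholds Optional length-2 increasing cutpoints; defaults
#'   to the -dCT tertiles.
#' @return Tibble `sample`, `gene`, `ct`, `neg_delta_ct`, `heat_bin`;
#'   samples missing the reference gene are excluded with a warning.
#' @export
neg_delta_ct <- function(ct_table, reference_gene, bin_thresholds = NULL) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(ct_table)))
  if (anyDuplicated(ct_table[, c("sample", "gene")])) {
    abort("duplicate (sample, gene) rows", class = "myospark_input_error")
  }
  ref <- ct_table |>
    dplyr::filter(.data$gene == reference_gene) |>
    dplyr::select("sample", ref_ct = "ct")
  missing <- setdiff(unique(ct_table$sample), ref$sample)
  if (length(missing)) {
    warn(sprintf("samples without reference gene excluded: %s",
                 paste(missing, collapse = ", ")))
  }
  out <- ct_table |>
    dplyr::inner_join(ref, by = "sample") |>
    dplyr::mutate(neg_delta_ct = -(.data$ct - .data$ref_ct)) |>
    dplyr::select(-"ref_ct")
  if (is.null(bin_thresholds)) {
    bin_thresholds <- unname(quantile(out$neg_delta_ct, c(1 / 3, 2 / 3)))
  }
  out$heat_bin <- cut(out$neg_delta_ct,
                      breaks = c(-Inf, bin_thresholds, Inf),
                      labels = c("low", "medium", "high"))
  as_tibble(out)
}

#' Compare a variable across conditions with the cohort's workflow
#'
#' Applies the line-pooling rule, then compares conditions: a two-sample
#' Welch t-test for exactly two conditions, one-way ANOVA with Tukey HSD
#' for three or more.  The report records which test ran and the pooling
#' decision.
#'
#' @param table Measurement tibble (see [pool_lines()]).
#' @param variable Variable to compare.
#' @param alpha Pooling significance level.
#' @return Tibble with one row per group label: the test used, statistic,
#'   p-value, pooling flag, and a list-column of Tukey pairwise results.
#' @export
compare_conditions <- function(table, variable, alpha = 0.05) {
  pooled <- pool_lines(table, variable, alpha)
  pooled$data |>
    dplyr::group_by(.data$group_label) |>
    dplyr::group_modify(function(d, key) {
      conds <- split(d$value, d$condition)
      conds <- conds[vapply(conds, length, integer(1)) >= 2]
      if (length(conds) < 2) {
        return(tibble(test = NA_character_, statistic = NA_real_,
                      p_value = NA_real_, pooled_lines = NA,
                      pairwise = list(NULL)))
      }
      res <- if (length(conds) == 2) {
        two_sample_ttest(conds[[1]], conds[[2]])
      } else oneway_anova_tukey(conds)
      grp <- sub("_[^_]+$", "", key$group_label)
      dec <- pooled$decisions[pooled$decisions$group %in%
                                c(key$group_label, grp), ]
      tibble(test = res$test, statistic = res$statistic,
             p_value = res$p_value,
             pooled_lines = isTRUE(dec$pooled[1]),
             pairwise = list(res$pairwise))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(variable = variable, .before = 1)
}
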