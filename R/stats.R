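#' Validate a named list of group samples
#'
#' At least two non-empty groups of finite observations (MAD or difference
#' values in mm, but any real measurements work).
#'
#' @param groups named list of numeric vectors.
#' @return the validated list, invisibly usable.
#' @export
group_samples <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need a list of at least 2 groups")
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  for (g in names(groups)) {
    v <- groups[[g]]
    if (!length(v)) stop("group ", g, " is empty")
    if (!all(is.finite(v))) stop("group ", g, " has non-finite values")
  }
  groups
}

#' Kruskal-Wallis omnibus test
#'
#' H computed from mid-ranks with the standard tie correction, p-value from
#' the chi-square approximation with k - 1 degrees of freedom (via base
#' `kruskal.test`). With all observations identical the statistic is defined
#' as 0 with p = 1.
#'
#' @param groups named list of numeric vectors (see [group_samples()]).
#' @return list of class `kw_test`: `statistic` (H), `df`, `p_value`,
#'   `n_total`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- group_samples(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(x) < 3L) stop("need at least 3 observations in total")
  if (length(unique(x)) == 1L) {
    out <- list(statistic = 0, df = length(groups) - 1L, p_value = 1,
                n_total = length(x))
    class(out) <- "kw_test"
    return(out)
  }
  kt <- stats::kruskal.test(x, g)
  structure(list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, n_total = length(x)),
            class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (N = %d)\n",
              x$statistic, x$df, x$p_value, x$n_total))
  invisible(x)
}

#' Dunn's post hoc test with Bonferroni adjustment
#'
#' Pairwise z-statistics on pooled mid-ranks with tie correction,
#' two-sided p-values multiplied by the number of comparisons
#' k(k-1)/2 and clamped at 1.
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level for the `significant` flags.
#' @return data frame of class `dunn_test` with columns `group1`, `group2`,
#'   `z`, `p_raw`, `p_adjusted`, `significant`.
#' @export
dunn_bonferroni <- function(groups, alpha = 0.05) {
  groups <- group_samples(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)  # mid-ranks
  rbar <- tapply(r, g, mean)[names(groups)]
  ni <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_term
  k <- length(groups)
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  z <- p_raw <- numeric(m)
  for (j in seq_len(m)) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    se <- sqrt(var_base * (1 / ni[[a]] + 1 / ni[[b]]))
    z[j] <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    p_raw[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  p_adj <- pmin(1, p_raw * m)
  structure(
    data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
               p_raw = p_raw, p_adjusted = p_adj,
               significant = p_adj < alpha),
    class = c("dunn_test", "data.frame")
  )
}

#' Normality screening (Shapiro-Wilk and Lilliefors-corrected KS)
#'
#' Reports both p-values and the nonparametric-branch decision: the
#' downstream pipeline uses nonparametric tests when either test rejects at
#' `alpha`. The Kolmogorov-Smirnov test is applied with estimated mean and
#' SD (Lilliefors correction, the common statistical-software default). A
#' constant sample is non-normal by convention (p reported 0).
#'
#' @param sample numeric vector, length >= 3.
#' @param alpha significance level.
#' @return list with `shapiro_p`, `ks_p`, `normal` (logical: neither test
#'   rejects).
#' @export
normality_screen <- function(sample, alpha = 0.05) {
  if (length(sample) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(sample))) stop("sample has non-finite values")
  if (length(unique(sample)) == 1L) {
    return(list(shapiro_p = 0, ks_p = 0, normal = FALSE))
  }
  sw <- stats::shapiro.test(sample)$p.value
  ks <- nortest::lillie.test(sample)$p.value
  list(shapiro_p = sw, ks_p = ks, normal = sw >= alpha && ks >= alpha)
}

#' Write a human-readable statistics report
#'
#' CSV of (comparison, statistic, df, p, adjusted p, significant) plus a
#' plain-text summary, for a Kruskal-Wallis omnibus test and its Dunn post
#' hoc table.
#'
#' @param kw a [kruskal_wallis()] result.
#' @param dunn a [dunn_bonferroni()] result (or `NULL` if the omnibus was not
#'   significant).
#' @param csv_path,txt_path output paths (either may be `NULL` to skip).
#' @param title heading for the text summary.
#' @return data frame of report rows, invisibly.
#' @export
write_stats_report <- function(kw, dunn = NULL, csv_path = NULL,
                               txt_path = NULL, title = "comparison") {
  rows <- data.frame(
    comparison = "omnibus", statistic = kw$statistic, df = kw$df,
    p = kw$p_value, p_adjusted = NA_real_,
    significant = kw$p_value < 0.05
  )
  if (!is.null(dunn)) {
    rows <- rbind(rows, data.frame(
      comparison = paste(dunn$group1, "vs", dunn$group2),
      statistic = dunn$z, df = NA_real_, p = dunn$p_raw,
      p_adjusted = dunn$p_adjusted, significant = dunn$significant
    ))
  }
  if (!is.null(csv_path)) {
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  if (!is.null(txt_path)) {
    txt <- c(
      title,
      sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g",
              kw$statistic, kw$df, kw$p_value),
      if (!is.null(dunn)) c(
        "Dunn-Bonferroni post hoc:",
        sprintf("  %s vs %s: z = %.3f, adj. p = %.4g%s",
                dunn$group1, dunn$group2, dunn$z, dunn$p_adjusted,
                ifelse(dunn$significant, " *", ""))
      )
    )
    writeLines(txt, txt_path)
  }
  invisible(rows)
}

#' Percentages of a characteristics count table
#'
#' Recomputes the percentage columns of a categorical sample-characteristics
#' table (counts per class within each characteristic) as
#' `100 * count / total`, rounded to one decimal, the convention of such
#' demographic tables.
#'
#' @param counts data frame with columns `characteristic`, `class`, `count`.
#' @return the input with columns `total` and `percent` added.
#' @export
characteristics_percentages <- function(counts) {
  stopifnot(all(c("characteristic", "class", "count") %in% names(counts)))
  totals <- tapply(counts$count, counts$characteristic, sum)
  counts$total <- as.integer(totals[counts$characteristic])
  counts$percent <- round(100 * counts$count / counts$total, 1)
  counts
}
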