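# Group comparisons: mean +/- sd summaries, one-way ANOVA across the three
# species groups, and Student's (pooled-variance) pairwise t-tests with
# Bonferroni correction at alpha = 0.05.

#' One-way ANOVA across groups
#'
#' @param groups list of numeric vectors, one per group (each length >= 2).
#' @return object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`. Identical groups (zero between- and within-variance) give `F = 0`,
#'   `p = 1`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least 2 values")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  k <- length(groups)
  N <- length(values)
  if (stats::var(values) == 0) {
    return(structure(list(F = 0, df_between = k - 1L, df_within = N - k, p = 1),
                     class = "anova_result"))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(
    list(F = unname(fit$statistic), df_between = k - 1L, df_within = N - k,
         p = unname(fit$p.value)),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Pairwise Student's t-tests with Bonferroni correction
#'
#' Two-sample pooled-variance t-test for every pair of groups; adjusted
#' p-values are `min(1, p * m)` for `m = k(k-1)/2` comparisons
#' (equivalent to dividing alpha by m).
#'
#' @param groups named list of numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return data frame `pair`, `t`, `p_raw`, `p_adjusted`, `significant`.
#' @export
pairwise_t_bonferroni <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2L)) {
    stop("every group needs at least 2 values")
  }
  nms <- names(groups) %||% as.character(seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nms
  pairs <- utils::combn(length(groups), 2)
  m <- ncol(pairs)
  out <- data.frame(
    pair = character(m), t = numeric(m), p_raw = numeric(m),
    p_adjusted = numeric(m), significant = logical(m),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    a <- groups[[i1]]
    b <- groups[[i2]]
    if (stats::var(a) == 0 && stats::var(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    out$pair[j] <- paste(nms[i1], nms[i2], sep = " vs ")
    out$t[j] <- unname(tt$statistic)
    out$p_raw[j] <- tt$p.value
    out$p_adjusted[j] <- min(1, tt$p.value * m)
    out$significant[j] <- out$p_adjusted[j] < alpha
  }
  out
}

#' Per-group mean and standard deviation for each metric
#'
#' @param table data frame with columns `specimen_id`, `group_id`, `metric`,
#'   `value` (long format).
#' @return data frame `group_id`, `metric`, `n`, `mean`, `sd` (sample sd,
#'   n-1 denominator; `NA` with a warning for singleton groups).
#' @export
summarize_groups <- function(table) {
  need <- c("group_id", "metric", "value")
  if (!all(need %in% names(table))) {
    stop("table must have columns group_id, metric, value")
  }
  out <- do.call(rbind, lapply(
    split(table, list(table$group_id, table$metric), drop = TRUE),
    function(d) {
      data.frame(group_id = d$group_id[1], metric = d$metric[1],
                 n = nrow(d), mean = mean(d$value), sd = sd_or_na(d$value),
                 stringsAsFactors = FALSE)
    }
  ))
  rownames(out) <- NULL
  if (any(out$n < 2L)) warning("singleton group(s): sd undefined, reported NA")
  out[order(out$metric, out$group_id), ]
}

#' Full statistics report over a per-specimen metrics table
#'
#' For every metric: group summaries, one-way ANOVA, and Bonferroni-adjusted
#' pairwise t-tests.
#'
#' @param metrics wide data frame with `specimen_id`, `group_id` and one
#'   column per metric.
#' @param alpha significance level.
#' @return list with `summary` (from [summarize_groups()]), `anova`
#'   (data frame per metric) and `pairwise` (data frame per metric/pair).
#' @export
group_stats_report <- function(metrics, alpha = 0.05) {
  id_cols <- intersect(c("specimen_id", "group_id"), names(metrics))
  metric_cols <- setdiff(names(metrics), id_cols)
  long <- do.call(rbind, lapply(metric_cols, function(mc) {
    data.frame(specimen_id = metrics$specimen_id,
               group_id = metrics$group_id, metric = mc,
               value = metrics[[mc]], stringsAsFactors = FALSE)
  }))
  long <- long[is.finite(long$value), ]
  anova_rows <- list()
  pw_rows <- list()
  for (mc in metric_cols) {
    d <- long[long$metric == mc, ]
    gl <- split(d$value, d$group_id)
    if (length(gl) < 2L || any(vapply(gl, length, 1L) < 2L)) next
    an <- anova_oneway(gl)
    anova_rows[[mc]] <- data.frame(
      metric = mc, F = an$F, df_between = an$df_between,
      df_within = an$df_within, p = an$p, stringsAsFactors = FALSE
    )
    pw <- pairwise_t_bonferroni(gl, alpha = alpha)
    pw$metric <- mc
    pw_rows[[mc]] <- pw
  }
  list(
    summary = summarize_groups(long),
    anova = do.call(rbind, c(anova_rows, list(make.row.names = FALSE))),
    pairwise = do.call(rbind, c(pw_rows, list(make.row.names = FALSE)))
  )
}
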