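#' A labelled sample of measurements from one experimental group
#'
#' Distribution-level comparisons (cumulative curves, Kolmogorov-Smirnov)
#' use the per-event values pooled across cells; mean-level tests (t,
#' ANOVA) use the per-cell means so that n equals the number of cells.
#'
#' @param label group label.
#' @param per_event_values pooled per-event measurements.
#' @param per_cell_means one mean per cell (may be empty if only
#'   distribution comparisons are needed).
#' @return an object of class `group_sample`.
#' @export
group_sample <- function(label, per_event_values,
                         per_cell_means = numeric(0)) {
  if (!length(per_event_values) && !length(per_cell_means))
    stop("a group sample cannot be empty", call. = FALSE)
  structure(list(label = label,
                 per_event_values = as.numeric(per_event_values),
                 per_cell_means = as.numeric(per_cell_means)),
            class = "group_sample")
}

#' Empirical cumulative probability curve
#'
#' Right-continuous step function with probability k/n at the k-th order
#' statistic, as plotted in cumulative probability plots of inter-event
#' intervals or amplitudes.
#'
#' @param values numeric vector (non-empty).
#' @return list with sorted `values` and cumulative `prob` (reaching
#'   exactly 1).
#' @export
cumulative_curve <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no values for a cumulative curve",
                            call. = FALSE)
  n <- length(values)
  list(values = sort(values), prob = seq_len(n) / n)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' is exact for small samples and asymptotic (Kolmogorov distribution) for
#' larger ones, as computed by [stats::ks.test()].
#'
#' @param a,b [group_sample()] objects or numeric vectors; at least 5
#'   values each.
#' @return list with `D`, `p`, and the two sample sizes.
#' @export
ks_compare <- function(a, b) {
  va <- if (inherits(a, "group_sample")) a$per_event_values else
    as.numeric(a)
  vb <- if (inherits(b, "group_sample")) b$per_event_values else
    as.numeric(b)
  if (length(va) < 5L || length(vb) < 5L)
    stop("Kolmogorov-Smirnov comparison needs at least 5 values per group",
         call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(va, vb))
  list(D = unname(kt$statistic), p = kt$p.value,
       n_a = length(va), n_b = length(vb))
}

#' Group comparison: unpaired t or one-way ANOVA with Bonferroni post test
#'
#' Two groups are compared with a two-sided unpaired Student's t-test on
#' the per-cell means. Three or more groups are compared with a one-way
#' ANOVA followed by all pairwise comparisons using the pooled residual
#' variance (the classic Bonferroni post test): each raw two-sided p-value
#' is multiplied by the number of pairs and capped at 1.
#'
#' @param groups list of [group_sample()] objects, each with at least 2
#'   per-cell means.
#' @param design `"two-group"` or `"multi-group"`; inferred from the number
#'   of groups when omitted.
#' @param alpha significance level for the flags (default 0.05).
#' @return a list report: for two groups, `t`, `df`, `p`, `significant`;
#'   for multi-group additionally the ANOVA table (`F`, `df1`, `df2`, `p`)
#'   and a `pairs` data.frame with raw and Bonferroni-adjusted p-values.
#' @export
group_tests <- function(groups, design = NULL, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  lapply(groups, function(g) stopifnot(inherits(g, "group_sample")))
  sizes <- vapply(groups, function(g) length(g$per_cell_means), 0L)
  if (any(sizes < 2L))
    stop("every group needs at least 2 cells", call. = FALSE)
  if (is.null(design))
    design <- if (length(groups) == 2L) "two-group" else "multi-group"
  design <- match.arg(design, c("two-group", "multi-group"))

  if (design == "two-group") {
    if (length(groups) != 2L)
      stop("two-group design needs exactly two groups", call. = FALSE)
    tt <- stats::t.test(groups[[1L]]$per_cell_means,
                        groups[[2L]]$per_cell_means, var.equal = TRUE)
    return(list(design = design, t = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                significant = tt$p.value < alpha, alpha = alpha))
  }

  vals <- unlist(lapply(groups, `[[`, "per_cell_means"))
  labs <- factor(rep(vapply(groups, `[[`, "", "label"), sizes))
  fit <- stats::aov(vals ~ labs)
  an <- summary(fit)[[1L]]
  mse <- an["Residuals", "Mean Sq"]
  df_res <- an["Residuals", "Df"]

  combos <- utils::combn(length(groups), 2L)
  n_pairs <- ncol(combos)
  pairs <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    i1 <- combos[1L, j]; i2 <- combos[2L, j]
    m1 <- mean(groups[[i1]]$per_cell_means)
    m2 <- mean(groups[[i2]]$per_cell_means)
    se <- sqrt(mse * (1 / sizes[i1] + 1 / sizes[i2]))
    tstat <- (m1 - m2) / se
    p_raw <- 2 * stats::pt(-abs(tstat), df_res)
    data.frame(group_a = groups[[i1]]$label,
               group_b = groups[[i2]]$label,
               t = tstat, df = df_res, p_raw = p_raw,
               p_adj = min(1, p_raw * n_pairs))
  }))
  pairs$significant <- pairs$p_adj < alpha
  list(design = design,
       anova = data.frame(F = an["labs", "F value"],
                          df1 = an["labs", "Df"], df2 = df_res,
                          p = an["labs", "Pr(>F)"]),
       pairs = pairs, alpha = alpha)
}
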