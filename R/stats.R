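#' Mean and sample SD of per-replicate values
#'
#' Data are reported as means plus/minus SD; the SD uses the n-1
#' denominator and is undefined (reported as `NA`) for a single replicate.
#'
#' @param values Numeric vector of per-replicate values (degC).
#' @return Named list `mean`, `sd`, `n`.
#' @export
group_summary <- function(values) {
  if (!length(values)) abort_validation("empty input: no replicate values")
  if (any(!is.finite(values))) abort_validation("values must be finite")
  list(mean = mean(values),
       sd = if (length(values) > 1) stats::sd(values) else NA_real_,
       n = length(values))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Compare replicate groups (one-way ANOVA, Tukey HSD, Student's t)
#'
#' Standard unpaired one-way ANOVA across the groups, with Tukey HSD
#' adjusted pairwise p values when there are three or more groups, and a
#' two-sided Student's t test (equal variances by default; Welch available
#' by flag) when there are exactly two. Significance stars follow the
#' 0.05/0.01/0.001 convention.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @param alpha Significance level used for the verdicts.
#' @param var_equal Equal-variance (Student) t test? `FALSE` gives Welch.
#' @return An object of class `group_comparison` with fields `summary`
#'   (per-group mean/sd/n), `anova` (`F`, `p`, `df`), `tukey_pairs` (data
#'   frame, >= 3 groups), `ttest` (two-group case), `alpha`.
#' @examples
#' compare_groups(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
compare_groups <- function(groups, alpha = 0.05, var_equal = TRUE) {
  if (!is.list(groups) || length(groups) < 2L) {
    abort_validation("groups must be a list of >= 2 value vectors")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    abort_validation("every group needs n >= 2")
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1L]]
  f_stat <- an[["F value"]][1L]
  p_val <- an[["Pr(>F)"]][1L]
  # all observations identical: no between- or within-group variance
  if (stats::var(df$value) == 0) {
    f_stat <- 0
    p_val <- 1
  }

  tukey <- NULL
  if (length(groups) >= 3L) {
    th <- stats::TukeyHSD(fit)$group
    tukey <- data.frame(pair = rownames(th), diff = th[, "diff"],
                        p_adj = th[, "p adj"],
                        stars = significance_stars(th[, "p adj"]),
                        row.names = NULL)
  }

  ttest <- NULL
  if (length(groups) == 2L) {
    if (stats::var(df$value) == 0) {
      ttest <- list(t = 0, p = 1, df = sum(lengths(groups)) - 2, stars = "ns")
    } else {
      tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = var_equal)
      ttest <- list(t = unname(tt$statistic), p = tt$p.value,
                    df = unname(tt$parameter),
                    stars = significance_stars(tt$p.value))
    }
  }

  summ <- do.call(rbind, lapply(names(groups), function(g) {
    s <- group_summary(groups[[g]])
    data.frame(group = g, mean = s$mean, sd = s$sd, n = s$n)
  }))

  structure(
    list(summary = summ,
         anova = list(F = f_stat, p = p_val,
                      df = c(an$Df[1L], an$Df[2L]),
                      stars = significance_stars(p_val)),
         tukey_pairs = tukey, ttest = ttest, alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-12s %.3f +/- %s (n=%d)\n", x$summary$group[i],
                x$summary$mean[i], format(x$summary$sd[i], digits = 3),
                x$summary$n[i]))
  }
  cat(sprintf("  one-way ANOVA: F(%d,%d) = %.4g, p = %.4g %s\n",
              x$anova$df[1], x$anova$df[2], x$anova$F, x$anova$p, x$anova$stars))
  if (!is.null(x$ttest)) {
    cat(sprintf("  Student's t: t = %.4g (df %.4g), p = %.4g %s\n",
                x$ttest$t, x$ttest$df, x$ttest$p, x$ttest$stars))
  }
  if (!is.null(x$tukey_pairs)) {
    cat("  Tukey HSD adjusted pairwise p:\n")
    for (i in seq_len(nrow(x$tukey_pairs))) {
      cat(sprintf("    %-16s diff %8.4g  p_adj %.4g %s\n",
                  x$tukey_pairs$pair[i], x$tukey_pairs$diff[i],
                  x$tukey_pairs$p_adj[i], x$tukey_pairs$stars[i]))
    }
  }
  invisible(x)
}

#' Reconstruct the pre-inhibition mitochondrial temperature
#'
#' Under the calibration assumption that full ATP-synthase inhibition
#' abolishes all mitochondrial heat production, the pre-inhibition
#' mitochondrial temperature is the ambient temperature plus the measured
#' temperature-decrease magnitude. If residual heat production remains,
#' the true temperature is higher, so the value is a lower bound (recorded
#' in the `"assumption"` attribute).
#'
#' @param ambient Ambient (cuvette) temperature, degC.
#' @param decrease_magnitude Measured temperature-decrease magnitude,
#'   degC (>= 0).
#' @return The inferred mitochondrial temperature (degC), with attribute
#'   `assumption`.
#' @examples
#' reconstruct_mito_temperature(37, 17)  # 54
#' @export
reconstruct_mito_temperature <- function(ambient, decrease_magnitude) {
  stopifnot_number(ambient, "ambient", 0, 60)
  if (!is_number(decrease_magnitude) || decrease_magnitude < 0) {
    abort_validation("decrease_magnitude must be >= 0")
  }
  structure(ambient + decrease_magnitude,
            assumption = paste("lower bound: assumes inhibition abolishes all",
                               "mitochondrial heat production"))
}
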