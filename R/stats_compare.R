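#' Paired t comparison between GPS-derived and dead-reckoned metrics
#'
#' Classical paired t-test on the per-night differences (df = n - 1),
#' the test used to compare path lengths and per-class time proportions
#' between the two positioning methods, with badger-nights as pairs.
#' Zero-variance differences are handled explicitly: all-zero gives
#' t = 0, p = 1; constant non-zero gives an infinite statistic with
#' p -> 0 and a `degenerate` flag.
#'
#' @param x,y equal-length numeric series (no missing pairs).
#' @return list of class `badger_test`: `statistic`, `df`, `p_value`,
#'   `estimate` (mean difference), `group_summary` (mean and SD per
#'   series), `method`, `degenerate`.
#' @export
paired_comparison <- function(x, y) {
  if (length(x) != length(y)) stop("paired series differ in length")
  if (anyNA(x) || anyNA(y)) stop("missing pairs are not allowed")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  gs <- data.frame(group = c("x", "y"),
                   mean = c(mean(x), mean(y)),
                   sd = c(stats::sd(x), stats::sd(y)))
  if (stats::sd(d) == 0) {
    degen <- mean(d) != 0
    res <- list(statistic = if (degen) sign(mean(d)) * Inf else 0,
                df = n - 1,
                p_value = if (degen) 0 else 1,
                estimate = mean(d),
                group_summary = gs,
                method = "paired t-test",
                degenerate = degen)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
    res <- list(statistic = unname(tt$statistic),
                df = unname(tt$parameter),
                p_value = tt$p.value,
                estimate = unname(tt$estimate),
                group_summary = gs,
                method = "paired t-test",
                degenerate = FALSE)
  }
  class(res) <- "badger_test"
  res
}

#' Welch's unequal-variance t comparison between individuals
#'
#' Welch's t-test with Welch-Satterthwaite (fractional) degrees of
#' freedom, used for between-animal comparisons of path length and land
#' use.
#'
#' @param a,b numeric series (each n >= 2).
#' @return list of class `badger_test` (fields as [paired_comparison()]).
#' @export
welch_comparison <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  gs <- data.frame(group = c("a", "b"),
                   mean = c(mean(a), mean(b)),
                   sd = c(stats::sd(a), stats::sd(b)))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    degen <- mean(a) != mean(b)
    res <- list(statistic = if (degen) sign(mean(a) - mean(b)) * Inf else 0,
                df = length(a) + length(b) - 2,
                p_value = if (degen) 0 else 1,
                estimate = mean(a) - mean(b),
                group_summary = gs,
                method = "Welch two-sample t-test",
                degenerate = degen)
  } else {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    res <- list(statistic = unname(tt$statistic),
                df = unname(tt$parameter),
                p_value = tt$p.value,
                estimate = unname(diff(rev(tt$estimate))),
                group_summary = gs,
                method = "Welch two-sample t-test",
                degenerate = FALSE)
  }
  class(res) <- "badger_test"
  res
}

#' @export
print.badger_test <- function(x, ...) {
  cat(sprintf("<badger_test> %s: t = %.4g, df = %.4g, p = %.4g%s\n",
              x$method, x$statistic, x$df, x$p_value,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

#' log10(x + 1) transform
#'
#' The shift by 1 accommodates exact zeros (nights with no time near a
#' feature) before log10 transformation, as applied to building and road
#' proportions prior to the land-use models.
#'
#' @param values non-negative numeric vector.
#' @return transformed vector.
#' @export
log10_plus_one <- function(values) {
  if (any(values < 0)) stop("values must be non-negative")
  log10(values + 1)
}

#' One-way land-use model with Tukey HSD post hoc comparisons
#'
#' Linear model `time ~ feature class` (fields / hedges / buildings /
#' roads), overall F and p, followed by all pairwise Tukey honestly
#' significant difference comparisons. Unadjusted pairwise p-values
#' (pooled-variance t on the same model) are reported alongside the
#' Tukey-adjusted ones.
#'
#' @param data data.frame with columns `value` (time or proportion,
#'   already transformed where appropriate) and `class` (feature class).
#' @return list of class `badger_landuse`: `F_statistic`, `df`, `p_value`,
#'   `pairwise` (data.frame: pair, difference, p_raw, p_tukey),
#'   `class_summary`.
#' @export
landuse_model <- function(data) {
  stopifnot(all(c("value", "class") %in% names(data)))
  data$class <- factor(data$class)
  if (nlevels(data$class) < 2) stop("need at least 2 feature classes")
  if (any(table(data$class) < 2)) {
    stop("need at least 2 observations per feature class")
  }
  if (stats::var(data$value) == 0) {
    # no variation at all: no between-class signal
    pairs <- utils::combn(levels(data$class), 2)
    pw <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                     difference = 0, p_raw = 1, p_tukey = 1)
    ns <- table(data$class)
    res <- list(F_statistic = 0,
                df = c(nlevels(data$class) - 1, nrow(data) - nlevels(data$class)),
                p_value = 1, pairwise = pw,
                class_summary = data.frame(class = levels(data$class),
                                           mean = unique(data$value),
                                           n = as.integer(ns)))
    class(res) <- "badger_landuse"
    return(res)
  }
  fit <- stats::aov(value ~ class, data = data)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$class

  mse <- an["Residuals", "Mean Sq"]
  dfres <- an["Residuals", "Df"]
  ns <- table(data$class)
  means <- tapply(data$value, data$class, mean)
  pairs <- utils::combn(levels(data$class), 2)
  pw <- data.frame(
    pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
    difference = means[pairs[2, ]] - means[pairs[1, ]],
    row.names = NULL
  )
  se <- sqrt(mse * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
  tstat <- pw$difference / se
  pw$p_raw <- 2 * stats::pt(-abs(tstat), dfres)
  pw$p_tukey <- tuk[pw$pair, "p adj"]

  res <- list(
    F_statistic = an["class", "F value"],
    df = c(an["class", "Df"], dfres),
    p_value = an["class", "Pr(>F)"],
    pairwise = pw,
    class_summary = data.frame(class = names(means),
                               mean = as.numeric(means),
                               n = as.integer(ns[names(means)]))
  )
  class(res) <- "badger_landuse"
  res
}

#' @export
print.badger_landuse <- function(x, ...) {
  cat(sprintf("<badger_landuse> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$F_statistic, x$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
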