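#' Root-mean-square error
#'
#' @param predicted Numeric vector.
#' @param measured Numeric vector of the same length.
#' @return `sqrt(mean((predicted - measured)^2))`.
#' @export
rmse <- function(predicted, measured) {
  if (length(predicted) != length(measured) || length(predicted) == 0) {
    stop("predicted and measured must be equal-length, non-empty vectors",
         call. = FALSE)
  }
  sqrt(mean((predicted - measured)^2))
}

#' Bland-Altman agreement analysis
#'
#' Differences `estimated - measured`; bias is their mean, and the 95%
#' limits of agreement are bias +/- 1.96 times their sample standard
#' deviation. Also counts points falling outside the limits.
#'
#' @param estimated Numeric vector.
#' @param measured Paired numeric vector, `n >= 2`.
#' @return Object of class `bland_altman`: `bias`, `loa_low`, `loa_high`,
#'   `n_outside`, plus the paired `means` and `differences` for plotting.
#' @export
bland_altman <- function(estimated, measured) {
  if (length(estimated) != length(measured)) {
    stop("estimated and measured must be paired", call. = FALSE)
  }
  if (length(estimated) < 2) stop("need at least two pairs", call. = FALSE)
  d <- estimated - measured
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * s
  structure(
    list(bias = bias, loa_low = loa[1], loa_high = loa[2],
         n_outside = sum(d < loa[1] | d > loa[2]),
         means = (estimated + measured) / 2, differences = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, 95%% LoA [%.3f, %.3f], %d of %d outside\n",
              x$bias, x$loa_low, x$loa_high, x$n_outside, length(x$differences)))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param x A [bland_altman()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$differences,
                 xlab = "Mean of estimated and measured",
                 ylab = "Difference (estimated - measured)", ...)
  graphics::abline(h = x$bias, col = "blue")
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  invisible(x)
}

#' Group summary statistics
#'
#' Sample size, mean and sample (n-1) standard deviation, either given
#' directly (as when only published summary rows are available) or computed
#' from raw observations.
#'
#' @param x Raw numeric vector, or `NULL` when `n`, `mean`, `sd` are given.
#' @param n,mean,sd Summary values when `x` is `NULL`.
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(x = NULL, n = NULL, mean = NULL, sd = NULL) {
  if (!is.null(x)) {
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  }
  if (is.null(n) || is.null(mean) || is.null(sd)) {
    stop("supply raw data or all of n, mean, sd", call. = FALSE)
  }
  if (n < 2 || sd < 0) stop("need n >= 2 and sd >= 0", call. = FALSE)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Pool stratified group summaries into one group
#'
#' Combines per-stratum summaries (for example sex-stratified published
#' rows) into a single group: the combined mean is the size-weighted mean,
#' and the combined sum of squares adds the within-stratum sums of squares
#' and the between-stratum terms `n_k (mean_k - combined mean)^2`.
#'
#' @param ... [group_summary()] objects (or a single list of them).
#' @return A pooled [group_summary()].
#' @export
pool_summaries <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && !inherits(gs[[1]], "group_summary")) gs <- gs[[1]]
  n <- vapply(gs, `[[`, 0, "n")
  m <- vapply(gs, `[[`, 0, "mean")
  s <- vapply(gs, `[[`, 0, "sd")
  ntot <- sum(n)
  mtot <- sum(n * m) / ntot
  ss <- sum((n - 1) * s^2) + sum(n * (m - mtot)^2)
  group_summary(n = ntot, mean = mtot, sd = sqrt(ss / (ntot - 1)))
}

#' Independent-samples t statistic from raw data or summaries
#'
#' Pooled-variance or Welch t statistic between two groups given either raw
#' vectors or [group_summary()] objects. The summary path exists because
#' published tables often report only mean +/- SD per group.
#'
#' @param group_a,group_b Numeric vectors or [group_summary()] objects.
#' @param variant `"pooled"` (df = n_a + n_b - 2) or `"welch"`
#'   (Welch-Satterthwaite df).
#' @return List with `t`, `df`, `variant`. When both variances are zero and
#'   the means equal, `t` is defined as 0.
#' @export
independent_t <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  as_gs <- function(g) if (inherits(g, "group_summary")) g else group_summary(g)
  a <- as_gs(group_a); b <- as_gs(group_b)
  delta <- a$mean - b$mean
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- if (se == 0) a$n + b$n - 2 else {
      (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    }
  }
  t <- if (se == 0) {
    if (delta == 0) 0 else sign(delta) * Inf
  } else delta / se
  list(t = t, df = df, variant = variant)
}

#' Screen groups for normality and variance homogeneity
#'
#' Runs a Shapiro-Wilk test per group and Levene's test across groups
#' (standard implementations), and recommends the pooled t-test when
#' Levene's p >= 0.05 and Welch otherwise.
#'
#' @param groups Named list of raw numeric vectors.
#' @param alpha Decision level for the Levene test (default 0.05).
#' @return List with `shapiro_p` (named vector; `NA` with a warning for
#'   groups of fewer than 3 observations), `levene_p`, and `recommendation`
#'   (`"pooled"` or `"welch"`).
#' @export
group_screen <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups))) names(groups) <- paste0("group_", seq_along(groups))
  shapiro_p <- vapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) < 3) {
      warning("group '", g, "' has fewer than 3 observations; ",
              "normality test skipped", call. = FALSE)
      return(NA_real_)
    }
    stats::shapiro.test(x)$p.value
  }, 0)
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)))
  lev <- car::leveneTest(values, labels)
  levene_p <- lev[["Pr(>F)"]][1]
  list(shapiro_p = shapiro_p, levene_p = levene_p,
       recommendation = if (is.na(levene_p) || levene_p >= alpha) "pooled" else "welch")
}
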