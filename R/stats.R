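#' Summarize residual error vectors
#'
#' Per-axis mean absolute error and SD, plus a magnitude row computed from
#' the per-sample Euclidean norms (so the magnitude mean is generally larger
#' than the norm of the per-axis means). SDs are population SDs of the
#' absolute values.
#'
#' @param residuals Tibble or data frame with columns `x`, `y`, `z` (um);
#'   columns named `c_x`, `c_y`, `c_z` (as produced by [make_error_record()])
#'   are also accepted.
#' @return A tibble with columns `component` (`"x"`, `"y"`, `"z"`,
#'   `"magnitude"`), `mae`, and `sd`.
#' @export
#' @examples
#' error_summary(tibble::tibble(x = 3, y = 4, z = 0))
error_summary <- function(residuals) {
  if (all(c("c_x", "c_y", "c_z") %in% names(residuals))) {
    residuals <- tibble::tibble(x = residuals$c_x, y = residuals$c_y,
                                z = residuals$c_z)
  }
  stopifnot(nrow(residuals) >= 1, all(c("x", "y", "z") %in% names(residuals)))
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mag <- sqrt(residuals$x^2 + residuals$y^2 + residuals$z^2)
  comp <- list(x = abs(residuals$x), y = abs(residuals$y),
               z = abs(residuals$z), magnitude = mag)
  tibble::tibble(
    component = names(comp),
    mae = unname(vapply(comp, mean, numeric(1))),
    sd = unname(vapply(comp, pop_sd, numeric(1)))
  )
}

as_2x2_counts <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    counts <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  } else {
    counts <- as.numeric(table)
  }
  stopifnot(length(counts) == 4, all(counts >= 0),
            all(counts == round(counts)))
  counts
}

#' Fisher's exact test for a 2 x 2 contingency table
#'
#' Two-sided exact p-value by summing, over all tables with the observed
#' margins, the hypergeometric point probabilities that do not exceed the
#' observed table's probability (with a relative tolerance factor of
#' 1 + 1e-7, the convention of mainstream statistics libraries). A table
#' with a zero margin carries no information and returns p = 1.
#'
#' @param table A 2 x 2 matrix `rbind(c(s1, f1), c(s2, f2))` of successes
#'   and failures for two groups, or the four counts in that order.
#' @return The two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(rbind(c(21, 11), c(36, 0))) # ~8e-5
fisher_exact_2x2 <- function(table) {
  cts <- as_2x2_counts(table)
  a <- cts[1]; b <- cts[2]; cc <- cts[3]; dd <- cts[4]
  m <- a + b; n <- cc + dd; k <- a + cc
  if (m == 0 || n == 0 || k == 0 || (b + dd) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

as_group_list <- function(data, values = NULL, groups = NULL) {
  if (is.list(data) && !is.data.frame(data)) return(data)
  stopifnot(is.data.frame(data))
  values <- values %||% "value"
  groups <- groups %||% "group"
  split(data[[values]], data[[groups]])
}

#' One-way analysis of variance across groups
#'
#' Standard fixed-effects decomposition via [stats::aov()]. The degenerate
#' all-groups-identical case (zero between- and within-group variance) is
#' reported as F = 0, p = 1 rather than 0/0.
#'
#' @param data A data frame with `value` and `group` columns, or a list of
#'   numeric vectors (one per group).
#' @param values,groups Column names when `data` is a data frame.
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @export
one_way_anova <- function(data, values = NULL, groups = NULL) {
  gl <- as_group_list(data, values, groups)
  stopifnot(length(gl) >= 2, all(vapply(gl, length, integer(1)) >= 2))
  df <- data.frame(
    value = unlist(gl, use.names = FALSE),
    group = factor(rep(names(gl) %||% seq_along(gl),
                       vapply(gl, length, integer(1))))
  )
  if (stats::var(df$value) <= 1e-25 * (1 + mean(df$value)^2)) {
    # all observations identical: no variance to decompose
    return(tibble::tibble(statistic = 0, df_between = nlevels(df$group) - 1L,
                          df_within = nrow(df) - nlevels(df$group),
                          p_value = 1))
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  tibble::tibble(statistic = tab[["F value"]][1],
                 df_between = tab[["Df"]][1],
                 df_within = tab[["Df"]][2],
                 p_value = tab[["Pr(>F)"]][1])
}

#' Tukey's honestly-significant-difference test
#'
#' Pairwise group comparisons with studentized-range adjusted p-values, via
#' [stats::TukeyHSD()] on the one-way fit.
#'
#' @inheritParams one_way_anova
#' @return A tibble with `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `adj_p_value`.
#' @export
tukey_hsd <- function(data, values = NULL, groups = NULL) {
  gl <- as_group_list(data, values, groups)
  stopifnot(length(gl) >= 2, all(vapply(gl, length, integer(1)) >= 2))
  df <- data.frame(
    value = unlist(gl, use.names = FALSE),
    group = factor(rep(names(gl) %||% seq_along(gl),
                       vapply(gl, length, integer(1))))
  )
  if (stats::var(df$value) <= 1e-25 * (1 + mean(df$value)^2)) {
    pairs <- utils::combn(levels(df$group), 2)
    return(tibble::tibble(
      contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
      estimate = 0, conf_low = 0, conf_high = 0, adj_p_value = 1
    ))
  }
  tk <- stats::TukeyHSD(stats::aov(value ~ group, data = df))$group
  tibble::tibble(
    contrast = rownames(tk), estimate = tk[, "diff"],
    conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
    adj_p_value = tk[, "p adj"]
  )
}

#' D'Agostino-Pearson K-squared normality test
#'
#' Two-sided chi-squared test combining skewness and kurtosis: the sample
#' skewness and kurtosis are transformed to approximately standard-normal
#' statistics (D'Agostino's skewness transformation; Anscombe-Glynn for
#' kurtosis), and `K2 = Z1^2 + Z2^2` is referred to a chi-squared
#' distribution with 2 degrees of freedom. The approximations require
#' n >= 20.
#'
#' @param x Numeric sample, n >= 20.
#' @return A one-row tibble: `statistic` (K2), `z_skewness`, `z_kurtosis`,
#'   `p_value`, `n`.
#' @export
dagostino_k2 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) stop("dagostino_k2 requires n >= 20", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("sample is constant", call. = FALSE)
  b1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2
  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis: Anscombe & Glynn (1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - e_b2) / sqrt(var_b2)
  sqrt_beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrt_beta1 * (2 / sqrt_beta1 + sqrt(1 + 4 / sqrt_beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  tibble::tibble(statistic = k2, z_skewness = z1, z_kurtosis = z2,
                 p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE), n = n)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Success-rate comparison report for two detection methods
#'
#' For each experiment stage, reports the two groups' success percentages
#' (integer-rounded), the relative improvement of group 2 over group 1
#' computed from the exact count fractions
#' `100 * (s2/n2 - s1/n1) / (s1/n1)`, and the two-sided
#' [fisher_exact_2x2()] p-value. Percent rounding is half-away-from-zero by
#' default; `"truncate"` floors instead.
#'
#' @param counts A tibble with columns `stage`, `s1`, `n1`, `s2`, `n2`
#'   (successes and attempts for the two methods).
#' @param rounding `"half_away"` or `"truncate"`.
#' @return A tibble with one row per stage: rates, `improvement_pct`
#'   (`NA` when the baseline rate is zero), and `fisher_p`.
#' @export
#' @examples
#' success_rate_report(tibble::tibble(
#'   stage = "pipette_detection", s1 = 21, n1 = 32, s2 = 36, n2 = 36
#' ))
success_rate_report <- function(counts, rounding = c("half_away", "truncate")) {
  rounding <- match.arg(rounding)
  stopifnot(all(c("stage", "s1", "n1", "s2", "n2") %in% names(counts)),
            all(counts$s1 <= counts$n1), all(counts$s2 <= counts$n2),
            all(counts$n1 > 0), all(counts$n2 > 0))
  rnd <- if (rounding == "half_away") round_half_away else floor
  p1 <- counts$s1 / counts$n1
  p2 <- counts$s2 / counts$n2
  improvement <- ifelse(p1 > 0, rnd(100 * (p2 - p1) / p1), NA_real_)
  fisher <- purrr::map_dbl(seq_len(nrow(counts)), function(i) {
    fisher_exact_2x2(rbind(
      c(counts$s1[i], counts$n1[i] - counts$s1[i]),
      c(counts$s2[i], counts$n2[i] - counts$s2[i])
    ))
  })
  tibble::tibble(
    stage = counts$stage,
    s1 = counts$s1, n1 = counts$n1, s2 = counts$s2, n2 = counts$n2,
    rate1_pct = rnd(100 * p1), rate2_pct = rnd(100 * p2),
    improvement_pct = improvement,
    fisher_p = fisher
  )
}

#' Reference success counts for the CNN vs cross-correlation comparison
#'
#' The published attempt counts for the two pipette-detection methods on an
#' automated patch-clamp rig: n = 32 attempts with cross-correlation
#' (success rates 66% / 59% / 37% for pipette detection, cell detection, and
#' whole-cell recording) and n = 36 with the CNN (100% / 92% / 64%),
#' recovered as integer counts 21/19/12 of 32 and 36/33/23 of 36.
#'
#' @return A tibble with columns `stage`, `s1`, `n1`, `s2`, `n2` (group 1 =
#'   cross-correlation, group 2 = CNN), suitable for
#'   [success_rate_report()].
#' @export
reference_success_counts <- function() {
  tibble::tibble(
    stage = c("pipette_detection", "cell_detection", "whole_cell"),
    s1 = c(21, 19, 12), n1 = c(32, 32, 32),
    s2 = c(36, 33, 23), n2 = c(36, 36, 36)
  )
}
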