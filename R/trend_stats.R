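# Step-down many-to-one trend tests: Williams' test on the observations,
# its rank-based Shirley-Williams analogue, the variance-heterogeneity gate
# that chooses between them, and two-group t / Wilcoxon comparisons.
# Critical values for the step statistics come from a seeded Monte-Carlo
# null (cached), validated against the closed-form k = 1 Student t limit.

.crit_cache <- new.env(parent = emptyenv())

#' Dose-response series
#'
#' Per-well metric observations for a control group and dose groups in
#' strictly increasing dose order, with the hypothesized trend direction.
#'
#' @param control numeric observations of the control group
#' @param doses named list of numeric observations, one per dose group,
#'   ordered by increasing dose
#' @param direction "decreasing" (toxicant suppresses the metric) or
#'   "increasing" (rescue restores it)
#' @return a `dose_series` list
#' @export
dose_series <- function(control, doses,
                        direction = c("decreasing", "increasing")) {
  direction <- match.arg(direction)
  stopifnot(is.list(doses), length(doses) >= 1)
  if (length(control) < 2 || any(vapply(doses, length, 1L) < 2)) {
    stop("every group needs at least 2 observations")
  }
  if (is.null(names(doses))) names(doses) <- paste0("dose", seq_along(doses))
  structure(list(control = as.numeric(control),
                 doses = lapply(doses, as.numeric),
                 direction = direction), class = "dose_series")
}

#' Pool-adjacent-violators isotonic means
#'
#' Weighted isotonic regression of the group means in the stated direction
#' by adjacent pooling; the pooled weighted mean is preserved.
#'
#' @param means group means in dose order
#' @param weights group sizes (weights)
#' @param direction "increasing" or "decreasing"
#' @return amalgamated means, monotone in `direction`
#' @export
pava_isotonic_means <- function(means, weights = rep(1, length(means)),
                                direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  stopifnot(length(means) == length(weights), all(weights > 0))
  s <- if (direction == "decreasing") -1 else 1
  x <- s * means
  # stack of blocks (value, weight, count)
  val <- numeric(0); wt <- numeric(0); cnt <- integer(0)
  for (i in seq_along(x)) {
    val <- c(val, x[i]); wt <- c(wt, weights[i]); cnt <- c(cnt, 1L)
    while (length(val) > 1 &&
           val[length(val) - 1] > val[length(val)]) {
      n <- length(val)
      v <- (val[n - 1] * wt[n - 1] + val[n] * wt[n]) / (wt[n - 1] + wt[n])
      w2 <- wt[n - 1] + wt[n]; c2 <- cnt[n - 1] + cnt[n]
      val <- c(val[seq_len(n - 2)], v)
      wt <- c(wt[seq_len(n - 2)], w2)
      cnt <- c(cnt[seq_len(n - 2)], c2)
    }
  }
  s * rep(val, cnt)
}

# Williams' amalgamated estimate for the top group only:
# max over u of the weighted mean of groups u..j (increasing direction).
amalgamated_top <- function(means, weights, j) {
  ws <- rev(cumsum(rev(means[1:j] * weights[1:j])))
  ww <- rev(cumsum(rev(weights[1:j])))
  max(ws / ww)
}

#' Monte-Carlo critical value for the Williams step statistic
#'
#' For k = 1 the statistic is the two-sample t statistic and the one-sided
#' Student t quantile is returned in closed form. For k > 1 the null
#' quantile of the step statistic (amalgamated top-group mean vs control,
#' scaled by the pooled-variance standard error) is estimated from seeded
#' standard-normal Monte-Carlo replicates and cached per design.
#'
#' @param k number of dose groups in play
#' @param df degrees of freedom of the pooled variance (Inf for the
#'   rank-based analogue)
#' @param alpha one-sided level
#' @param n per-dose-group sizes (length k; recycled if scalar)
#' @param n0 control group size
#' @param n_mc Monte-Carlo replicates
#' @param seed RNG seed for the Monte-Carlo draw
#' @return the critical value
#' @export
critical_values_williams <- function(k, df, alpha = 0.025, n = 6, n0 = NULL,
                                     n_mc = 100000L, seed = 186283L) {
  stopifnot(k >= 1)
  n <- rep(n, length.out = k)
  if (is.null(n0)) n0 <- n[1]
  if (k == 1) {
    return(if (is.finite(df)) stats::qt(1 - alpha, df) else
      stats::qnorm(1 - alpha))
  }
  key <- paste(k, df, alpha, paste(n, collapse = ","), n0, n_mc, seed,
               sep = "|")
  if (!is.null(.crit_cache[[key]])) return(.crit_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x0 <- stats::rnorm(n_mc, 0, sqrt(1 / n0))
  xm <- matrix(stats::rnorm(n_mc * k), n_mc, k) %*% diag(1 / sqrt(n), k)
  s2 <- if (is.finite(df)) stats::rchisq(n_mc, df) / df else rep(1, n_mc)
  # amalgamated top mean, vectorized over replicates
  ws <- sweep(xm, 2, n, `*`)
  best <- rep(-Inf, n_mc)
  for (u in k:1) {
    num <- rowSums(ws[, u:k, drop = FALSE])
    den <- sum(n[u:k])
    best <- pmax(best, num / den)
  }
  t_stat <- (best - x0) / sqrt(s2 * (1 / n[k] + 1 / n0))
  cv <- as.numeric(stats::quantile(t_stat, 1 - alpha, type = 8))
  .crit_cache[[key]] <- cv
  cv
}

trend_result <- function(series, rows, test, alpha, het_p = NA_real_) {
  structure(list(table = rows, test = test, alpha = alpha,
                 direction = series$direction, heterogeneity_p = het_p),
            class = "trend_result")
}

#' Williams' step-down trend test
#'
#' Tests each dose against the control assuming a monotone dose effect,
#' stepping down from the highest dose. At step j the statistic is the
#' amalgamated (isotonic) mean of dose j minus the control mean, divided by
#' the pooled-variance standard error; it is compared to the one-sided
#' Williams-type critical value for j groups. The step-down stops at the
#' first non-significant dose, so significance is coherent in dose.
#'
#' @param series a [dose_series]
#' @param alpha one-sided level (0.025 by default)
#' @param n_mc,seed Monte-Carlo settings for [critical_values_williams]
#' @return a `trend_result`
#' @export
williams_test <- function(series, alpha = 0.025, n_mc = 100000L,
                          seed = 186283L) {
  stopifnot(inherits(series, "dose_series"))
  sgn <- if (series$direction == "decreasing") -1 else 1
  x0 <- sgn * series$control
  xs <- lapply(series$doses, function(v) sgn * v)
  k <- length(xs)
  n <- vapply(xs, length, 1L); n0 <- length(x0)
  groups <- c(list(x0), xs)
  ss <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  df <- sum(vapply(groups, length, 1L)) - (k + 1)
  s2 <- ss / df
  means <- vapply(xs, mean, 1)
  rows <- data.frame(dose = names(series$doses), statistic = NA_real_,
                     critical = NA_real_, significant = FALSE)
  stop_down <- FALSE
  for (j in k:1) {
    if (stop_down) break
    mu_j <- amalgamated_top(means, n, j)
    se <- sqrt(s2 * (1 / n[j] + 1 / n0))
    t_j <- if (se > 0) (mu_j - mean(x0)) / se else 0
    cv <- critical_values_williams(j, df, alpha, n = n[1:j], n0 = n0,
                                   n_mc = n_mc, seed = seed)
    rows$statistic[j] <- t_j
    rows$critical[j] <- cv
    if (t_j > cv) rows$significant[j] <- TRUE else stop_down <- TRUE
  }
  trend_result(series, rows, "williams", alpha)
}

#' Shirley-Williams rank-based step-down trend test
#'
#' Nonparametric analogue of [williams_test]: at each step the control and
#' the doses still in play are jointly re-ranked (midranks for ties), the
#' amalgamated mean rank of the top dose is compared to the control mean
#' rank with the rank-variance scaling, against Williams-type critical
#' values with infinite degrees of freedom. Invariant under strictly
#' increasing transforms of the observations.
#'
#' @inheritParams williams_test
#' @return a `trend_result`
#' @export
shirley_williams_test <- function(series, alpha = 0.025, n_mc = 100000L,
                                  seed = 186283L) {
  stopifnot(inherits(series, "dose_series"))
  sgn <- if (series$direction == "decreasing") -1 else 1
  x0 <- sgn * series$control
  xs <- lapply(series$doses, function(v) sgn * v)
  k <- length(xs)
  n <- vapply(xs, length, 1L); n0 <- length(x0)
  rows <- data.frame(dose = names(series$doses), statistic = NA_real_,
                     critical = NA_real_, significant = FALSE)
  stop_down <- FALSE
  for (j in k:1) {
    if (stop_down) break
    pool <- c(x0, unlist(xs[1:j]))
    rk <- rank(pool)  # midranks
    nn <- length(pool)
    r0 <- mean(rk[seq_len(n0)])
    gm <- numeric(j)
    off <- n0
    for (g in 1:j) {
      gm[g] <- mean(rk[(off + 1):(off + n[g])])
      off <- off + n[g]
    }
    ties <- table(rk)
    tie_corr <- 1 - sum(ties^3 - ties) / (nn^3 - nn)
    v <- nn * (nn + 1) / 12 * tie_corr
    rbar_j <- amalgamated_top(gm, n, j)
    se <- sqrt(v * (1 / n[j] + 1 / n0))
    t_j <- if (se > 0) (rbar_j - r0) / se else 0
    cv <- critical_values_williams(j, Inf, alpha, n = n[1:j], n0 = n0,
                                   n_mc = n_mc, seed = seed)
    rows$statistic[j] <- t_j
    rows$critical[j] <- cv
    if (t_j > cv) rows$significant[j] <- TRUE else stop_down <- TRUE
  }
  trend_result(series, rows, "shirley_williams", alpha)
}

#' Variance-heterogeneity gate
#'
#' Chooses between the parametric and the rank-based trend test: Bartlett's
#' test across all groups (control included); heterogeneous variances
#' (p < alpha_het) select the Shirley-Williams test, otherwise Williams'.
#' A zero-variance group makes Bartlett degenerate: when all groups are
#' constant the equal-variances convention (p = 1) keeps Williams';
#' otherwise the gate falls back to the rank test with a warning.
#'
#' @param series a [dose_series]
#' @param alpha_het level of Bartlett's test
#' @return list(test = "williams"|"shirley_williams", p = Bartlett p-value)
#' @export
heterogeneity_gate <- function(series, alpha_het = 0.05) {
  stopifnot(inherits(series, "dose_series"))
  groups <- c(list(series$control), series$doses)
  vars <- vapply(groups, stats::var, 1)
  if (all(vars == 0)) {
    return(list(test = "williams", p = 1))
  }
  if (any(vars == 0)) {
    warning("zero-variance group; falling back to Shirley-Williams")
    return(list(test = "shirley_williams", p = NA_real_))
  }
  vals <- unlist(groups)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  p <- stats::bartlett.test(vals, grp)$p.value
  list(test = if (p < alpha_het) "shirley_williams" else "williams", p = p)
}

#' Run the gated trend test
#'
#' Convenience wrapper: [heterogeneity_gate] then the selected test.
#'
#' @inheritParams williams_test
#' @param alpha_het level of the heterogeneity gate
#' @return a `trend_result` (the gate's p-value is recorded)
#' @export
trend_test <- function(series, alpha = 0.025, alpha_het = 0.05,
                       n_mc = 100000L, seed = 186283L) {
  gate <- heterogeneity_gate(series, alpha_het)
  res <- if (gate$test == "williams") {
    williams_test(series, alpha, n_mc, seed)
  } else {
    shirley_williams_test(series, alpha, n_mc, seed)
  }
  res$heterogeneity_p <- gate$p
  res
}

#' Two-group comparison (Student t or Wilcoxon rank sum)
#'
#' Two-sided comparison of a treated group against control: Student's t
#' with pooled variance when the F-test finds the variances homogeneous at
#' the 0.05 level, the Wilcoxon rank-sum test otherwise. The choice can be
#' forced with `method`.
#'
#' @param control,treated numeric observations
#' @param alpha significance level (0.05 by default)
#' @param method "auto", "t" or "wilcoxon"
#' @return list(p, significant, method)
#' @export
two_group_test <- function(control, treated, alpha = 0.05,
                           method = c("auto", "t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(control) < 2 || length(treated) < 2) {
    stop("each group needs at least 2 observations")
  }
  if (stats::var(control) == 0 && stats::var(treated) == 0 &&
      mean(control) == mean(treated) && method == "auto") {
    # identical constant groups: no evidence either way
    return(list(p = 1, significant = FALSE, method = "wilcoxon"))
  }
  if (method == "auto") {
    if (stats::var(control) == 0 || stats::var(treated) == 0) {
      # degenerate spread: the F-test is undefined, fall back to ranks
      method <- "wilcoxon"
    } else {
      fp <- stats::var.test(control, treated)$p.value
      method <- if (fp < 0.05) "wilcoxon" else "t"
    }
  }
  p <- if (method == "t") {
    stats::t.test(control, treated, var.equal = TRUE)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(control, treated,
                                        exact = NULL)$p.value)
  }
  list(p = p, significant = p < alpha, method = method)
}
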