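#' Group summary triple (mean, SD, n)
#'
#' The `(mean, sample SD, n)` triple in which results are printed
#' ("0.36 +/- 0.13 SD, n = 8") and from which summary-statistic tests are
#' computed.
#'
#' @param mean group mean.
#' @param sd sample standard deviation (n - 1 denominator), >= 0.
#' @param n group size.
#' @return object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), sd >= 0, n >= 1)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' @rdname group_summary
#' @param x numeric vector to summarize (for `summarize_group`), or object
#'   to print.
#' @param ... unused.
#' @export
summarize_group <- function(x) {
  x <- x[!is.na(x)]
  group_summary(mean(x), if (length(x) > 1) stats::sd(x) else 0, length(x))
}

#' @rdname group_summary
#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.4g ± %.4g SD (n = %d)\n", x$mean, x$sd, x$n))
  invisible(x)
}

test_result <- function(statistic, df, p, method, note = NULL) {
  structure(list(statistic = statistic, df = df, p = p, method = method,
                 note = note),
            class = "telo_test")
}

#' @export
print.telo_test <- function(x, ...) {
  stat_name <- if (x$method %in% c("anova", "tukey")) "F/q" else "t"
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

as_group_summary <- function(g) {
  if (inherits(g, "group_summary")) return(g)
  if (is.list(g) && all(c("mean", "sd", "n") %in% names(g)))
    return(group_summary(g$mean, g$sd, g$n))
  if (is.numeric(g) && length(g) == 3)
    return(group_summary(g[1], g[2], g[3]))
  stop("expected a group_summary or (mean, sd, n)", call. = FALSE)
}

#' Two-sample t-test from summary statistics
#'
#' Student (pooled-variance) or Welch two-sample t-test computed from two
#' `(mean, SD, n)` triples, with a two-sided p-value. This is the form in
#' which published comparisons can be re-derived when only the printed
#' summaries are available.
#'
#' @param a,b [group_summary()] objects (or `c(mean, sd, n)` vectors).
#' @param variant `"student"` (pooled variance, df = n_a + n_b - 2) or
#'   `"welch"` (Satterthwaite df).
#' @return a `telo_test` with fields statistic, df, p, method. If both SDs
#'   are zero the convention p = 1 (equal means) or p = 0 (unequal means) is
#'   applied and noted.
#' @export
t_from_summary <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as_group_summary(a); b <- as_group_summary(b)
  if (a$n < 2 || b$n < 2) stop("each group needs n >= 2", call. = FALSE)
  if (a$sd == 0 && b$sd == 0) {
    equal <- isTRUE(all.equal(a$mean, b$mean))
    note <- "both SDs zero; degenerate p by convention"
    message(note)
    return(test_result(if (equal) 0 else Inf,
                       if (variant == "student") a$n + b$n - 2 else NA_real_,
                       if (equal) 1 else 0, variant, note))
  }
  d <- a$mean - b$mean
  if (variant == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- d / se
  test_result(t, df, 2 * stats::pt(-abs(t), df), variant)
}

#' Two-sample t-test on raw values
#'
#' Identical by construction to [t_from_summary()] applied to the two
#' samples' own summaries.
#'
#' @param x,y numeric samples (each n >= 2 after NA removal).
#' @param variant `"student"` or `"welch"`.
#' @return a `telo_test`.
#' @export
t_unpaired <- function(x, y, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  t_from_summary(summarize_group(x), summarize_group(y), variant)
}

#' Paired t-test
#'
#' One-sample t-test on within-pair differences (df = n_pairs - 1,
#' two-sided). Incomplete pairs (either side `NA`) are dropped with a
#' message recording the count.
#'
#' @param u,v paired numeric vectors of equal length.
#' @return a `telo_test` with method `"paired"`.
#' @export
t_paired <- function(u, v) {
  if (length(u) != length(v)) stop("u and v must pair up", call. = FALSE)
  keep <- !(is.na(u) | is.na(v))
  if (any(!keep))
    message("dropped ", sum(!keep), " incomplete pair(s)")
  d <- u[keep] - v[keep]
  n <- length(d)
  if (n < 2) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    note <- "all differences identical; degenerate p by convention"
    message(note)
    return(test_result(if (mean(d) == 0) 0 else Inf, n - 1,
                       if (mean(d) == 0) 1 else 0, "paired", note))
  }
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  test_result(t, n - 1, 2 * stats::pt(-abs(t), n - 1), "paired")
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs n >= 2", call. = FALSE)
  groups
}

#' One-way ANOVA
#'
#' Fixed-effects one-way analysis of variance; F with (k - 1, N - k)
#' degrees of freedom. With two groups, F equals the square of the pooled
#' two-sample t statistic and the p-values coincide.
#'
#' @param groups list of numeric vectors (k >= 2, each n >= 2).
#' @return a `telo_test` with method `"anova"`, `df = c(k - 1, N - k)`.
#' @export
anova_oneway <- function(groups) {
  groups <- check_groups(groups)
  vals <- unlist(groups)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (stats::var(vals) == 0) {
    note <- "all observations identical; F = 0 by convention"
    message(note)
    return(test_result(0, c(length(groups) - 1,
                            length(vals) - length(groups)), 1,
                       "anova", note))
  }
  ft <- stats::oneway.test(vals ~ fac, var.equal = TRUE)
  test_result(unname(ft$statistic), unname(ft$parameter), ft$p.value,
              "anova")
}

# Upper tail of the studentized range distribution with k groups and df
# error degrees of freedom, by direct numerical integration of the defining
# double integral (absolute error well below 1e-6; stats::ptukey is only
# accurate to ~1e-4, which breaks the exact k = 2 reduction to the t-test).
ptukey_upper <- function(q, k, df) {
  if (!is.finite(q)) return(if (q > 0) 0 else 1)
  if (q <= 0) return(1)
  pr_range_scaled <- function(u) {  # P(range of k std normals <= q * u)
    vapply(u, function(ui) {
      f <- function(z) stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * ui))^(k - 1)
      k * stats::integrate(f, -9, 9, rel.tol = 1e-11,
                           abs.tol = 1e-13)$value
    }, 1)
  }
  ln_c <- (df / 2) * log(df / 2) - lgamma(df / 2) + log(2)
  dchi <- function(u) exp(ln_c + (df - 1) * log(u) - df * u^2 / 2)
  cdf <- stats::integrate(function(u) dchi(u) * pr_range_scaled(u),
                          0, Inf, rel.tol = 1e-10)$value
  min(1, max(0, 1 - cdf))
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group comparisons after one-way ANOVA, with p-values from
#' the studentized range distribution on (k, N - k) degrees of freedom
#' (Tukey-Kramer standard error for unbalanced groups), evaluated by
#' numerical integration. With k = 2 the adjusted p equals the pooled
#' t-test p (q = t * sqrt(2)).
#'
#' @param groups list of numeric vectors (k >= 2, each n >= 2); names are
#'   used as group labels when present.
#' @return data.frame with one row per pair: group_a, group_b, diff,
#'   statistic (q), df1 (k), df2 (N - k), p.
#' @export
tukey_hsd <- function(groups) {
  groups <- check_groups(groups)
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  ns <- vapply(groups, length, 1L)
  ms <- vapply(groups, mean, 1)
  N <- sum(ns)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1))
  mse <- ssw / (N - k)
  pairs <- utils::combn(k, 2)
  out <- data.frame(group_a = nm[pairs[1, ]], group_b = nm[pairs[2, ]],
                    diff = ms[pairs[1, ]] - ms[pairs[2, ]],
                    statistic = NA_real_, df1 = k, df2 = N - k,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
    if (se == 0) {
      out$statistic[j] <- if (out$diff[j] == 0) 0 else Inf
      out$p[j] <- if (out$diff[j] == 0) 1 else 0
    } else {
      q <- abs(out$diff[j]) / se
      out$statistic[j] <- q
      out$p[j] <- ptukey_upper(q, k, N - k)
    }
  }
  rownames(out) <- NULL
  out
}

#' Pool group summaries
#'
#' Combines `(mean, SD, n)` triples into the summary of the concatenated
#' sample: `N = sum n_i`, weighted mean, and combined sample variance
#' `[sum (n_i - 1) s_i^2 + sum n_i (m_i - m)^2] / (N - 1)`.
#'
#' @param parts list of [group_summary()] objects (or `c(mean, sd, n)`).
#' @return a `group_summary` of the pooled sample.
#' @export
pooled_group_summary <- function(parts) {
  stopifnot(length(parts) >= 1)
  parts <- lapply(parts, as_group_summary)
  if (length(parts) == 1) return(parts[[1]])
  ns <- vapply(parts, function(p) p$n, 1L)
  ms <- vapply(parts, function(p) p$mean, 1)
  ss <- vapply(parts, function(p) p$sd, 1)
  N <- sum(ns)
  m <- sum(ns * ms) / N
  v <- (sum((ns - 1) * ss^2) + sum(ns * (ms - m)^2)) / (N - 1)
  group_summary(m, sqrt(v), N)
}

#' Positive-to-negative cell ratio
#'
#' Ratio of marker-positive to marker-negative cells (positive/negative,
#' not positive/total), as used for Ki67 and gammaH2AX scoring.
#'
#' @param n_positive,n_negative non-negative counts; `n_negative >= 1`.
#' @return the ratio.
#' @export
positive_ratio <- function(n_positive, n_negative) {
  stopifnot(n_positive >= 0)
  if (n_negative < 1) stop("n_negative must be >= 1", call. = FALSE)
  n_positive / n_negative
}

#' Organoid count normalization
#'
#' Rescales an end-point organoid count by the factor that maps the starting
#' count to 100: `end_count * 100 / start_count`.
#'
#' @param start_count starting organoid count (>= 1).
#' @param end_count end-point organoid count.
#' @return normalized count.
#' @export
organoid_norm <- function(start_count, end_count) {
  if (start_count < 1) stop("start_count must be >= 1", call. = FALSE)
  end_count * 100 / start_count
}
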