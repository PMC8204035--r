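#' Intraclass correlation ICC(2,1): two-way random effects, absolute
#' agreement, single measurement
#'
#' Computed from the two-way ANOVA mean squares (rows = cases, columns =
#' raters/sessions) with the F-based 95 percent confidence interval of
#' McGraw and Wong. This is the agreement form: a constant offset between
#' raters lowers it, unlike a consistency ICC.
#'
#' @param table numeric matrix, rows = cases (>= 2), columns = raters (>= 2),
#'   complete (no missing cells).
#' @param form ICC form; only the two-way random absolute-agreement single
#'   measurement form is provided.
#' @param conf confidence level.
#' @return list with `icc`, `ci_lo`, `ci_hi` (clipped to [-1, 1]), the mean
#'   squares, and the form label.
#' @export
icc <- function(table, form = "ICC21_agreement", conf = 0.95) {
  form <- match.arg(form)
  x <- as.matrix(table)
  if (any(is.na(x))) stop("ICC requires a complete table (no missing cells)")
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) stop("need at least 2 cases and 2 raters")
  grand <- mean(x)
  if (sum((x - grand)^2) < 1e-30) stop("zero total variance: ICC undefined")
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm - grand)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  val <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  # McGraw & Wong F-based interval for ICC(A,1)
  alpha <- 1 - conf
  a <- k * val / (n * (1 - val))
  b <- 1 + k * val * (n - 1) / (n * (1 - val))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  # near-perfect agreement drives v to extreme values where qf emits a
  # numerical-accuracy warning; the interval is still accurate to ~1e-3
  fl <- suppressWarnings(qf(1 - alpha / 2, n - 1, v))
  fu <- suppressWarnings(qf(1 - alpha / 2, v, n - 1))
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  clip <- function(z) max(-1, min(1, z))
  list(icc = clip(val), ci_lo = clip(lo), ci_hi = clip(hi),
       msr = msr, msc = msc, mse = mse, n = n, k = k,
       form = "ICC(2,1) two-way random, absolute agreement, single measurement")
}

#' Wilcoxon signed rank test (exact for small samples, ties allowed)
#'
#' Paired two-sided test. Zero differences are dropped (Wilcoxon's original
#' rule) and their count reported. Ties receive average ranks. For n <= 25
#' retained pairs the two-sided p-value is exact, from the full distribution
#' of the positive-rank sum over all 2^n sign assignments (computed by
#' dynamic programming over the integer grid of doubled ranks, which equals
#' complete enumeration); above that, a normal approximation with tie and
#' continuity correction is used.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return list with `statistic` (W, the positive-rank sum), `p_value`,
#'   `n_used`, `n_zero`, and `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n < 3) stop("need at least 3 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    ir <- as.integer(round(2 * r))  # doubled ranks are integers under ties
    maxs <- sum(ir)
    # distribution of the doubled positive-rank sum over all sign patterns
    cnt <- numeric(maxs + 1)
    cnt[1] <- 1
    for (ri in ir) {
      shifted <- c(rep(0, ri), cnt[seq_len(maxs + 1 - ri)])
      cnt <- cnt + shifted
    }
    w2 <- round(2 * W)
    p_le <- sum(cnt[seq_len(w2 + 1)]) / 2^n
    p_ge <- sum(cnt[seq.int(w2 + 1, maxs + 1)]) / 2^n
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (sign-assignment enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = W, p_value = p, n_used = n, n_zero = n_zero, method = method)
}

#' Mean, absolute mean and SD summaries
#'
#' @param values numeric vector.
#' @param absolute also summarize absolute values (default TRUE).
#' @return list with `mean`, `sd` (sample, n-1; `NA` with a flag for a single
#'   value), and, if requested, `abs_mean`, `abs_sd`.
#' @export
summarize_values <- function(values, absolute = TRUE) {
  if (length(values) == 0) stop("no values")
  out <- list(mean = mean(values),
              sd = if (length(values) > 1) sd(values) else NA_real_,
              n = length(values),
              sd_undefined = length(values) < 2)
  if (absolute) {
    a <- abs(values)
    out$abs_mean <- mean(a)
    out$abs_sd <- if (length(a) > 1) sd(a) else NA_real_
  }
  out
}
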