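#' Convert a correlation coefficient to a t statistic
#'
#' The test statistic of the Pearson correlation test,
#' \eqn{t = r\sqrt{df}/\sqrt{1-r^2}}, which follows a central t distribution
#' with `df` degrees of freedom when the population correlation is zero.
#' For a correlation computed on N pairs, `df = N - 2`.
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @param df Degrees of freedom (N - 2), `df >= 1`.
#' @return Numeric vector of t statistics; `r = 1` and `r = -1` map to
#'   `Inf` and `-Inf` respectively.
#' @examples
#' r_to_t(0.5, 16)
#' @export
r_to_t <- function(r, df) {
  stopifnot(all(abs(r) <= 1), all(df >= 1))
  out <- r * sqrt(df) / sqrt(1 - r^2)
  out[r == 1] <- Inf
  out[r == -1] <- -Inf
  out
}

#' Exact p-value for a Pearson correlation
#'
#' Recomputes the p-value from `r` and `df` alone via the t transform. The
#' one-sided p-value takes the observed direction as the hypothesised one
#' (so it is half the two-sided value): the most favourable bound for the
#' reporting author.
#'
#' @inheritParams r_to_t
#' @param sides `"two.sided"` (default) or `"one.sided"`.
#' @return p-value(s) in `[0, 1]`.
#' @examples
#' exact_p(0.17, 228)
#' @export
exact_p <- function(r, df, sides = c("two.sided", "one.sided")) {
  sides <- match.arg(sides)
  stopifnot(all(abs(r) <= 1))
  if (any(df < 1)) stop("df must be >= 1")
  p <- 2 * stats::pt(abs(r_to_t(r, df)), df, lower.tail = FALSE)
  p <- pmin(p, 1)
  if (sides == "one.sided") p <- p / 2
  p
}

#' Critical absolute correlation at significance level alpha
#'
#' The smallest `|r|` significant at level `alpha` for given degrees of
#' freedom, obtained by inverting the t quantile:
#' \eqn{r_c = t_c/\sqrt{t_c^2 + df}}. Significance is taken as
#' \eqn{p \le \alpha}, so a correlation exactly at the boundary counts as
#' significant.
#'
#' @param df Degrees of freedom (N - 2).
#' @param alpha Significance level in (0, 1).
#' @inheritParams exact_p
#' @return Critical `|r|` value(s) in (0, 1).
#' @examples
#' critical_r(98, 0.05)
#' @export
critical_r <- function(df, alpha = 0.05, sides = c("two.sided", "one.sided")) {
  sides <- match.arg(sides)
  stopifnot(all(df >= 1), alpha > 0, alpha < 1)
  tails <- if (sides == "two.sided") 2 else 1
  tc <- stats::qt(1 - alpha / tails, df)
  tc / sqrt(tc^2 + df)
}

#' Null sampling density of the correlation coefficient
#'
#' Density of the sample correlation of bivariate-normal data when the
#' population correlation is zero:
#' \eqn{f_0(r \mid df) = (1-r^2)^{(df-2)/2} / B(1/2, df/2)} on (-1, 1).
#'
#' @inheritParams critical_r
#' @param r Evaluation point(s) in (-1, 1).
#' @return Density value(s).
#' @export
null_density <- function(r, df) {
  stopifnot(all(abs(r) < 1), all(df >= 1))
  exp(((df - 2) / 2) * log1p(-r^2) - lbeta(0.5, df / 2))
}

#' Expected non-significant |r| under the null hypothesis
#'
#' The mean absolute correlation one would observe among non-significant
#' results if the null hypothesis were true, for given degrees of freedom:
#' the integral of \eqn{u \cdot 2f_0(u)} between 0 and the critical
#' threshold, by default normalised by the probability of landing below the
#' threshold (a conditional mean; set `conditional = FALSE` for the raw
#' integral). Both pieces have closed forms: the numerator integrates to
#' \eqn{2(1-(1-r_c^2)^{df/2})/(df\,B(1/2, df/2))} and the denominator is
#' \eqn{P(r^2 \le r_c^2) = I_{r_c^2}(1/2, df/2)} (regularised incomplete
#' beta, since \eqn{r^2 \sim \mathrm{Beta}(1/2, df/2)} under the null).
#'
#' @inheritParams critical_r
#' @param conditional Normalise by the non-significance probability
#'   (default `TRUE`).
#' @return A one-row tibble with `df`, `alpha`, `sides`, `r_crit` and
#'   `expected_abs_r_nonsig`.
#' @examples
#' expected_abs_r_nonsig(48, 0.05)
#' @export
expected_abs_r_nonsig <- function(df, alpha = 0.05,
                                  sides = c("two.sided", "one.sided"),
                                  conditional = TRUE) {
  sides <- match.arg(sides)
  rc <- critical_r(df, alpha, sides)
  num <- 2 * (1 - exp((df / 2) * log1p(-rc^2))) /
    (df * exp(lbeta(0.5, df / 2)))
  denom <- if (conditional) stats::pbeta(rc^2, 0.5, df / 2) else 1
  tibble::tibble(
    df = df, alpha = alpha, sides = sides, r_crit = rc,
    expected_abs_r_nonsig = num / denom
  )
}

# Gauss hypergeometric 2F1(1/2, 1/2; c; z) by its series, vectorised in z.
# Converges for z in [0, 1); c = n - 1/2 is large here so decay is fast.
hyp2f1_half <- function(z, c) {
  s <- rep(1, length(z))
  term <- rep(1, length(z))
  k <- 0
  repeat {
    term <- term * (0.5 + k)^2 / ((c + k) * (k + 1)) * z
    s <- s + term
    k <- k + 1
    if (max(abs(term)) < 1e-16 * max(s) || k > 20000L) break
  }
  s
}

#' Exact sampling density of the correlation coefficient
#'
#' Density of the sample correlation of `n` bivariate-normal pairs with
#' population correlation `rho` (Hotelling's form):
#' \deqn{f(r) = \frac{(n-2)\,\Gamma(n-1)}{\sqrt{2\pi}\,\Gamma(n-1/2)}
#'  (1-\rho^2)^{(n-1)/2} (1-r^2)^{(n-4)/2} (1-\rho r)^{-(n-3/2)}
#'  \,{}_2F_1\!\left(\tfrac12,\tfrac12; n-\tfrac12; \tfrac{1+\rho r}{2}\right)}
#' Reduces to [null_density()] (with `df = n - 2`) at `rho = 0`.
#'
#' @param r Evaluation point(s) in (-1, 1).
#' @param rho Population correlation in (-1, 1).
#' @param n Number of pairs, `n >= 4` for a proper density.
#' @return Density value(s).
#' @export
r_sampling_density <- function(r, rho, n) {
  stopifnot(abs(rho) < 1, n >= 4, all(abs(r) < 1))
  lg <- (n - 1) / 2 * log1p(-rho^2) + (n - 4) / 2 * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r)
  cst <- log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5)
  exp(cst + lg) * hyp2f1_half((1 + rho * r) / 2, n - 0.5)
}

#' Exact power of the Pearson correlation test
#'
#' Probability that the sample correlation of `n` bivariate-normal pairs
#' with population correlation `r` falls in the rejection region at level
#' `alpha`, computed by integrating the exact sampling density
#' ([r_sampling_density()]) over the region beyond [critical_r()]. The
#' Fisher-z normal approximation is available as a labelled alternative for
#' cross-checks; it may disagree with the exact model by one or two units of
#' N near a power target.
#'
#' @param r Population correlation, `0 < r < 1`.
#' @param n Sample size(s), `n >= 4`.
#' @inheritParams critical_r
#' @param method `"exact"` (default) or `"fisher_z"`.
#' @return Power value(s) in (0, 1).
#' @examples
#' power_at_n(0.3, 84)
#' @export
power_at_n <- function(r, n, alpha = 0.05,
                       sides = c("two.sided", "one.sided"),
                       method = c("exact", "fisher_z")) {
  sides <- match.arg(sides)
  method <- match.arg(method)
  stopifnot(r > 0, r < 1, all(n >= 4))
  vapply(n, function(n1) {
    if (method == "fisher_z") {
      tails <- if (sides == "two.sided") 2 else 1
      zc <- stats::qnorm(1 - alpha / tails)
      z <- atanh(r) * sqrt(n1 - 3)
      p <- stats::pnorm(z - zc)
      if (sides == "two.sided") p <- p + stats::pnorm(-z - zc)
      return(p)
    }
    rc <- critical_r(n1 - 2, alpha, sides)
    up <- stats::integrate(r_sampling_density, rc, 1, rho = r, n = n1,
                           rel.tol = 1e-10)$value
    lo <- if (sides == "two.sided") {
      stats::integrate(r_sampling_density, -1, -rc, rho = r, n = n1,
                       rel.tol = 1e-10)$value
    } else 0
    min(up + lo, 1)
  }, numeric(1))
}

#' Smallest sample size achieving a target power
#'
#' Integer bisection on [power_at_n()]: returns the minimal `N >= 4` whose
#' exact power reaches `power` — no rounding of fractional solutions, which
#' removes the ceiling/rounding ambiguity of approximate formulas.
#'
#' @inheritParams power_at_n
#' @param power Target power in (0, 1).
#' @param n_max Search cap; an error mentioning the cap is raised when the
#'   target power is unattainable below it.
#' @return The required sample size (integer).
#' @examples
#' required_n(0.3)                 # 84
#' required_n(0.17)                # 269 (exact model; see vignette)
#' @export
required_n <- function(r, alpha = 0.05, power = 0.8,
                       sides = c("two.sided", "one.sided"),
                       method = c("exact", "fisher_z"),
                       n_max = 1e6) {
  sides <- match.arg(sides)
  method <- match.arg(method)
  stopifnot(r > 0, r < 1, power > 0, power < 1)
  f <- function(n) power_at_n(r, n, alpha, sides, method)
  lo <- 4L
  if (f(lo) >= power) return(lo)
  hi <- 8L
  while (f(hi) < power) {
    lo <- hi
    hi <- hi * 2L
    if (hi > n_max) {
      stop("target power ", power, " not attainable for r = ", r,
           " below n_max = ", n_max)
    }
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (f(mid) >= power) hi <- mid else lo <- mid
  }
  hi
}

#' Fisher's z transform and its inverse
#'
#' `fisher_z()` maps a correlation to `atanh(r)`; `inverse_fisher_z()` maps
#' back with `tanh(z)`. Used for approximate confidence intervals and as a
#' cross-check on the exact power model.
#'
#' @param r Correlation(s), `|r| < 1`.
#' @param z z value(s).
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1")
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)
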