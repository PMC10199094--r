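#' D'Agostino-Pearson omnibus normality test
#'
#' Omnibus K-squared test combining transformed sample skewness and kurtosis
#' (D'Agostino, Belanger & D'Agostino Jr., 1990). The skewness component uses
#' the Johnson SU approximation, the kurtosis component the Anscombe-Glynn
#' approximation; `K2 = Zg1^2 + Zg2^2` is referred to a chi-squared
#' distribution with 2 degrees of freedom. Requires `n >= 8` for the kurtosis
#' approximation to be usable.
#'
#' @param x Numeric vector; non-finite values are dropped.
#' @return An object of class `"htest"` with `statistic` (K2), `parameter`
#'   (df = 2) and `p.value`.
#' @export
dagostino_test <- function(x) {
  dname <- deparse(substitute(x))
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) {
    abort("D'Agostino-Pearson omnibus test requires n >= 8",
          class = "retinocog_domain_error")
  }
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) {
    abort("all values are identical; normality test undefined",
          class = "retinocog_domain_error")
  }
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2 - 3

  # skewness: Johnson SU transform
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis: Anscombe-Glynn transform
  Eg2 <- -6 / (n + 1)
  Vg2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - Eg2) / sqrt(Vg2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Zg2 <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) *
    sqrt(9 * A / 2)

  K2 <- Zg1^2 + Zg2^2
  structure(
    list(
      statistic = c("K-squared" = K2),
      parameter = c(df = 2),
      p.value = pchisq(K2, df = 2, lower.tail = FALSE),
      method = "D'Agostino-Pearson omnibus normality test",
      data.name = dname
    ),
    class = "htest"
  )
}

#' Four-test normality battery
#'
#' Runs the Anderson-Darling, D'Agostino-Pearson omnibus, Shapiro-Wilk, and
#' Lilliefors-corrected Kolmogorov-Smirnov tests on a vector (typically model
#' residuals). A sample is treated as normally distributed only when *all
#' four* tests are non-significant at `alpha`; no multiplicity correction is
#' applied across the tests, by design — each test gets a full veto.
#'
#' @param x Numeric vector, `n >= 8`.
#' @param alpha Significance level for the pass/fail verdict (default 0.05).
#' @return A tibble with columns `test`, `statistic`, `p_value`, `pass`
#'   (p > alpha), plus attribute `"normal"`: `TRUE` iff every test passes.
#' @export
normality_battery <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 8) {
    abort("normality battery requires n >= 8", class = "retinocog_domain_error")
  }
  tests <- list(
    anderson_darling = nortest::ad.test(x),
    dagostino_pearson = dagostino_test(x),
    shapiro_wilk = shapiro.test(x),
    kolmogorov_smirnov = nortest::lillie.test(x)
  )
  out <- purrr::imap_dfr(tests, function(ht, name) {
    tibble(
      test = name,
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      pass = ht$p.value > alpha
    )
  })
  attr(out, "normal") <- all(out$pass)
  out
}
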