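#' Fisher z-transform of a correlation
#'
#' @param r correlation in (-1, 1).
#' @param n optional sample size; if given, the standard error
#'   `1/sqrt(n - 3)` is attached.
#' @return `z = atanh(r)`, with attribute `"se"` when `n` is supplied.
#' @examples
#' fisher_z(0.1095)  # 0.1099
#' @export
fisher_z <- function(r, n = NULL) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1 for the Fisher z-transform")
  z <- atanh(r)
  if (!is.null(n)) attr(z, "se") <- 1 / sqrt(n - 3)
  z
}

#' Spearman rank correlation with midranks and a two-sided test
#'
#' Pearson correlation of midranks; p-value from [stats::cor.test()]
#' (exact for small tie-free samples, asymptotic otherwise).
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return List with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    out <- list(rho = NA_real_, p_value = NA_real_)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = length(x) <= 10))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Upper-tail chi-square probability
#'
#' @param x nonnegative statistic.
#' @param df degrees of freedom (>= 1).
#' @return `P(Chi2_df >= x)`.
#' @examples
#' chi2_sf(130.231, 137)  # about 0.65
#' @export
chi2_sf <- function(x, df) {
  stopifnot(x >= 0, df >= 1)
  stats::pchisq(x, df, lower.tail = FALSE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param x,y numeric samples (each of size >= 5).
#' @param center subtract each sample's mean first (as done when comparing
#'   phase distributions up to a mean shift).
#' @return List with `D` (max CDF gap) and `p_value` (asymptotic).
#' @export
ks_2sample <- function(x, y, center = FALSE) {
  stopifnot(length(x) >= 5, length(y) >= 5)
  if (center) {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Pearson/Spearman correlation report
#'
#' @param x,y numeric vectors.
#' @return Data frame with Pearson `r`, Fisher `z`, Spearman `rho`,
#'   two-sided p-values and `n`.
#' @export
correlation_report <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  pt <- stats::cor.test(x, y)
  sp <- spearman_cor(x, y)
  data.frame(r = unname(pt$estimate), z = atanh(unname(pt$estimate)),
             p_pearson = pt$p.value, rho = sp$rho, p_spearman = sp$p_value,
             n = length(x))
}
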