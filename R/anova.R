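#' Dunn-Sidak adjusted significance level
#'
#' Family-wise error control for k independent tests:
#' `alpha' = 1 - (1 - alpha)^(1/k)`. For two per-clone test families at
#' family alpha 0.05 this gives 0.0253, conventionally rounded to 0.025.
#'
#' @param family_alpha family-wise error rate in (0, 1).
#' @param k number of tests, >= 1.
#' @return per-test significance level.
#' @examples
#' dunn_sidak_alpha(0.05, 2)  # 0.02532057
#' @export
dunn_sidak_alpha <- function(family_alpha, k) {
  if (!is.numeric(family_alpha) || family_alpha <= 0 || family_alpha >= 1)
    stop("family_alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(k) || k < 1)
    stop("k must be a positive number of tests", call. = FALSE)
  1 - (1 - family_alpha)^(1 / k)
}

#' Endpoint transformation used before ANOVA
#'
#' Age at first reproduction is natural-log transformed to stabilise its
#' pronounced heterogeneous variances; every other endpoint is analysed on
#' its raw scale.
#'
#' @param values numeric endpoint values (`NA` allowed).
#' @param endpoint endpoint label; `"afr"` (any case) selects the log.
#' @return transformed values.
#' @export
transform_endpoint <- function(values, endpoint) {
  if (tolower(endpoint) %in% c("afr", "ln_afr", "age_at_first_reproduction")) {
    if (any(values <= 0, na.rm = TRUE))
      stop("AFR must be strictly positive for the log transform", call. = FALSE)
    log(values)
  } else {
    values
  }
}

#' Two-way fixed-effects ANOVA for one endpoint
#'
#' Fits `value ~ concentration * parasite` with both factors fixed, on
#' complete cases. Mortality makes the realised design unbalanced even
#' though it is balanced by construction, so partial (Type II)
#' sums of squares are the default decomposition; sequential (Type I) is
#' available by flag and coincides with Type II on balanced data. F is the
#' term mean square over the residual mean square; a degenerate fit with
#' zero residual variance reports F and P as `NA` rather than infinity.
#'
#' @param data data.frame with columns `concentration`, `parasite_level`
#'   and the response.
#' @param response name of the response column.
#' @param alpha significance level used for the `significant` flag.
#' @param ss_type `"II"` (partial, default) or `"I"` (sequential).
#' @return Object of class `anova_cell`: data.frame with rows
#'   concentration / parasite / interaction / residual and columns `term`,
#'   `ss`, `df`, `F`, `P`, `significant`; attributes `alpha`, `ss_type`,
#'   `n` and `model` (the underlying `lm` fit).
#' @export
two_way_anova <- function(data, response, alpha = 0.05,
                          ss_type = c("II", "I")) {
  ss_type <- match.arg(ss_type)
  d <- data.frame(
    y = data[[response]],
    A = factor(data$concentration),
    B = factor(data$parasite_level))
  d <- d[stats::complete.cases(d), ]
  d$A <- droplevels(d$A); d$B <- droplevels(d$B)
  if (nlevels(d$A) < 2L || nlevels(d$B) < 2L)
    stop("each factor needs at least two levels with data", call. = FALSE)
  tab <- table(d$A, d$B)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)
    stop("interaction inestimable: empty cell(s) ",
         paste(paste0("(", rownames(tab)[empty[, 1]], ", ",
                      colnames(tab)[empty[, 2]], ")"), collapse = ", "),
         call. = FALSE)
  }
  fit <- stats::lm(y ~ A * B, data = d)
  total_ss <- sum((d$y - mean(d$y))^2)
  perfect <- sum(stats::residuals(fit)^2) <= 1e-12 * max(total_ss, 1)
  if (perfect) {
    # zero residual variance: car::Anova refuses; the sequential
    # decomposition carries the (possibly all-zero) term SS, F stays NA
    a <- suppressWarnings(stats::anova(fit))
    ss <- a[["Sum Sq"]][match(c("A", "B", "A:B", "Residuals"), rownames(a))]
    df <- a[["Df"]][match(c("A", "B", "A:B", "Residuals"), rownames(a))]
  } else if (ss_type == "II") {
    a <- car::Anova(fit, type = 2)
    ss <- a[["Sum Sq"]][match(c("A", "B", "A:B", "Residuals"), rownames(a))]
    df <- a[["Df"]][match(c("A", "B", "A:B", "Residuals"), rownames(a))]
  } else {
    a <- stats::anova(fit)
    ss <- a[["Sum Sq"]][match(c("A", "B", "A:B", "Residuals"), rownames(a))]
    df <- a[["Df"]][match(c("A", "B", "A:B", "Residuals"), rownames(a))]
  }
  ms_res <- ss[4] / df[4]
  degenerate <- !is.finite(ms_res) || ms_res <= .Machine$double.eps *
    max(sum(ss), 1)
  Fv <- if (degenerate) rep(NA_real_, 3) else (ss[1:3] / df[1:3]) / ms_res
  Pv <- if (degenerate) rep(NA_real_, 3) else
    stats::pf(Fv, df[1:3], df[4], lower.tail = FALSE)
  out <- data.frame(
    term = c("concentration", "parasite", "interaction", "residual"),
    ss = ss, df = df,
    F = c(Fv, NA_real_), P = c(Pv, NA_real_),
    significant = c(!is.na(Pv) & Pv <= alpha, NA),
    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "ss_type") <- ss_type
  attr(out, "n") <- nrow(d)
  attr(out, "model") <- fit
  class(out) <- c("anova_cell", "data.frame")
  out
}

#' Residual diagnostics for a fitted ANOVA
#'
#' Summary numbers used to judge the usual ANOVA assumptions from residual
#' plots: the max/min ratio of per-cell residual variances, and the skewness
#' and excess kurtosis of the pooled residuals. Purely descriptive — no
#' automatic decision is taken.
#'
#' @param residuals numeric residual vector.
#' @param cells factor (or vector) of cell labels, same length.
#' @return list with `variance_ratio` (`NA` and `degenerate = TRUE` when all
#'   residuals are constant), `cell_variances`, `skewness`,
#'   `excess_kurtosis`, `degenerate`.
#' @export
residual_diagnostics <- function(residuals, cells) {
  stopifnot(length(residuals) == length(cells))
  v <- tapply(residuals, cells, stats::var)
  v <- v[!is.na(v)]
  degenerate <- length(v) == 0L || max(v) <= 0
  ratio <- if (degenerate || min(v) <= 0) NA_real_ else max(v) / min(v)
  m <- mean(residuals)
  s2 <- mean((residuals - m)^2)
  if (s2 > 0) {
    skew <- mean((residuals - m)^3) / s2^1.5
    kurt <- mean((residuals - m)^4) / s2^2 - 3
  } else {
    skew <- NA_real_; kurt <- NA_real_
  }
  list(variance_ratio = ratio, cell_variances = v, skewness = skew,
       excess_kurtosis = kurt, degenerate = degenerate)
}
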