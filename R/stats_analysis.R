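# Statistical layer: Spearman correlation with its t test, Kruskal-Wallis H
# with a chi-squared decision, and root-function dose-CNR fits with
# matched-CNR dose readout.

#' Spearman rank correlation coefficient
#'
#' Pearson correlation of average ranks; ties receive mean ranks.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return r in \[-1, 1\].
#' @export
spearman_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(rx, ry)
}

#' t statistic for the significance of a correlation
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, compared against the two-sided
#' Student t critical value at `n - 2` degrees of freedom.
#'
#' @param r Correlation coefficient with `|r| <= 1`.
#' @param n Number of observations (>= 3).
#' @return The t statistic; `Inf` (with sign of r, and a warning) when
#'   `|r| = 1`.
#' @export
t_from_r <- function(r, n) {
  if (n < 3) stop("need n >= 3 observations")
  if (abs(r) > 1) stop("|r| cannot exceed 1")
  if (abs(r) == 1) {
    warning("|r| = 1: t statistic is infinite")
    return(sign(r) * Inf)
  }
  r * sqrt(n - 2) / sqrt(1 - r^2)
}

#' Critical value of the t or chi-squared reference distribution
#'
#' Two-sided critical t (upper `1 - alpha/2` Student t quantile) or
#' chi-squared critical value (upper `1 - alpha` quantile), as used for the
#' correlation t test and the Kruskal-Wallis decision respectively.
#'
#' @param distribution `"t"` or `"chi2"`.
#' @param alpha Significance level in (0, 1) (default 0.05).
#' @param df Degrees of freedom (>= 1).
#' @return Critical value.
#' @export
critical_value <- function(distribution = c("t", "chi2"), alpha = 0.05, df) {
  distribution <- match.arg(distribution)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (df < 1) stop("df must be >= 1")
  switch(distribution,
         t = stats::qt(1 - alpha / 2, df),
         chi2 = stats::qchisq(1 - alpha, df))
}

#' Kruskal-Wallis H statistic
#'
#' Ranks all observations jointly (mean ranks for ties), forms the group rank
#' sums `T_j` and returns
#' `H = 12 / (n (n + 1)) * sum_j T_j^2 / n_j - 3 (n + 1)`.
#' The printed formula carries no tie correction; with `tie_correct = TRUE`
#' H is divided by `1 - sum(t^3 - t) / (n^3 - n)` over tie groups (the
#' standard correction).
#'
#' @param groups List of >= 2 non-empty numeric vectors, total n >= 3.
#' @param tie_correct Apply the tie correction (default `FALSE`).
#' @return H (>= 0 up to floating error).
#' @export
kruskal_wallis <- function(groups, tie_correct = FALSE) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least two groups")
  if (any(!vapply(groups, length, integer(1))))
    stop("all groups must be non-empty")
  all_x <- unlist(groups, use.names = FALSE)
  n <- length(all_x)
  if (n < 3) stop("need at least 3 observations in total")
  rk <- rank(all_x, ties.method = "average")
  sizes <- vapply(groups, length, integer(1))
  idx <- rep(seq_along(groups), sizes)
  Tj <- tapply(rk, idx, sum)
  H <- 12 / (n * (n + 1)) * sum(Tj^2 / sizes) - 3 * (n + 1)
  if (tie_correct) {
    tcounts <- table(all_x)
    corr <- 1 - sum(tcounts^3 - tcounts) / (n^3 - n)
    if (corr > 0) H <- H / corr
  }
  unname(H)
}

#' Dose-CNR series
#'
#' Paired mean-glandular-dose / CNR observations for one method.
#'
#' @param method_label Method name (e.g. `"kes"`).
#' @param mgd_mGy Doses in mGy (> 0).
#' @param cnr CNR values, same length.
#' @return Object of class `dose_cnr_series` with `n` observations.
#' @export
dose_cnr_series <- function(method_label, mgd_mGy, cnr) {
  if (length(mgd_mGy) != length(cnr)) stop("dose and CNR lengths differ")
  if (any(mgd_mGy <= 0)) stop("doses must be positive")
  structure(list(method_label = method_label,
                 points = data.frame(mgd_mGy = mgd_mGy, cnr = cnr),
                 n = length(cnr)), class = "dose_cnr_series")
}

#' Read dose-CNR series from CSV
#'
#' Columns `method, mgd_mgy, cnr`; returns one series per method.
#'
#' @param path CSV path.
#' @return Named list of [dose_cnr_series()].
#' @export
read_dose_cnr_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("method", "mgd_mgy", "cnr") %in% names(df)))
  out <- lapply(split(df, df$method), function(d)
    dose_cnr_series(d$method[1], d$mgd_mgy, d$cnr))
  out
}

#' Root-function fit CNR = a * sqrt(MGD)
#'
#' Least-squares coefficient through the origin,
#' `a = sum(sqrt(D_i) * CNR_i) / sum(D_i)`; Poisson noise propagation forces
#' proportionality through zero, so the default fit has no intercept. With
#' `intercept = TRUE` an ordinary `lm(cnr ~ sqrt(mgd))` fit is returned
#' instead (non-default diagnostic).
#'
#' @param series A [dose_cnr_series()] with n >= 3.
#' @param intercept Allow an intercept (default `FALSE`).
#' @return For the default, a list with `a` and `method_label`; with an
#'   intercept, additionally `b` (the intercept).
#' @export
fit_root <- function(series, intercept = FALSE) {
  stopifnot(inherits(series, "dose_cnr_series"))
  if (series$n < 3) stop("need at least 3 points to fit")
  D <- series$points$mgd_mGy; C <- series$points$cnr
  if (all(D == 0)) stop("degenerate fit: all doses zero")
  if (!intercept)
    return(list(a = sum(sqrt(D) * C) / sum(D), method_label = series$method_label))
  co <- stats::coef(stats::lm(C ~ sqrt(D)))
  list(a = unname(co[2]), b = unname(co[1]), method_label = series$method_label)
}

#' Free-exponent power-law fit CNR = a * D^b
#'
#' Log-log least squares; used to verify the square-root dose law (b near
#' 0.5) on simulated exposure ladders.
#'
#' @param series A [dose_cnr_series()] with positive CNR values.
#' @return List with `a`, `b`.
#' @export
fit_power <- function(series) {
  stopifnot(inherits(series, "dose_cnr_series"))
  D <- series$points$mgd_mGy; C <- series$points$cnr
  if (any(C <= 0)) stop("power-law fit needs positive CNR values")
  co <- stats::coef(stats::lm(log(C) ~ log(D)))
  list(a = exp(unname(co[1])), b = unname(co[2]))
}

#' Dose required to reach a target CNR under the root model
#'
#' Inverts `CNR = a * sqrt(D)`: `D = (cnr_target / a)^2`. The matched-CNR
#' dose ratio between two methods is `(a2/a1)^2`, independent of the target.
#'
#' @param fit_a Root-fit coefficient (> 0).
#' @param cnr_target Target CNR (> 0).
#' @return Dose in mGy.
#' @export
dose_at_cnr <- function(fit_a, cnr_target) {
  if (fit_a <= 0) stop("fit coefficient must be positive")
  if (cnr_target <= 0) stop("target CNR must be positive")
  (cnr_target / fit_a)^2
}

#' Correlation / Kruskal-Wallis summary for dose-CNR series
#'
#' For each series: Spearman r between CNR and MGD, the t statistic, the
#' two-sided critical t at `alpha`, and the decision. Across series: the
#' Kruskal-Wallis H on the CNR values with its chi-squared critical value at
#' `c - 1` degrees of freedom.
#'
#' @param series_list Named list of [dose_cnr_series()].
#' @param alpha Significance level (default 0.05).
#' @return Object of class `stats_report`: list with `per_series` (data
#'   frame: method, n, r, t_calc, t_crit, reject) and `kruskal` (list: H,
#'   df, chi2_crit, reject).
#' @export
stats_report <- function(series_list, alpha = 0.05) {
  per <- do.call(rbind, lapply(series_list, function(s) {
    r <- spearman_r(s$points$mgd_mGy, s$points$cnr)
    t <- t_from_r(r, s$n)
    tc <- critical_value("t", alpha, s$n - 2)
    data.frame(method = s$method_label, n = s$n, r = r, t_calc = t,
               t_crit = tc, reject = abs(t) > tc)
  }))
  rownames(per) <- NULL
  kw <- NULL
  if (length(series_list) >= 2) {
    H <- kruskal_wallis(lapply(series_list, function(s) s$points$cnr))
    dfk <- length(series_list) - 1
    cc <- critical_value("chi2", alpha, dfk)
    kw <- list(H = H, df = dfk, chi2_crit = cc, reject = H > cc)
  }
  structure(list(per_series = per, kruskal = kw, alpha = alpha),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<stats_report> correlation of CNR with MGD (alpha =", x$alpha, ")\n")
  print(x$per_series, row.names = FALSE, digits = 4)
  if (!is.null(x$kruskal))
    cat(sprintf("Kruskal-Wallis: H = %.3f vs chi2(%d) critical %.3f -> %s\n",
                x$kruskal$H, x$kruskal$df, x$kruskal$chi2_crit,
                if (x$kruskal$reject) "reject H0" else "retain H0"))
  invisible(x)
}
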