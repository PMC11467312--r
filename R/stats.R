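#' Group statistics
#'
#' Two-group comparisons used for cohort and behavioral variables: pooled
#' Student t, Mann-Whitney U (min-U convention, exact by enumeration for
#' small samples), Pearson chi-square without continuity correction, and
#' Spearman correlation with scaled-MAD outlier screening.
#'
#' @name group-stats
NULL

#' Mann-Whitney U test
#'
#' U is the smaller of the two group statistics (`min(U1, U2)`), computed with
#' midranks for ties. The two-sided p-value is exact — by full enumeration of
#' group assignments — when `length(x) + length(y) <= 12`, otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples
#' @return list with `U`, `p_value`, `method`
#' @export
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  u_of <- function(xi) {
    # xi: indices of the x-sample within the combined data
    r <- rank(comb)
    u1 <- sum(r[xi]) - nx * (nx + 1) / 2
    min(u1, nx * ny - u1)
  }
  comb <- c(x, y)
  u_obs <- u_of(seq_len(nx))
  if (n <= 12) {
    combos <- utils::combn(n, nx)
    u_null <- apply(combos, 2, u_of)
    p <- mean(u_null <= u_obs)
    method <- "exact enumeration"
  } else {
    r <- rank(comb)
    ties <- table(comb)
    mu <- nx * ny / 2
    sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs + 0.5 - mu) / sqrt(sig2)  # U = min(...) <= mu
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal approximation with tie correction"
  }
  list(U = u_obs, p_value = p, method = method)
}

#' Pooled-variance (Student) two-sample t test
#'
#' @param x,y numeric samples of size >= 2; missing values are dropped
#' @return list with `t`, `df` (`n_x + n_y - 2`), `p_value`, group means
#' @export
student_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Pearson chi-square on a 2x2 table, no continuity correction
#'
#' @param tab 2x2 matrix of counts
#' @return list with `chi2`, `df` (1), `p_value`
#' @export
pearson_chi2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in the 2x2 table")
  }
  expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expct <= 0)) stop("expected counts must be positive")
  chi2 <- sum((tab - expct)^2 / expct)
  list(chi2 = chi2, df = 1L, p_value = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Spearman correlation with scaled-MAD outlier removal
#'
#' Values of the screened variable lying more than `3 * 1.4826 * MAD` from
#' its median are flagged; the flagged pairs are removed and the Spearman
#' rank correlation is computed on the remainder.
#'
#' @param x,y paired numeric vectors (>= 4 pairs)
#' @param screen which variable to screen for outliers: `"y"` (default),
#'   `"x"`, or `"both"`
#' @return list with `rho`, `p_value`, `outliers` (logical per input pair),
#'   `n_used`
#' @export
spearman_mad <- function(x, y, screen = c("y", "x", "both")) {
  screen <- match.arg(screen)
  stopifnot(length(x) == length(y))
  if (length(x) < 4) stop("need at least 4 paired values")
  flag_var <- function(v) {
    smad <- 1.4826 * stats::median(abs(v - stats::median(v)))
    abs(v - stats::median(v)) > 3 * smad
  }
  out <- switch(screen,
                y = flag_var(y),
                x = flag_var(x),
                both = flag_var(x) | flag_var(y))
  keep <- !out
  if (sum(keep) < 3) stop("fewer than 3 pairs remain after outlier removal")
  ct <- stats::cor.test(x[keep], y[keep], method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value, outliers = out,
       n_used = sum(keep))
}

#' Cohort comparison table
#'
#' Recomputes the standard two-group cohort comparisons from a cohort table:
#' pooled t for age and lesion volume (missing volumes excluded pairwise),
#' Mann-Whitney U for lesion age, and Pearson chi-square (no continuity
#' correction) for sex.
#'
#' @param cohort a `cohort_table`
#' @return data frame with one row per variable: group means (SD), statistic,
#'   df where applicable, p-value
#' @export
cohort_stats <- function(cohort) {
  s <- cohort$group == "subacute"
  msd <- function(v) sprintf("%.2f (%.2f)", mean(v, na.rm = TRUE),
                             stats::sd(v, na.rm = TRUE))
  age_t <- student_t(cohort$age[s], cohort$age[!s])
  la_u <- mann_whitney_u(cohort$lesion_age_weeks[s],
                         cohort$lesion_age_weeks[!s])
  vol_t <- student_t(cohort$lesion_volume_mm3[s], cohort$lesion_volume_mm3[!s])
  sex_tab <- rbind(subacute = c(M = sum(s & cohort$sex == "M"),
                                F = sum(s & cohort$sex == "F")),
                   chronic = c(M = sum(!s & cohort$sex == "M"),
                               F = sum(!s & cohort$sex == "F")))
  sex_c <- pearson_chi2(sex_tab)
  data.frame(
    variable = c("age_years", "lesion_age_weeks", "lesion_volume_mm3",
                 "sex_male_female"),
    subacute = c(msd(cohort$age[s]), msd(cohort$lesion_age_weeks[s]),
                 msd(cohort$lesion_volume_mm3[s]),
                 paste0(sex_tab[1, 1], "/", sex_tab[1, 2])),
    chronic = c(msd(cohort$age[!s]), msd(cohort$lesion_age_weeks[!s]),
                msd(cohort$lesion_volume_mm3[!s]),
                paste0(sex_tab[2, 1], "/", sex_tab[2, 2])),
    statistic = c(age_t$t, la_u$U, vol_t$t, sex_c$chi2),
    df = c(age_t$df, NA, vol_t$df, sex_c$df),
    p_value = c(age_t$p_value, la_u$p_value, vol_t$p_value, sex_c$p_value),
    stringsAsFactors = FALSE
  )
}
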