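#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a p-value from the
#' large-sample t approximation — the association measure used to compare
#' sweep-rate indices with tissue-Doppler annular velocities.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' ROC analysis with an accuracy-optimal cutoff
#'
#' Builds the full ROC curve over all thresholds (AUC by the trapezoidal
#' rule) and reports the operating point that maximizes classification
#' accuracy, with ties broken toward higher specificity. Candidate cutoffs
#' are midpoints between consecutive distinct scores (plus open ends), and
#' the reported rule is `score < cutoff` is positive when
#' `direction = "lower_is_positive"` (e.g. low PSR_E flags dysfunction), or
#' `score > cutoff` when `"higher_is_positive"` (e.g. long DT).
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector: `TRUE` = positive class
#'   (dysfunction).
#' @param direction which tail of the score is the positive class.
#' @return list with `auc`, `cutoff`, `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy` (all rates in percent), and the ROC coordinate table
#'   `curve`.
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("lower_is_positive",
                                       "higher_is_positive")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stop("both classes must be present")
  s <- if (direction == "lower_is_positive") -scores else scores
  u <- sort(unique(s))
  thr <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(thr, function(th) sum(labels & s > th) / np, 0)
  spec <- vapply(thr, function(th) sum(!labels & s <= th) / nn, 0)
  acc <- (sens * np + spec * nn) / (np + nn)
  # trapezoid over the (FPR, TPR) staircase
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (sens[o][-1] + sens[o][-length(o)]) / 2)
  best <- which(acc == max(acc))
  best <- best[which.max(spec[best])]
  th <- thr[best]
  cutoff <- if (direction == "lower_is_positive") -th else th
  tp <- sum(labels & s > th); fp <- sum(!labels & s > th)
  fn <- np - tp; tn <- nn - fp
  list(auc = auc, cutoff = cutoff, direction = direction,
       sensitivity = 100 * tp / np, specificity = 100 * tn / nn,
       ppv = if (tp + fp) 100 * tp / (tp + fp) else NA_real_,
       npv = if (tn + fn) 100 * tn / (tn + fn) else NA_real_,
       accuracy = 100 * (tp + tn) / (np + nn),
       curve = data.frame(threshold = thr, sens = sens, spec = spec))
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean paired difference `x2 - x1`) with 95% limits of agreement
#' `bias +/- 1.96 * SD(differences)`.
#'
#' @param x1,x2 paired measurements (n >= 2).
#' @return list with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x1, x2) {
  ok <- stats::complete.cases(x1, x2)
  d <- x2[ok] - x1[ok]
  n <- length(d)
  if (n < 2L) stop("at least 2 complete pairs are required")
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd_diff = s, n = n)
}

#' Intraclass correlation (two-way, absolute agreement, single measures)
#'
#' ICC(A,1) in the McGraw & Wong nomenclature — the conventional model for
#' two fixed raters measuring the same subjects — with the F-based 95%
#' confidence interval. Computed from the two-way ANOVA mean squares
#' (subjects x raters).
#'
#' @param x1,x2 paired measurements (n >= 5 subjects).
#' @param conf confidence level (default 0.95).
#' @return list with `icc`, `ci_low`, `ci_high`, `n`.
#' @export
icc_agreement <- function(x1, x2, conf = 0.95) {
  ok <- stats::complete.cases(x1, x2)
  y <- cbind(x1[ok], x2[ok])
  n <- nrow(y); k <- ncol(y)
  if (n < 5L) stop("at least 5 complete pairs are required")
  gm <- mean(y)
  rm_ <- rowMeans(y); cm_ <- colMeans(y)
  msr <- k * sum((rm_ - gm)^2) / (n - 1)
  msc <- n * sum((cm_ - gm)^2) / (k - 1)
  sse <- sum((y - outer(rm_, rep(1, k)) -
                outer(rep(1, n), cm_) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (abs(denom) < 1e-12 || (msr < 1e-12 && msc < 1e-12 && mse < 1e-12)) {
    warning("zero between-subject variance: ICC undefined")
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = n))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  if (!is.finite(a) || !is.finite(b)) {  # icc == 1 exactly
    return(list(icc = icc, ci_low = NA_real_, ci_high = NA_real_, n = n))
  }
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(icc = icc, ci_low = lo, ci_high = hi, n = n)
}

#' Label diastolic function from tissue-Doppler reference values
#'
#' The guideline rule used to dichotomize cohorts: dysfunction when septal
#' e' < 8 cm/s, lateral e' < 10 cm/s, or LA volume index >= 34 mL/m^2
#' (when available).
#'
#' @param e_prime_septal,e_prime_lateral TDI velocities (cm/s).
#' @param la_volume_index optional LA volume index (mL/m^2); `NA` entries
#'   are ignored.
#' @return logical vector: `TRUE` = dysfunction.
#' @export
label_dysfunction <- function(e_prime_septal, e_prime_lateral,
                              la_volume_index = NULL) {
  lab <- (e_prime_septal < 8) | (e_prime_lateral < 10)
  if (!is.null(la_volume_index))
    lab <- lab | (!is.na(la_volume_index) & la_volume_index >= 34)
  lab
}

#' Cohort reporting summary
#'
#' Given a per-subject table joining pipeline outputs and reference
#' columns, computes the standard cohort statistics: Spearman correlation
#' of `psr_ratio` against the TDI e'/a' ratios (septal, lateral, and their
#' average, when present) and ROC classification of each sweep-volume
#' index against the dysfunction label.
#'
#' @param subjects data frame with columns `psr_e`, `psr_ratio`,
#'   `dt_sv_ms`, `dsvrt50_pct_rr`, and optionally `e_prime_septal`,
#'   `a_prime_septal`, `e_prime_lateral`, `a_prime_lateral`, `dysfunction`
#'   (logical).
#' @return list with elements `correlations` (named list of
#'   [spearman_corr()] results) and `roc` (named list of [roc_analysis()]
#'   results); empty elements when the reference columns are absent.
#' @export
cohort_report <- function(subjects) {
  out <- list(correlations = list(), roc = list())
  has <- function(...) all(c(...) %in% names(subjects))
  if (has("e_prime_septal", "a_prime_septal", "psr_ratio")) {
    sep <- subjects$e_prime_septal / subjects$a_prime_septal
    out$correlations$psr_ratio_vs_septal <-
      spearman_corr(subjects$psr_ratio, sep)
    if (has("e_prime_lateral", "a_prime_lateral")) {
      lat <- subjects$e_prime_lateral / subjects$a_prime_lateral
      out$correlations$psr_ratio_vs_lateral <-
        spearman_corr(subjects$psr_ratio, lat)
      out$correlations$psr_ratio_vs_average <-
        spearman_corr(subjects$psr_ratio, (sep + lat) / 2)
    }
  }
  if (has("dysfunction")) {
    lab <- subjects$dysfunction
    for (v in intersect(c("psr_e", "psr_ratio"), names(subjects)))
      out$roc[[v]] <- roc_analysis(subjects[[v]], lab, "lower_is_positive")
    for (v in intersect(c("dt_sv_ms", "dsvrt50_pct_rr"), names(subjects)))
      out$roc[[v]] <- roc_analysis(subjects[[v]], lab, "higher_is_positive")
  }
  out
}
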