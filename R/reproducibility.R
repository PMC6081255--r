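# Inter-reader agreement: two-way random absolute-agreement ICC(2,1),
# Bland-Altman limits of agreement, and Cohen's kappa.

check_pair <- function(reader1, reader2, min_n = 2L) {
  stopifnot(length(reader1) == length(reader2))
  if (length(reader1) < min_n) {
    stop("need at least ", min_n, " paired subjects", call. = FALSE)
  }
  invisible(NULL)
}

#' Single-measure intraclass correlation, two-way random, absolute agreement
#'
#' ICC(2,1) from the two-way ANOVA mean squares with subjects and raters as
#' random effects:
#' (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)),
#' where MS_R, MS_C and MS_E are the subject, rater and residual mean
#' squares. Absolute agreement penalises a systematic offset between
#' readers, unlike consistency-type ICCs.
#'
#' @param reader1,reader2 Matched measurements, n >= 3 subjects.
#' @return ICC in \[-1, 1\]. Zero between-subject variance makes the
#'   coefficient undefined: `NaN` with a warning.
#' @export
icc_two_way_random_absolute <- function(reader1, reader2) {
  check_pair(reader1, reader2, min_n = 3L)
  n <- length(reader1); k <- 2L
  Y <- cbind(reader1, reader2)
  grand <- mean(Y)
  row_m <- rowMeans(Y); col_m <- colMeans(Y)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= .Machine$double.eps^0.5 && msr <= .Machine$double.eps^0.5) {
    warning("no between-subject variance; ICC undefined")
    return(NaN)
  }
  (msr - mse) / denom
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean difference reader1 - reader2) and 95% limits of agreement
#' bias +/- 1.96 SD(differences), plus the per-subject (mean, difference)
#' points for plotting.
#'
#' @param reader1,reader2 Matched measurements, n >= 2.
#' @return List with `bias`, `loa_lower`, `loa_upper`, `sd_diff`, and
#'   `points` (data.frame: mean, difference).
#' @export
bland_altman <- function(reader1, reader2) {
  check_pair(reader1, reader2, min_n = 2L)
  d <- reader1 - reader2
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_diff = s,
       points = data.frame(mean = (reader1 + reader2) / 2, difference = d))
}

#' Cohen's kappa for two binary raters
#'
#' kappa = (p_o - p_e) / (1 - p_e), with chance agreement p_e computed from
#' the raters' marginal frequencies.
#'
#' @param reader1,reader2 Matched binary ratings (logical or 0/1), n >= 2.
#' @return kappa in \[-1, 1\]; undefined (NaN, with a warning) when both
#'   raters are constant so that p_e = 1.
#' @export
cohens_kappa <- function(reader1, reader2) {
  check_pair(reader1, reader2, min_n = 2L)
  r1 <- as.logical(reader1); r2 <- as.logical(reader2)
  n <- length(r1)
  po <- mean(r1 == r2)
  pe <- mean(r1) * mean(r2) + mean(!r1) * mean(!r2)
  if (1 - pe <= .Machine$double.eps^0.5) {
    warning("both raters constant; kappa undefined")
    return(NaN)
  }
  (po - pe) / (1 - pe)
}

#' Inter-reader agreement over a set of measurements
#'
#' Given per-subject values from two readers for several named measurements,
#' computes the per-measurement ICC(2,1), its arithmetic mean across
#' measurements (the summary the radiomic-reproducibility analysis reports),
#' and Bland-Altman limits.
#'
#' @param table data.frame with columns `subject`, `measurement`, `reader1`,
#'   `reader2`.
#' @return List with `per_measurement` (data.frame: measurement, icc, bias,
#'   loa_lower, loa_upper) and `average_icc`.
#' @export
agreement_summary <- function(table) {
  stopifnot(all(c("subject", "measurement", "reader1", "reader2") %in% names(table)))
  rows <- lapply(split(table, table$measurement), function(d) {
    ba <- bland_altman(d$reader1, d$reader2)
    data.frame(measurement = d$measurement[1],
               icc = icc_two_way_random_absolute(d$reader1, d$reader2),
               bias = ba$bias, loa_lower = ba$loa_lower,
               loa_upper = ba$loa_upper)
  })
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  list(per_measurement = per, average_icc = mean(per$icc))
}
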