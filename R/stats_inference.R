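# Univariate screening, stepwise logistic regression, radiomic feature
# selection, ROC/AUC machinery, operating-point metrics and the DeLong test
# for correlated AUCs.

#' Two-sample t-test (Student pooled-variance by default)
#'
#' @param x1,x2 Numeric samples, each of length >= 2.
#' @param var_equal Pooled-variance Student test if `TRUE` (default; matches
#'   the era's SPSS default), Welch otherwise.
#' @return List with `statistic`, `p_value`, `mean1`, `mean2`, `df`.
#' @export
two_sample_ttest <- function(x1, x2, var_equal = TRUE) {
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  if (stats::var(x1) == 0 && stats::var(x2) == 0) {
    # degenerate: no within-group variance
    p <- if (mean(x1) == mean(x2)) 1 else 0
    return(list(statistic = if (p == 1) 0 else Inf, p_value = p,
                mean1 = mean(x1), mean2 = mean(x2),
                df = length(x1) + length(x2) - 2))
  }
  tt <- stats::t.test(x1, x2, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean1 = mean(x1), mean2 = mean(x2), df = unname(tt$parameter))
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Continuity correction is off by default; switchable, since either variant
#' is in routine use.
#'
#' @param tab 2x2 matrix of counts with positive marginals.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chi_squared_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal in 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2L) stop("labels must be binary", call. = FALSE)
  # positive class: symptomatic if present, else the second level
  pos <- if ("acute_subacute_symptomatic" %in% u) "acute_subacute_symptomatic" else u[2]
  as.character(labels) == pos
}

#' AUC as the Mann-Whitney concordance probability
#'
#' Fraction of (positive, negative) pairs where the positive scores higher;
#' ties count one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (logical, 0/1, or two-level; the symptomatic
#'   level is the positive class).
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' @inheritParams auc_mann_whitney
#' @return data.frame of (fpr, tpr) points, monotone non-decreasing, from
#'   (0,0) to (1,1); score >= threshold classifies positive.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & !y) / sum(!y), tpr = sum(pred & y) / sum(y))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, 1], tpr = pts[, 2])
}

#' Optimise the ROC operating point by Youden's J
#'
#' Chooses the threshold maximising J = sensitivity + specificity - 1 (ties
#' broken toward higher specificity) and reports the operating
#' characteristics there, including the likelihood ratios
#' LR+ = sens/(1 - spec) and 1/LR- = spec/(1 - sens).
#'
#' @inheritParams auc_mann_whitney
#' @return An object of class `diagnostic_result`: list with `roc`, `auc`,
#'   `optimal_threshold`, `sensitivity`, `specificity`, `accuracy`,
#'   `lr_plus`, `inv_lr_minus`, `youden`.
#' @export
optimise_operating_point <- function(scores, labels) {
  y <- as_binary_labels(labels)
  roc <- roc_curve(scores, labels)
  sens <- roc$tpr; spec <- 1 - roc$fpr
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]            # ties -> higher specificity
  thr <- roc$threshold[best]
  pred <- scores >= thr
  acc <- mean(pred == y)
  res <- list(
    roc = roc, auc = auc_mann_whitney(scores, labels),
    optimal_threshold = thr,
    sensitivity = sens[best], specificity = spec[best], accuracy = acc,
    lr_plus = likelihood_ratio_pos(sens[best], spec[best]),
    inv_lr_minus = inv_likelihood_ratio_neg(sens[best], spec[best]),
    youden = j[best])
  class(res) <- "diagnostic_result"
  res
}

#' Positive likelihood ratio from sensitivity and specificity
#' @param sens,spec Sensitivity and specificity in \[0, 1\].
#' @return `sens / (1 - spec)` (Inf at perfect specificity).
#' @export
likelihood_ratio_pos <- function(sens, spec) {
  if (spec >= 1) Inf else sens / (1 - spec)
}

#' Reciprocal negative likelihood ratio, `spec / (1 - sens)`
#' @inheritParams likelihood_ratio_pos
#' @return 1/LR- (Inf at perfect sensitivity).
#' @export
inv_likelihood_ratio_neg <- function(sens, spec) {
  if (sens >= 1) Inf else spec / (1 - sens)
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf(paste0("<diagnostic_result> AUC %.3f | threshold %.4g | ",
                     "sens %.3f spec %.3f acc %.3f | LR+ %.3f 1/LR- %.3f\n"),
              x$auc, x$optimal_threshold, x$sensitivity, x$specificity,
              x$accuracy, x$lr_plus, x$inv_lr_minus))
  invisible(x)
}

## ---------------------------------------------------------------------------
## logistic regression with stepwise selection

fit_logistic <- function(data, outcome, vars) {
  f <- stats::as.formula(paste(outcome, "~",
                               if (length(vars)) paste(vars, collapse = "+") else "1"))
  suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
}

lrt_p <- function(fit_small, fit_big) {
  dev <- fit_small$deviance - fit_big$deviance
  df <- fit_small$df.residual - fit_big$df.residual
  stats::pchisq(max(dev, 0), df = max(df, 1L), lower.tail = FALSE)
}

#' Stepwise logistic regression (forward likelihood-ratio with backward pruning)
#'
#' SPSS-style forward-LR emulation: at each step the candidate with the
#' smallest likelihood-ratio p-value enters if below `entry_p`; after each
#' entry, included variables whose removal LRT p-value exceeds `stay_p` are
#' pruned. Coefficients are maximum-likelihood (IRLS); odds ratios carry Wald
#' 95% CIs exp(beta +/- 1.96 SE). Complete separation or non-convergence is
#' flagged, never silently returned.
#'
#' @param data data.frame containing outcome and candidates.
#' @param outcome Name of a binary (0/1 or logical) outcome column.
#' @param candidates Character vector of candidate predictor columns.
#' @param entry_p,stay_p Entry and removal thresholds.
#' @return An object of class `logistic_fit`: list with `selected`,
#'   `coefficients`, `odds_ratios` (data.frame with CI), `converged`,
#'   `separation`, `model` (the glm).
#' @export
stepwise_logistic <- function(data, outcome, candidates,
                              entry_p = 0.10, stay_p = 0.05) {
  stopifnot(nrow(data) > length(candidates))
  for (v in candidates) {
    if (length(unique(data[[v]])) < 2L) {
      stop("constant candidate variable: ", v, call. = FALSE)
    }
  }
  y <- data[[outcome]]
  if (is.character(y) || is.factor(y)) data[[outcome]] <- as_binary_labels(y)
  selected <- character(0)
  seen_states <- character(0)          # guards against entry/removal cycles
  repeat {
    state <- paste(sort(selected), collapse = "|")
    if (state %in% seen_states) break
    seen_states <- c(seen_states, state)
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    base_fit <- fit_logistic(data, outcome, selected)
    ps <- vapply(remaining, function(v)
      lrt_p(base_fit, fit_logistic(data, outcome, c(selected, v))), 0)
    if (min(ps) >= entry_p) break
    selected <- c(selected, remaining[which.min(ps)])
    # backward pruning (may empty the model again)
    repeat {
      if (length(selected) == 0L) break
      full <- fit_logistic(data, outcome, selected)
      rem_p <- vapply(selected, function(v)
        lrt_p(fit_logistic(data, outcome, setdiff(selected, v)), full), 0)
      worst <- which.max(rem_p)
      if (rem_p[worst] <= stay_p) break
      selected <- selected[-worst]
    }
  }
  fit <- fit_logistic(data, outcome, selected)
  coefs <- summary(fit)$coefficients
  separation <- any(abs(coefs[, "Estimate"]) > 15) || any(coefs[, "Std. Error"] > 1e3)
  ors <- NULL
  if (length(selected)) {
    b <- coefs[selected, "Estimate"]; se <- coefs[selected, "Std. Error"]
    ors <- data.frame(variable = selected, or = exp(b),
                      ci_lower = exp(b - 1.96 * se),
                      ci_upper = exp(b + 1.96 * se),
                      p_value = coefs[selected, "Pr(>|z|)"],
                      row.names = NULL)
  }
  structure(list(selected = selected, coefficients = stats::coef(fit),
                 odds_ratios = ors, converged = fit$converged,
                 separation = separation, model = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit> selected:",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n")
  if (!is.null(x$odds_ratios)) print(x$odds_ratios)
  if (!x$converged || x$separation) {
    cat("warning: fit flagged (convergence/separation)\n")
  }
  invisible(x)
}

#' Univariate screen of a cohort table
#'
#' Continuous variables get a two-sample t-test, binary/logical variables a
#' chi-squared test on the 2x2 table; each also gets a univariate AUC.
#'
#' @param data data.frame.
#' @param outcome Binary outcome column name.
#' @param variables Columns to screen.
#' @param var_equal,correct Passed to the underlying tests.
#' @return data.frame (variable, type, statistic, p_value, auc).
#' @export
univariate_screen <- function(data, outcome, variables, var_equal = TRUE,
                              correct = FALSE) {
  y <- as_binary_labels(data[[outcome]])
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    if (is.logical(x) || length(unique(x)) == 2L) {
      xb <- if (is.logical(x)) x else x == max(x)
      tab <- table(factor(xb, c(FALSE, TRUE)), factor(y, c(FALSE, TRUE)))
      res <- chi_squared_2x2(tab, correct = correct)
      type <- "categorical"
    } else {
      res <- two_sample_ttest(x[y], x[!y], var_equal = var_equal)
      type <- "continuous"
    }
    data.frame(variable = v, type = type, statistic = res$statistic,
               p_value = res$p_value,
               auc = auc_mann_whitney(as.numeric(data[[v]]), y))
  })
  do.call(rbind, rows)
}

#' Select radiomic features by t-test significance and univariate AUC
#'
#' A feature is kept when its two-sided Student t-test p-value is below
#' `p_threshold` and its univariate AUC, computed symmetrically as
#' max(AUC, 1 - AUC), exceeds `auc_threshold`. An empty selection is allowed.
#'
#' @param features data.frame of numeric feature columns.
#' @param labels Binary labels, one per row.
#' @param p_threshold,auc_threshold Gate values.
#' @param p_adjust `"none"` (default; the source analysis applies no
#'   multiple-testing correction across its features) or `"BH"` for
#'   Benjamini-Hochberg adjustment of the t-test p-values before gating.
#' @return Character vector of selected feature names.
#' @export
select_radiomic_features <- function(features, labels, p_threshold = 0.05,
                                     auc_threshold = 0.65,
                                     p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  y <- as_binary_labels(labels)
  stopifnot(sum(y) >= 2, sum(!y) >= 2)
  stats_tab <- vapply(names(features), function(v) {
    x <- features[[v]]
    if (stats::var(x[y]) == 0 && stats::var(x[!y]) == 0) {
      return(c(p = 1, auc = 0.5))
    }
    a <- auc_mann_whitney(x, y)
    c(p = two_sample_ttest(x[y], x[!y])$p_value, auc = max(a, 1 - a))
  }, numeric(2))
  p <- stats_tab["p", ]
  if (p_adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  names(features)[p < p_threshold & stats_tab["auc", ] > auc_threshold]
}

## ---------------------------------------------------------------------------
## DeLong

# Placement values: V10 over positives, V01 over negatives.
delong_placements <- function(scores, y) {
  x <- scores[y]; z <- scores[!y]
  m <- length(x); n <- length(z)
  # psi(x, z) = 1, 1/2, 0 for x >, =, < z; row/col means via ranks
  v10 <- vapply(x, function(xi) (sum(xi > z) + 0.5 * sum(xi == z)) / n, 0)
  v01 <- vapply(z, function(zi) (sum(x > zi) + 0.5 * sum(x == zi)) / m, 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single AUC
#'
#' @inheritParams auc_mann_whitney
#' @return Estimated variance of the empirical AUC.
#' @export
delong_auc_variance <- function(scores, labels) {
  y <- as_binary_labels(labels)
  pl <- delong_placements(scores, y)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both models score the same patients; the variance of the AUC difference
#' uses the covariance of the placement-value components, and the two-sided
#' p-value comes from the normal approximation. Identical scores give z = 0,
#' p = 1.
#'
#' @param scores1,scores2 Scores of the two models on the same patients.
#' @inheritParams auc_mann_whitney
#' @return List with `auc1`, `auc2`, `z`, `p_value`, `var_diff`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  stopifnot(length(scores1) == length(scores2))
  y <- as_binary_labels(labels)
  if (sum(y) == 0 || sum(!y) == 0) stop("both classes must be present", call. = FALSE)
  p1 <- delong_placements(scores1, y)
  p2 <- delong_placements(scores2, y)
  m <- length(p1$v10); n <- length(p1$v01)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (var_diff <= .Machine$double.eps) {
    return(list(auc1 = p1$auc, auc2 = p2$auc, z = 0, p_value = 1,
                var_diff = var_diff))
  }
  z <- (p1$auc - p2$auc) / sqrt(var_diff)
  list(auc1 = p1$auc, auc2 = p2$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}
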