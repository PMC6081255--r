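# End-to-end orchestration: cohort assembly with exclusion bookkeeping,
# model tiers (traditional logistic, radiomic forest, combined), and
# table-style reports.

#' Assemble the analysis cohort from a screening manifest
#'
#' Rows with a non-empty exclusion reason are dropped; the ledger records
#' counts by reason and asserts included + excluded = screened. Acute and
#' sub-acute symptomatic labels are merged into one positive class.
#'
#' @param manifest data.frame with a `label` column (values among
#'   `acute_symptomatic`, `subacute_symptomatic`, `asymptomatic`, or already
#'   merged) and an exclusion-reason column (empty string or NA = included).
#' @param exclusion_col Name of the exclusion-reason column.
#' @return List with `cohort` (included rows, labels merged) and `ledger`
#'   (class `exclusion_ledger`: screened, excluded_by_reason, included).
#' @export
assemble_cohort <- function(manifest, exclusion_col = "exclusion_reason") {
  stopifnot(is.data.frame(manifest), "label" %in% names(manifest))
  if (anyDuplicated(manifest$patient_id)) {
    stop("duplicate patient identifiers in manifest", call. = FALSE)
  }
  reason <- if (exclusion_col %in% names(manifest)) {
    as.character(manifest[[exclusion_col]])
  } else {
    rep("", nrow(manifest))
  }
  reason[is.na(reason)] <- ""
  excluded <- reason != ""
  by_reason <- if (any(excluded)) table(reason[excluded]) else table(character(0))
  ledger <- structure(list(
    screened = nrow(manifest),
    excluded_by_reason = as.list(by_reason),
    included = sum(!excluded)), class = "exclusion_ledger")
  stopifnot(ledger$included + sum(excluded) == ledger$screened)
  cohort <- manifest[!excluded, , drop = FALSE]
  cohort$label <- merge_symptom_labels(cohort$label)
  list(cohort = cohort, ledger = ledger)
}

merge_symptom_labels <- function(label) {
  out <- as.character(label)
  out[out %in% c("acute_symptomatic", "subacute_symptomatic",
                 "acute_subacute_symptomatic")] <- "acute_subacute_symptomatic"
  bad <- !out %in% c("acute_subacute_symptomatic", "asymptomatic")
  if (any(bad)) stop("unrecognised label(s): ",
                     paste(unique(out[bad]), collapse = ", "), call. = FALSE)
  out
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("<exclusion_ledger> screened %d, excluded %d, included %d\n",
              x$screened, x$screened - x$included, x$included))
  for (r in names(x$excluded_by_reason)) {
    cat(sprintf("  - %s: %d\n", r, x$excluded_by_reason[[r]]))
  }
  invisible(x)
}

traditional_variables <- function() {
  c("sex_male", "age", "diabetes", "hypertension", "hyperlipidaemia",
    "smoking", "iph", "plaque_burden", "mla", "stenosis_percent",
    "enhancement_ratio")
}

#' Traditional model: univariate screen, stepwise logistic, ROC
#'
#' Screens the clinical covariates and conventional plaque metrics at
#' p < 0.10, runs stepwise logistic regression on the survivors, scores
#' patients by the linear predictor and optimises the operating point.
#'
#' @param conv data.frame from [cohort_conventional()] (or equivalent) with
#'   a `label` column.
#' @param variables Candidate columns (default the clinical + conventional set).
#' @param entry_p Univariate screening threshold.
#' @return List with `screen`, `fit` (`logistic_fit`), `scores`,
#'   `diagnostics` (`diagnostic_result`; AUC 0.5 flagged fit if nothing was
#'   selected).
#' @export
run_traditional_model <- function(conv, variables = traditional_variables(),
                                  entry_p = 0.10) {
  variables <- intersect(variables, names(conv))
  conv <- as.data.frame(conv)
  for (v in variables) conv[[v]] <- as.numeric(conv[[v]])
  screen <- univariate_screen(conv, "label", variables)
  candidates <- screen$variable[screen$p_value < entry_p]
  y <- as_binary_labels(conv$label)
  if (length(candidates) == 0L) {
    return(list(screen = screen, fit = NULL, scores = rep(0.5, nrow(conv)),
                diagnostics = degenerate_diagnostics(y)))
  }
  fit <- stepwise_logistic(conv, "label", candidates)
  scores <- if (length(fit$selected)) {
    unname(stats::predict(fit$model, type = "link"))
  } else {
    rep(0.5, nrow(conv))
  }
  diag <- if (length(fit$selected)) {
    optimise_operating_point(scores, y)
  } else {
    degenerate_diagnostics(y)
  }
  list(screen = screen, fit = fit, scores = scores, diagnostics = diag)
}

degenerate_diagnostics <- function(y) {
  structure(list(roc = data.frame(threshold = c(Inf, -Inf), fpr = c(0, 1),
                                  tpr = c(0, 1)),
                 auc = 0.5, optimal_threshold = NA_real_,
                 sensitivity = NA_real_, specificity = NA_real_,
                 accuracy = max(mean(y), mean(!y)), lr_plus = NA_real_,
                 inv_lr_minus = NA_real_, youden = NA_real_,
                 degenerate = TRUE),
            class = "diagnostic_result")
}

#' Radiomic model: per-sequence feature selection plus random forest
#'
#' Selects features per sequence with the t-test/AUC gate, fits the shallow
#' forest on the union, and scores. Resubstitution scoring by default
#' (mirroring the source workflow); `cv_folds > 0` adds a stratified k-fold
#' cross-validated AUC as an honesty check on the optimism of
#' resubstitution.
#'
#' @param features Wide feature table from [cohort_features()] (columns
#'   `<seq>_<feature>`), with `label`.
#' @param sequences Subset of sequences whose features are candidates.
#' @param extra_columns Additional columns (e.g. conventional metrics) forced
#'   into the forest's feature set (the combined model).
#' @param seed Seed for the forest (and fold assignment).
#' @param cv_folds 0 (default) or a fold count.
#' @param p_threshold,auc_threshold Selection gate.
#' @param ... Passed to [fit_forest()].
#' @return List with `selected` (per sequence), `model`, `scores`,
#'   `diagnostics`, and `cv_auc` (NA unless `cv_folds > 0`). Empty selection
#'   gives a degenerate result with AUC 0.5 and `model = NULL`.
#' @export
run_radiomic_model <- function(features, sequences = c("T1", "CE_T1"),
                               extra_columns = character(0), seed = 1L,
                               cv_folds = 0L, p_threshold = 0.05,
                               auc_threshold = 0.65, ...) {
  y <- as_binary_labels(features$label)
  selected <- lapply(sequences, function(sq) {
    cols <- grep(paste0("^", sq, "_"), names(features), value = TRUE)
    select_radiomic_features(features[cols], y, p_threshold, auc_threshold)
  })
  names(selected) <- sequences
  use <- c(unlist(selected, use.names = FALSE), extra_columns)
  if (length(use) == 0L) {
    return(list(selected = selected, model = NULL,
                scores = rep(0.5, nrow(features)),
                diagnostics = degenerate_diagnostics(y), cv_auc = NA_real_))
  }
  X <- features[use]
  model <- fit_forest(X, y, always_try = extra_columns, seed = seed, ...)
  scores <- predict_proba(model, X)
  cv <- NA_real_
  if (cv_folds > 0L) {
    cv <- cv_forest_auc(features, y, sequences, extra_columns, cv_folds,
                        seed, p_threshold, auc_threshold, ...)
  }
  list(selected = selected, model = model, scores = scores,
       diagnostics = optimise_operating_point(scores, y), cv_auc = cv)
}

# Stratified k-fold CV with selection redone inside each training fold.
cv_forest_auc <- function(features, y, sequences, extra_columns, folds, seed,
                          p_threshold, auc_threshold, ...) {
  with_rng(seed + 1L, {
    fold <- integer(length(y))
    fold[y] <- sample(rep_len(seq_len(folds), sum(y)))
    fold[!y] <- sample(rep_len(seq_len(folds), sum(!y)))
    scores <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      sel <- unlist(lapply(sequences, function(sq) {
        cols <- grep(paste0("^", sq, "_"), names(features), value = TRUE)
        select_radiomic_features(features[tr, cols], y[tr],
                                 p_threshold, auc_threshold)
      }), use.names = FALSE)
      use <- c(sel, extra_columns)
      if (length(use) == 0L || length(unique(y[tr])) < 2L) {
        scores[!tr] <- 0.5
        next
      }
      m <- fit_forest(features[tr, use, drop = FALSE], y[tr],
                      always_try = intersect(extra_columns, use),
                      seed = seed + f, ...)
      scores[!tr] <- predict_proba(m, features[!tr, use, drop = FALSE])
    }
    auc_mann_whitney(scores, y)
  })
}

#' Run the full three-tier analysis on one synthetic (or user) cohort
#'
#' Traditional logistic model, radiomic forest (chosen sequences), and the
#' combined model (selected radiomic features plus IPH, MLA and enhancement
#' ratio), with pairwise DeLong comparisons.
#'
#' @param conv Conventional-metrics table with covariates and `label`.
#' @param features Radiomic feature table with `label` (same row order).
#' @param sequences Sequences for the radiomic tier.
#' @param seed Seed for the forests.
#' @param cv_folds Passed to the forest tiers.
#' @return List with `traditional`, `radiomic`, `combined`, `delong`
#'   (data.frame of pairwise comparisons).
#' @export
run_analysis <- function(conv, features, sequences = c("T1", "CE_T1"),
                         seed = 1L, cv_folds = 0L) {
  stopifnot(identical(conv$patient_id, features$patient_id))
  trad <- run_traditional_model(conv)
  rad <- run_radiomic_model(features, sequences, seed = seed,
                            cv_folds = cv_folds)
  extra <- data.frame(iph = as.numeric(conv$iph), mla = conv$mla,
                      enhancement_ratio = conv$enhancement_ratio,
                      traditional_score = trad$scores)
  feat_plus <- cbind(features, extra)
  comb <- run_radiomic_model(feat_plus, sequences,
                             extra_columns = names(extra), seed = seed,
                             cv_folds = cv_folds)
  y <- as_binary_labels(conv$label)
  pairs <- list(c("traditional", "radiomic"), c("traditional", "combined"),
                c("radiomic", "combined"))
  all_scores <- list(traditional = trad$scores, radiomic = rad$scores,
                     combined = comb$scores)
  delong <- do.call(rbind, lapply(pairs, function(p) {
    dl <- delong_test(all_scores[[p[1]]], all_scores[[p[2]]], y)
    data.frame(model1 = p[1], model2 = p[2], auc1 = dl$auc1, auc2 = dl$auc2,
               z = dl$z, p_value = dl$p_value)
  }))
  list(traditional = trad, radiomic = rad, combined = comb, delong = delong)
}

#' Table-style reports from an analysis
#'
#' Emits the cohort-description, univariate/multivariate, selected-feature
#' and diagnostic-accuracy summaries as data.frames, and optionally writes
#' them as CSV plus a JSON bundle carrying identical numbers.
#'
#' @param analysis Result of [run_analysis()].
#' @param conv,features The tables the analysis was run on.
#' @param dir Optional output directory for CSV/JSON files.
#' @return List of data.frames: `cohort_summary`, `univariate`,
#'   `multivariate`, `selected_features`, `diagnostics`, `delong`.
#' @export
report_tables <- function(analysis, conv, features, dir = NULL) {
  y <- as_binary_labels(conv$label)
  n <- length(y)
  # cohort description; percentages computed from the actual counts
  bin_vars <- intersect(c("sex_male", "diabetes", "hypertension",
                          "hyperlipidaemia", "smoking", "iph"), names(conv))
  cohort_summary <- do.call(rbind, lapply(bin_vars, function(v) {
    cnt <- sum(as.logical(conv[[v]]))
    data.frame(characteristic = v, count = cnt, percent = 100 * cnt / n)
  }))
  cohort_summary <- rbind(cohort_summary, data.frame(
    characteristic = c("acute_subacute_symptomatic", "asymptomatic"),
    count = c(sum(y), sum(!y)),
    percent = 100 * c(sum(y), sum(!y)) / n))
  multi <- if (!is.null(analysis$traditional$fit)) {
    analysis$traditional$fit$odds_ratios
  } else {
    data.frame()
  }
  sel <- unlist(analysis$radiomic$selected)
  sel_rows <- do.call(rbind, lapply(unlist(analysis$radiomic$selected,
                                           use.names = FALSE), function(f) {
    data.frame(feature = f,
               mean_symptomatic = mean(features[[f]][y]),
               sd_symptomatic = stats::sd(features[[f]][y]),
               mean_asymptomatic = mean(features[[f]][!y]),
               sd_asymptomatic = stats::sd(features[[f]][!y]),
               p_value = two_sample_ttest(features[[f]][y],
                                          features[[f]][!y])$p_value)
  }))
  diag_row <- function(name, d, cv = NA_real_) {
    data.frame(model = name, da = d$accuracy, auc = d$auc,
               sensitivity = d$sensitivity, specificity = d$specificity,
               lr_plus = d$lr_plus, inv_lr_minus = d$inv_lr_minus,
               cv_auc = cv)
  }
  diagnostics <- rbind(
    diag_row("traditional", analysis$traditional$diagnostics),
    diag_row("radiomic", analysis$radiomic$diagnostics,
             analysis$radiomic$cv_auc),
    diag_row("combined", analysis$combined$diagnostics,
             analysis$combined$cv_auc))
  out <- list(cohort_summary = cohort_summary,
              univariate = analysis$traditional$screen,
              multivariate = multi,
              selected_features = if (is.null(sel_rows)) data.frame() else sel_rows,
              diagnostics = diagnostics,
              delong = analysis$delong)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    jsonlite::write_json(out, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
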