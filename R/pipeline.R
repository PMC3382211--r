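# End-to-end orchestration: cohort I/O, gender-stratified analysis
# (per-subject fits -> coefficient clusters -> univariate discriminants
# with cutoffs, plus the trials 1-5 comparison analyses), and report
# serialisation.

#' Pipeline configuration
#'
#' @param min_stratum minimum subjects per diagnosis group within a sex
#'   stratum; smaller strata are skipped with a warning.
#' @param boundary boundary convention for discriminant functions:
#'   `"midpoint"` (unweighted midpoint of the group centroids, default)
#'   or `"weighted"` (size-weighted, i.e. score 0).
#' @param standardize_trials scale trial columns before Ward clustering.
#' @param max_count list length (16 for CVLT-II List A).
#' @param include_trials_analysis also run the raw trials 1-5 analyses
#'   (whole-group LDA, Ward clusters, cluster LDA) for comparison.
#' @return A list of class `"lc_config"`.
#' @export
pipeline_config <- function(min_stratum = 6L,
                            boundary = c("midpoint", "weighted"),
                            standardize_trials = FALSE,
                            max_count = 16,
                            include_trials_analysis = TRUE) {
  structure(list(
    min_stratum = as.integer(min_stratum),
    boundary = match.arg(boundary),
    standardize_trials = isTRUE(standardize_trials),
    max_count = max_count,
    include_trials_analysis = isTRUE(include_trials_analysis)
  ), class = "lc_config")
}

cohort_schema <- c("subject_id", "diagnosis", "sex",
                   "t1", "t2", "t3", "t4", "t5")

#' Read a cohort table from CSV
#'
#' Expects the header `subject_id,diagnosis,sex,t1,t2,t3,t4,t5` with
#' `diagnosis` in `{control, patient}`, `sex` in `{F, M}` and integer
#' trial counts in `[0, max_count]`. Validation failures name the
#' offending rows (numbered as in the file, header = line 1).
#'
#' @param path CSV file path.
#' @param max_count maximum admissible recall count, default 16.
#' @return A validated cohort `data.frame`.
#' @export
read_cohort_csv <- function(path, max_count = 16) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  validate_cohort(raw, max_count = max_count)
}

#' Validate a cohort table
#'
#' @param cohort a data frame with the cohort schema columns.
#' @inheritParams read_cohort_csv
#' @return The cohort with typed columns, invisibly classed
#'   `"lc_cohort"`.
#' @export
validate_cohort <- function(cohort, max_count = 16) {
  miss <- setdiff(cohort_schema, names(cohort))
  if (length(miss) > 0) {
    stop("cohort is missing required columns: ",
         paste(miss, collapse = ", "),
         " (schema: ", paste(cohort_schema, collapse = ","), ")",
         call. = FALSE)
  }
  n <- nrow(cohort)
  if (n == 0) stop("cohort is empty", call. = FALSE)
  rowno <- seq_len(n) + 1L  # file line numbers (header is line 1)
  problems <- character(0)
  dup <- duplicated(cohort$subject_id)
  if (any(dup)) {
    problems <- c(problems, paste0("duplicate subject_id at row(s) ",
                                   paste(rowno[dup], collapse = ", ")))
  }
  bad <- !cohort$diagnosis %in% c("control", "patient")
  if (any(bad)) {
    problems <- c(problems,
                  paste0("diagnosis must be control/patient at row(s) ",
                         paste(rowno[bad], collapse = ", ")))
  }
  bad <- !cohort$sex %in% c("F", "M")
  if (any(bad)) {
    problems <- c(problems, paste0("sex must be F/M at row(s) ",
                                   paste(rowno[bad], collapse = ", ")))
  }
  for (tc in paste0("t", 1:5)) {
    v <- suppressWarnings(as.numeric(cohort[[tc]]))
    bad <- is.na(v) | v < 0 | v > max_count | v != round(v)
    if (any(bad)) {
      problems <- c(problems,
                    paste0(tc, " must be an integer in [0, ", max_count,
                           "] at row(s) ",
                           paste(rowno[bad], collapse = ", ")))
    }
    cohort[[tc]] <- v
  }
  if (length(problems) > 0) {
    stop("invalid cohort table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  for (col in c("B2", "B3", "B4")) {
    if (col %in% names(cohort)) cohort[[col]] <- as.numeric(cohort[[col]])
  }
  if (!inherits(cohort, "lc_cohort")) {
    class(cohort) <- c("lc_cohort", class(cohort))
  }
  cohort
}

#' Write a cohort table (and optional latent-truth sidecar) to CSV
#'
#' Writes the plain cohort schema columns to `path`. If `truth_path` is
#' given and the cohort carries latent truths (`subgroup`, `B2`, `B3`,
#' `B4`), a sidecar `subject_id,subgroup,B2,B3,B4` is written for
#' recovery studies.
#'
#' @param cohort a cohort data frame.
#' @param path output CSV path.
#' @param truth_path optional sidecar CSV path.
#' @export
write_cohort_csv <- function(cohort, path, truth_path = NULL) {
  utils::write.csv(as.data.frame(cohort)[cohort_schema], path,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(truth_path)) {
    tc <- c("subject_id", "subgroup", "B2", "B3", "B4")
    if (!all(tc %in% names(cohort))) {
      stop("cohort carries no latent truths to write", call. = FALSE)
    }
    utils::write.csv(as.data.frame(cohort)[tc], truth_path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Fit the averaged learning curve of a cohort subset
#'
#' Computes the per-trial mean recall of the subset and fits the
#' learning-curve model to the five means, the standard summary curve for
#' a group or cluster.
#'
#' @param cohort a cohort data frame (any non-empty subset).
#' @param max_count list length for fitting bounds.
#' @return An `"lc_fit"` (see [fit_learning_curve()]).
#' @export
fit_averaged_curve <- function(cohort, max_count = 16) {
  tm <- if (is.matrix(cohort)) cohort
        else as.matrix(as.data.frame(cohort)[paste0("t", 1:5)])
  if (nrow(tm) == 0) stop("empty cohort subset", call. = FALSE)
  fit_learning_curve(colMeans(tm), max_count = max_count)
}

# Univariate discriminant pass for one coefficient within one sex
# stratum: cluster both diagnosis groups on the coefficient, train on
# control-higher vs patient-lower, verify on the held-out clusters.
coefficient_analysis <- function(coef_name, ctrl_vals, pat_vals,
                                 ctrl_trials, pat_trials, config) {
  out <- list(coefficient = coef_name)
  out$control_clusters <- two_means_1d(ctrl_vals)
  out$patient_clusters <- two_means_1d(pat_vals)

  ch <- ctrl_vals[out$control_clusters$labels == "higher"]
  cl <- ctrl_vals[out$control_clusters$labels == "lower"]
  pl <- pat_vals[out$patient_clusters$labels == "lower"]
  ph <- pat_vals[out$patient_clusters$labels == "higher"]

  # averaged raw-trial curves of each coefficient cluster
  out$cluster_curves <- list(
    control_higher = fit_averaged_curve(
      ctrl_trials[out$control_clusters$labels == "higher", , drop = FALSE],
      config$max_count),
    control_lower = fit_averaged_curve(
      ctrl_trials[out$control_clusters$labels == "lower", , drop = FALSE],
      config$max_count),
    patient_lower = fit_averaged_curve(
      pat_trials[out$patient_clusters$labels == "lower", , drop = FALSE],
      config$max_count),
    patient_higher = fit_averaged_curve(
      pat_trials[out$patient_clusters$labels == "higher", , drop = FALSE],
      config$max_count)
  )

  if (length(ch) >= 3 && length(pl) >= 3) {
    m <- matrix(ch, ncol = 1, dimnames = list(NULL, coef_name))
    p <- matrix(pl, ncol = 1, dimnames = list(NULL, coef_name))
    model <- fit_lda(m, p, groups = c("control", "patient"),
                     boundary = config$boundary)
    out$model <- model
    out$cutoff <- threshold_from_function(
      model$coefficients[["C0"]], model$coefficients[[coef_name]],
      model$boundary)
    out$holdout_control_lower <- if (length(cl) > 0) {
      verify_holdout(model, matrix(cl, ncol = 1), "control")
    }
    out$holdout_patient_higher <- if (length(ph) > 0) {
      verify_holdout(model, matrix(ph, ncol = 1), "control")
    }
  } else {
    out$skipped <- sprintf(
      "training clusters too small (control-higher %d, patient-lower %d)",
      length(ch), length(pl))
  }
  out
}

#' Run the full memory-impairment analysis on a cohort
#'
#' For each sex stratum with both diagnosis groups present: compare the
#' groups per trial (pooled t-tests); fit every subject's learning curve
#' (non-convergent fits are excluded from coefficient analyses and
#' counted); cluster each diagnosis group by fitted `B3` and by `B4`
#' (exact two-means); train a univariate discriminant function on the
#' higher memory-functioning cluster of controls versus the lower cluster
#' of patients — the selection rule throughout — with boundary value,
#' Wilks' lambda, Bartlett chi-square and the predictor-space impairment
#' cutoff; verify it on the held-out clusters (control-lower,
#' patient-higher, counting cases classified on the healthy side); and
#' fit averaged curves per group and per cluster. Optionally the raw
#' trials 1-5 analyses (whole-group LDA and Ward-cluster LDA) are run for
#' comparison.
#'
#' @param cohort a cohort data frame (see [read_cohort_csv()]).
#' @param config a [pipeline_config()].
#' @return A list of class `"lc_report"` with one entry per analysed sex
#'   stratum plus skip records. The analysis is deterministic: identical
#'   cohort and config give an identical report.
#' @export
run_full_analysis <- function(cohort, config = pipeline_config()) {
  cohort <- validate_cohort(as.data.frame(cohort),
                            max_count = config$max_count)
  report <- list(config = config, n_subjects = nrow(cohort),
                 strata = list(), skipped = list())

  for (sx in c("F", "M")) {
    sub <- cohort[cohort$sex == sx, , drop = FALSE]
    ctrl <- sub[sub$diagnosis == "control", , drop = FALSE]
    pat <- sub[sub$diagnosis == "patient", , drop = FALSE]
    if (nrow(ctrl) < config$min_stratum || nrow(pat) < config$min_stratum) {
      msg <- sprintf(
        "stratum %s skipped: %d control(s), %d patient(s) (minimum %d each)",
        sx, nrow(ctrl), nrow(pat), config$min_stratum)
      warning(msg, call. = FALSE)
      report$skipped[[sx]] <- msg
      next
    }
    stratum <- list(sex = sx,
                    n_control = nrow(ctrl), n_patient = nrow(pat))
    ct <- as.matrix(ctrl[paste0("t", 1:5)])
    pt <- as.matrix(pat[paste0("t", 1:5)])

    stratum$trial_t_tests <- compare_group_means(ct, pt)
    stratum$averaged_curves <- list(
      control = fit_averaged_curve(ctrl, config$max_count),
      patient = fit_averaged_curve(pat, config$max_count)
    )

    if (config$include_trials_analysis) {
      trials <- list()
      trials$whole_group_lda <- tryCatch(
        fit_lda(ct, pt, groups = c("control", "patient"),
                boundary = config$boundary),
        error = function(e) conditionMessage(e))
      trials$control_clusters <- tryCatch(
        ward_trials(ct, standardize = config$standardize_trials),
        error = function(e) conditionMessage(e))
      trials$patient_clusters <- tryCatch(
        ward_trials(pt, standardize = config$standardize_trials),
        error = function(e) conditionMessage(e))
      if (inherits(trials$control_clusters, "lc_clusters") &&
          inherits(trials$patient_clusters, "lc_clusters")) {
        chm <- ct[trials$control_clusters$labels == "higher", ,
                  drop = FALSE]
        plm <- pt[trials$patient_clusters$labels == "lower", ,
                  drop = FALSE]
        trials$cluster_curves <- list(
          control_higher = fit_averaged_curve(
            ctrl[trials$control_clusters$labels == "higher", ],
            config$max_count),
          control_lower = fit_averaged_curve(
            ctrl[trials$control_clusters$labels == "lower", ],
            config$max_count),
          patient_lower = fit_averaged_curve(
            pat[trials$patient_clusters$labels == "lower", ],
            config$max_count),
          patient_higher = fit_averaged_curve(
            pat[trials$patient_clusters$labels == "higher", ],
            config$max_count)
        )
        trials$cluster_lda <- tryCatch(
          fit_lda(chm, plm, groups = c("control", "patient"),
                  boundary = config$boundary),
          error = function(e) conditionMessage(e))
      }
      stratum$trials_analysis <- trials
    }

    fit_one <- function(m) {
      lapply(seq_len(nrow(m)), function(i) {
        fit_learning_curve(m[i, ], max_count = config$max_count)
      })
    }
    cfits <- fit_one(ct)
    pfits <- fit_one(pt)
    cconv <- vapply(cfits, function(f) f$converged, TRUE)
    pconv <- vapply(pfits, function(f) f$converged, TRUE)
    stratum$n_nonconverged <- sum(!cconv) + sum(!pconv)
    stratum$subject_fits <- list(control = cfits, patient = pfits)

    stratum$coefficient_analyses <- list()
    for (cf in c("B3", "B4")) {
      cv <- vapply(cfits[cconv], function(f) f$params[[cf]], 0.0)
      pv <- vapply(pfits[pconv], function(f) f$params[[cf]], 0.0)
      stratum$coefficient_analyses[[cf]] <- tryCatch(
        coefficient_analysis(cf, cv, pv, ct[cconv, , drop = FALSE],
                             pt[pconv, , drop = FALSE], config),
        error = function(e) list(coefficient = cf,
                                 skipped = conditionMessage(e)))
    }
    report$strata[[sx]] <- stratum
  }
  if (length(report$strata) == 0) {
    stop("no analysable stratum in cohort", call. = FALSE)
  }
  class(report) <- "lc_report"
  report
}

#' @export
print.lc_report <- function(x, ...) {
  cat("Memory-impairment analysis report:", x$n_subjects, "subjects,",
      length(x$strata), "sex stratum/strata\n")
  for (sx in names(x$strata)) {
    st <- x$strata[[sx]]
    cat(sprintf("\n== Sex %s: %d controls, %d patients (%d fit failures)\n",
                sx, st$n_control, st$n_patient, st$n_nonconverged))
    for (cf in names(st$coefficient_analyses)) {
      ca <- st$coefficient_analyses[[cf]]
      if (!is.null(ca$skipped)) {
        cat(sprintf("  %s: skipped (%s)\n", cf, ca$skipped))
        next
      }
      m <- ca$model
      cat(sprintf(
        "  %s: y = %.3f + %.3f*%s, Y_b = %.3f -> cutoff %.2f words\n",
        cf, m$coefficients[["C0"]], m$coefficients[[cf]], cf,
        m$boundary, ca$cutoff))
      cat(sprintf(
        "      lambda = %.3f, chi2(%d) = %.3f, P = %.3g; training %s\n",
        m$wilks_lambda, m$df, m$chi2, m$p_value,
        paste(sprintf("%s %.1f%%", m$training$group,
                      m$training$percent_correct), collapse = ", ")))
    }
  }
  for (msg in x$skipped) cat("\n", msg, "\n", sep = "")
  invisible(x)
}

#' Check a report's internal consistency
#'
#' Recomputes, from the models stored in the report, every derived
#' quantity the report also stores — predictor cutoffs via
#' [threshold_from_function()], boundary placement between the centroids,
#' classification counts and percentages — and collects any mismatch.
#'
#' @param report an `"lc_report"`.
#' @return `TRUE` if consistent, otherwise a character vector of issues.
#' @export
verify_report <- function(report) {
  issues <- character(0)
  for (sx in names(report$strata)) {
    st <- report$strata[[sx]]
    for (cf in names(st$coefficient_analyses)) {
      ca <- st$coefficient_analyses[[cf]]
      if (!is.null(ca$skipped)) next
      m <- ca$model
      cut2 <- threshold_from_function(m$coefficients[["C0"]],
                                      m$coefficients[[cf]], m$boundary)
      if (abs(cut2 - ca$cutoff) > 1e-10) {
        issues <- c(issues, sprintf("%s/%s: stored cutoff %.6f != %.6f",
                                    sx, cf, ca$cutoff, cut2))
      }
      if (!(m$boundary > min(m$centroids) && m$boundary < max(m$centroids))) {
        issues <- c(issues, sprintf("%s/%s: boundary outside centroids",
                                    sx, cf))
      }
      tr <- m$training
      if (any(tr$correct + tr$incorrect != tr$n) ||
          any(abs(tr$percent_correct - 100 * tr$correct / tr$n) > 1e-9)) {
        issues <- c(issues, sprintf("%s/%s: inconsistent training counts",
                                    sx, cf))
      }
      for (h in c("holdout_control_lower", "holdout_patient_higher")) {
        ho <- ca[[h]]
        if (is.null(ho)) next
        if (abs(ho$percent_match - 100 * ho$n_match / ho$n) > 1e-9) {
          issues <- c(issues, sprintf("%s/%s: inconsistent %s", sx, cf, h))
        }
      }
    }
  }
  if (length(issues) == 0) TRUE else issues
}

# Strip an lc_report down to JSON-serialisable pieces.
report_to_list <- function(report) {
  fit_lst <- function(f) {
    if (is.null(f)) return(NULL)
    list(params = as.list(f$params), se = as.list(f$se),
         r_squared = f$r_squared, converged = f$converged,
         n_points = f$n_points)
  }
  lda_lst <- function(m) {
    if (is.null(m) || !inherits(m, "lc_lda")) return(m)
    list(coefficients = as.list(m$coefficients), boundary = m$boundary,
         wilks_lambda = m$wilks_lambda, chi2 = m$chi2, df = m$df,
         p_value = m$p_value, centroids = as.list(m$centroids),
         n_per_group = as.list(m$n_per_group),
         training = m$training)
  }
  clus_lst <- function(cl) {
    if (is.null(cl) || !inherits(cl, "lc_clusters")) return(cl)
    out <- list(sizes = as.list(cl$sizes), method = cl$method)
    if (!is.null(cl$ranges)) out$ranges <- cl$ranges
    if (!is.null(cl$centers)) out$centers <- cl$centers
    out
  }
  strata <- lapply(report$strata, function(st) {
    ca <- lapply(st$coefficient_analyses, function(a) {
      if (!is.null(a$skipped)) return(list(coefficient = a$coefficient,
                                           skipped = a$skipped))
      list(coefficient = a$coefficient,
           control_clusters = clus_lst(a$control_clusters),
           patient_clusters = clus_lst(a$patient_clusters),
           model = lda_lst(a$model), cutoff = a$cutoff,
           cluster_curves = lapply(a$cluster_curves, fit_lst),
           holdout_control_lower =
             a$holdout_control_lower[c("n", "n_match", "percent_match")],
           holdout_patient_higher =
             a$holdout_patient_higher[c("n", "n_match", "percent_match")])
    })
    out <- list(sex = st$sex, n_control = st$n_control,
                n_patient = st$n_patient,
                n_nonconverged = st$n_nonconverged,
                trial_t_tests = st$trial_t_tests,
                averaged_curves = lapply(st$averaged_curves, fit_lst),
                coefficient_analyses = ca)
    if (!is.null(st$trials_analysis)) {
      ta <- st$trials_analysis
      out$trials_analysis <- list(
        whole_group_lda = lda_lst(ta$whole_group_lda),
        control_clusters = clus_lst(ta$control_clusters),
        patient_clusters = clus_lst(ta$patient_clusters),
        cluster_curves = lapply(ta$cluster_curves, fit_lst),
        cluster_lda = lda_lst(ta$cluster_lda))
    }
    out
  })
  list(n_subjects = report$n_subjects,
       config = unclass(report$config),
       strata = strata, skipped = report$skipped)
}

# Plain-text table rendering mirroring the published tables' layout:
# per-trial means by group/cluster, then averaged-curve coefficients,
# then the discriminant summary per coefficient.
render_report_text <- function(report) {
  lines <- c("Memory-impairment analysis report",
             sprintf("Subjects: %d", report$n_subjects), "")
  fmt_fit <- function(f) {
    if (is.null(f) || !f$converged) return("fit failed")
    sprintf("B2 %5.2f +/- %4.2f  B3 %5.2f +/- %4.2f  B4 %5.2f +/- %4.2f  R2 %.4f",
            f$params[["B2"]], f$se[["B2"]], f$params[["B3"]], f$se[["B3"]],
            f$params[["B4"]], f$se[["B4"]], f$r_squared)
  }
  for (sx in names(report$strata)) {
    st <- report$strata[[sx]]
    lines <- c(lines, sprintf("=== Sex %s (%d controls, %d patients)",
                              sx, st$n_control, st$n_patient))
    lines <- c(lines, "Averaged learning curves:")
    for (g in names(st$averaged_curves)) {
      lines <- c(lines, sprintf("  %-16s %s", g,
                                fmt_fit(st$averaged_curves[[g]])))
    }
    for (cf in names(st$coefficient_analyses)) {
      ca <- st$coefficient_analyses[[cf]]
      if (!is.null(ca$skipped)) {
        lines <- c(lines, sprintf("%s analysis skipped: %s", cf,
                                  ca$skipped))
        next
      }
      m <- ca$model
      lines <- c(lines, sprintf("%s clusters and discriminant:", cf))
      lines <- c(lines, sprintf(
        "  control lower/higher n = %d/%d, patient lower/higher n = %d/%d",
        ca$control_clusters$sizes[["lower"]],
        ca$control_clusters$sizes[["higher"]],
        ca$patient_clusters$sizes[["lower"]],
        ca$patient_clusters$sizes[["higher"]]))
      for (g in names(ca$cluster_curves)) {
        lines <- c(lines, sprintf("  %-16s %s", g,
                                  fmt_fit(ca$cluster_curves[[g]])))
      }
      lines <- c(lines, sprintf(
        "  y = %.3f + %.3f*%s, Y_b = %.3f, lambda = %.3f, chi2 = %.3f, cutoff = %.2f",
        m$coefficients[["C0"]], m$coefficients[[cf]], cf, m$boundary,
        m$wilks_lambda, m$chi2, ca$cutoff))
      pc <- m$training$percent_correct
      lines <- c(lines, sprintf(
        "  training correct: control %.1f%%, patient %.1f%%", pc[1], pc[2]))
    }
    lines <- c(lines, "")
  }
  for (msg in report$skipped) lines <- c(lines, msg)
  lines
}

#' Write an analysis report to disk
#'
#' Serialises the report as structured JSON and, optionally, as a
#' human-readable plain-text rendering of the main tables.
#'
#' @param report an `"lc_report"` from [run_full_analysis()].
#' @param path output JSON path.
#' @param text_path optional plain-text output path.
#' @export
write_report <- function(report, path, text_path = NULL) {
  stopifnot(inherits(report, "lc_report"))
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null",
                       dataframe = "rows")
  if (!is.null(text_path)) {
    writeLines(render_report_text(report), text_path)
  }
  invisible(path)
}
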