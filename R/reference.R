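# Bundled group-level reference values from the published CVLT-II
# multiple-sclerosis learning-curve study this package operationalises:
# per-trial mean recall for 14 groups/clusters, averaged-curve model
# coefficients, the printed univariate discriminant functions with their
# boundaries and clinical cutoffs, and the printed Wilks'-lambda tests.
# Individual-level data were never deposited; these summaries are the
# only reproducible surface and double as test fixtures.

#' Published per-trial mean recall by group
#'
#' Mean CVLT-II List A recall on trials 1-5 for the study's groups and
#' trial-score clusters (98 healthy controls, 365 MS patients; male/female
#' strata; lower/higher memory-functioning Ward clusters of trials 1-5).
#' Each row is an averaged learning curve to which
#' [fit_learning_curve()] can be applied.
#'
#' @format A data frame with 14 rows: `item` (table row number), `group`
#'   (description), `diagnosis`, `sex`, `cluster` (`all`, `lower` or
#'   `higher`), `n`, and `t1`..`t5` (mean words recalled).
#' @export
cvlt_trial_means <- local({
  rows <- list(
    list(1, "Healthy participants, total", "control", "all", "all", 98,
         c(7.26, 10.67, 12.22, 13.09, 13.76)),
    list(2, "MS patients, total", "patient", "all", "all", 365,
         c(6.15, 9.16, 10.46, 11.32, 11.66)),
    list(3, "Healthy participants, males", "control", "M", "all", 20,
         c(5.90, 8.75, 10.75, 11.55, 12.50)),
    list(4, "Healthy participants, females", "control", "F", "all", 78,
         c(7.60, 11.17, 12.60, 13.49, 14.08)),
    list(5, "MS patients, males", "patient", "M", "all", 99,
         c(5.65, 8.15, 9.30, 10.17, 10.42)),
    list(6, "MS patients, females", "patient", "F", "all", 266,
         c(6.33, 9.53, 10.89, 11.74, 12.12)),
    list(7, "Healthy males, lower trials cluster", "control", "M", "lower",
         9, c(4.44, 7.44, 9.78, 10.33, 11.00)),
    list(8, "Healthy males, higher trials cluster", "control", "M",
         "higher", 11, c(6.82, 9.82, 11.27, 12.36, 13.55)),
    list(9, "MS males, lower trials cluster", "patient", "M", "lower", 46,
         c(4.78, 6.41, 7.20, 7.63, 8.02)),
    list(10, "MS males, higher trials cluster", "patient", "M", "higher",
         53, c(6.40, 9.66, 11.13, 12.38, 12.51)),
    list(11, "Healthy females, lower trials cluster", "control", "F",
         "lower", 38, c(6.82, 9.68, 10.92, 12.24, 13.24)),
    list(12, "Healthy females, higher trials cluster", "control", "F",
         "higher", 40, c(8.35, 12.58, 14.20, 14.68, 14.88)),
    list(13, "MS females, lower trials cluster", "patient", "F", "lower",
         133, c(5.32, 7.73, 8.75, 9.68, 10.29)),
    list(14, "MS females, higher trials cluster", "patient", "F", "higher",
         133, c(7.35, 11.34, 13.02, 13.81, 13.95))
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(item = r[[1]], group = r[[2]], diagnosis = r[[3]],
               sex = r[[4]], cluster = r[[5]], n = r[[6]],
               t1 = r[[7]][1], t2 = r[[7]][2], t3 = r[[7]][3],
               t4 = r[[7]][4], t5 = r[[7]][5])
  }))
  rownames(out) <- NULL
  out
})

#' Published averaged-curve model coefficients
#'
#' Coefficients (with asymptotic SEs, and R-squared where printed) of the
#' learning-curve model fitted to averaged curves: rows 1-6 are the
#' whole-group curves matching `cvlt_trial_means` items 1-6; rows with
#' `source = "trials-cluster"` are the curves of the Ward trial-score
#' clusters (`cvlt_trial_means` items 7-14, no R-squared printed); rows
#' with `source = "coef-cluster"` are the curves of the two-means B3/B4
#' coefficient clusters used to seed the synthetic-cohort generator.
#' `mean_item` links each row to its `cvlt_trial_means` row where one
#' exists.
#'
#' @format A data frame with columns `group`, `diagnosis`, `sex`,
#'   `cluster`, `cluster_by`, `source`, `mean_item`, `B2`, `B2_se`, `B3`,
#'   `B3_se`, `B4`, `B4_se`, `r_squared`, `n`.
#' @export
cvlt_curve_fits <- local({
  r <- function(group, diagnosis, sex, cluster, cluster_by, source,
                mean_item, B2, B2_se, B3, B3_se, B4, B4_se, r2, n) {
    data.frame(group = group, diagnosis = diagnosis, sex = sex,
               cluster = cluster, cluster_by = cluster_by, source = source,
               mean_item = mean_item, B2 = B2, B2_se = B2_se, B3 = B3,
               B3_se = B3_se, B4 = B4, B4_se = B4_se, r_squared = r2,
               n = n)
  }
  out <- rbind(
    r("All healthy participants", "control", "all", "all", NA, "group",
      1, 0.65, 0.06, 7.28, 0.13, 14.17, 0.22, 0.9987, 98),
    r("Female healthy participants", "control", "F", "all", NA, "group",
      4, 0.70, 0.07, 7.63, 0.15, 14.38, 0.23, 0.9982, 78),
    r("Male healthy participants", "control", "M", "all", NA, "group",
      3, 0.47, 0.06, 5.90, 0.17, 13.58, 0.48, 0.9978, 20),
    r("All MS patients", "patient", "all", "all", NA, "group",
      2, 0.70, 0.04, 6.16, 0.09, 12.01, 0.13, 0.9992, 365),
    r("Female MS patients", "patient", "F", "all", NA, "group",
      6, 0.72, 0.04, 6.35, 0.09, 12.44, 0.13, 0.9993, 266),
    r("Male MS patients", "patient", "M", "all", NA, "group",
      5, 0.64, 0.06, 5.66, 0.10, 10.86, 0.17, 0.9987, 99),
    # averaged curves of the Ward trials 1-5 clusters (no printed R^2)
    r("Healthy males, lower trials cluster", "control", "M", "lower",
      "trials", "trials-cluster", 7, NA, NA, 4.39, 0.29, 11.69, 0.55,
      NA, 9),
    r("Healthy males, higher trials cluster", "control", "M", "higher",
      "trials", "trials-cluster", 8, NA, NA, 6.90, 0.27, 15.00, 1.00,
      NA, 11),
    r("MS males, lower trials cluster", "patient", "M", "lower",
      "trials", "trials-cluster", 9, NA, NA, 4.80, 0.08, 8.29, 0.14,
      NA, 46),
    r("MS males, higher trials cluster", "patient", "M", "higher",
      "trials", "trials-cluster", 10, NA, NA, 6.40, 0.21, 13.10, 0.34,
      NA, 53),
    r("Healthy females, lower trials cluster", "control", "F", "lower",
      "trials", "trials-cluster", 11, NA, NA, 6.90, 0.26, 14.92, 1.11,
      NA, 38),
    r("Healthy females, higher trials cluster", "control", "F", "higher",
      "trials", "trials-cluster", 12, NA, NA, 8.34, 0.05, 15.01, 0.04,
      NA, 40),
    r("MS females, lower trials cluster", "patient", "F", "lower",
      "trials", "trials-cluster", 13, NA, NA, 5.36, 0.17, 10.99, 0.44,
      NA, 133),
    r("MS females, higher trials cluster", "patient", "F", "higher",
      "trials", "trials-cluster", 14, NA, NA, 7.34, 0.08, 14.22, 0.09,
      NA, 133),
    # averaged curves of the two-means B3/B4 coefficient clusters
    r("Healthy males, lower B3 cluster", "control", "M", "lower", "B3",
      "coef-cluster", NA, 0.4407, 0.0902, 3.91, 0.30, 13.72, 0.95,
      0.9956, 9),
    r("Healthy males, higher B3 cluster", "control", "M", "higher", "B3",
      "coef-cluster", NA, 0.5274, 0.177, 7.50, 0.36, 13.46, 0.85,
      0.9850, 11),
    r("Healthy males, lower B4 cluster", "control", "M", "lower", "B4",
      "coef-cluster", NA, 1.1353, 0.3044, 4.38, 0.42, 9.96, 0.37,
      0.9838, 5),
    r("Healthy males, higher B4 cluster", "control", "M", "higher", "B4",
      "coef-cluster", NA, 0.3361, 0.0317, 6.39, 0.09, 15.76, 0.49,
      0.9994, 15),
    r("MS males, lower B3 cluster", "patient", "M", "lower", "B3",
      "coef-cluster", NA, 0.6505, 0.0344, 4.26, 0.06, 9.81, 0.11,
      0.9995, 48),
    r("MS males, higher B3 cluster", "patient", "M", "higher", "B3",
      "coef-cluster", NA, 0.6179, 0.0821, 6.97, 0.14, 11.85, 0.25,
      0.9971, 51),
    r("MS males, lower B4 cluster", "patient", "M", "lower", "B4",
      "coef-cluster", NA, 0.8192, 0.0252, 5.17, 0.03, 8.74, 0.03,
      0.9998, 59),
    r("MS males, higher B4 cluster", "patient", "M", "higher", "B4",
      "coef-cluster", NA, 0.5087, 0.1041, 6.37, 0.28, 14.21, 0.69,
      0.9946, 40),
    r("Healthy females, lower B3 cluster", "control", "F", "lower", "B3",
      "coef-cluster", NA, 0.7231, 0.0807, 5.27, 0.24, 14.28, 0.34,
      0.9976, 22),
    r("Healthy females, higher B3 cluster", "control", "F", "higher", "B3",
      "coef-cluster", NA, 0.6877, 0.064, 8.56, 0.12, 14.43, 0.19,
      0.9984, 56),
    r("Healthy females, lower B4 cluster", "control", "F", "lower", "B4",
      "coef-cluster", NA, 2.0767, 3.6190, 6.98, 1.44, 10.81, 0.92,
      0.7277, 3),
    r("Healthy females, higher B4 cluster", "control", "F", "higher", "B4",
      "coef-cluster", NA, 0.6616, 0.0855, 7.67, 0.20, 14.63, 0.33,
      0.9971, 75),
    r("MS females, lower B3 cluster", "patient", "F", "lower", "B3",
      "coef-cluster", NA, 0.6286, 0.0614, 5.06, 0.14, 11.62, 0.24,
      0.9984, 152),
    r("MS females, higher B3 cluster", "patient", "F", "higher", "B3",
      "coef-cluster", NA, 0.8507, 0.0109, 8.08, 0.02, 13.63, 0.02,
      0.9999, 114),
    r("MS females, lower B4 cluster", "patient", "F", "lower", "B4",
      "coef-cluster", NA, 0.8642, 0.0812, 5.40, 0.11, 9.88, 0.13,
      0.9981, 109),
    r("MS females, higher B4 cluster", "patient", "F", "higher", "B4",
      "coef-cluster", NA, 0.6541, 0.0431, 7.01, 0.11, 14.26, 0.17,
      0.9992, 157)
  )
  rownames(out) <- NULL
  out
})

#' Published discriminant functions, boundaries and clinical cutoffs
#'
#' The univariate (B3 or B4, per sex) discriminant functions reported by
#' the reference study, with their boundary values and the clinical
#' impairment cutoffs obtained by inverting each function at its boundary
#' (a male patient with `B3 < 5.84` words has impaired readiness to
#' learn, `B4 < 12.03` impaired ability to learn; females: 6.76 and
#' 12.79). `published_cutoff` carries the cutoff exactly as printed;
#' [threshold_from_function()] recomputes it from `c0`, `c1` and
#' `boundary`.
#'
#' @format A data frame with columns `sex`, `predictor`, `c0`, `c1`,
#'   `boundary`, `published_cutoff`, `wilks_lambda`, `chi2`, `n_reference`
#'   (training healthy cluster size), `n_patient` (training patient
#'   cluster size).
#' @export
cvlt_discriminant_functions <- local({
  out <- data.frame(
    sex = c("M", "M", "F", "F"),
    predictor = c("B3", "B4", "B3", "B4"),
    c0 = c(-4.518, -4.923, -4.923, -8.399),
    c1 = c(0.937, 0.466, 0.827, 0.679),
    boundary = c(0.958, 0.681, 0.672, 0.285),
    published_cutoff = c(5.84, 12.03, 6.76, 12.79),
    wilks_lambda = c(0.406, 0.534, 0.372, 0.301),
    chi2 = c(50.958, 44.820, 202.964, 217.890),
    n_reference = c(11, 15, 56, 75),
    n_patient = c(48, 59, 152, 109)
  )
  out
})

#' Published multivariate (trials 1-5) discriminant functions
#'
#' The five-predictor discriminant functions on raw trial scores, stored
#' for [classify()] / [threshold_from_function()]-style use only: they
#' cannot be re-derived without the study's individual-level data.
#'
#' @format A data frame with columns `analysis`, `sex`, `c0`, `c1`..`c5`,
#'   `boundary`.
#' @export
cvlt_trials_discriminants <- data.frame(
  analysis = c("whole-group", "whole-group", "whole-group",
               "trials-clusters", "trials-clusters"),
  sex = c("all", "M", "F", "M", "F"),
  c0 = c(-4.774, -2.666, -5.378, -5.123, -7.326),
  c1 = c(0.1564, -0.104, 0.200, -0.160, 0.121),
  c2 = c(-0.040, -0.245, 0.245, 0.180, 0.191),
  c3 = c(0.047, 0.295, -0.018, 0.186, 0.295),
  c4 = c(-0.04906, -0.306, 0.011, 0.115, 0.114),
  c5 = c(0.349, 0.523, 0.319, 0.287, 0.063),
  boundary = c(0.420, 0.305, 0.242, 1.459, 1.881)
)

#' Published Wilks'-lambda tests
#'
#' Every printed (Wilks' lambda, chi-square) pair of the reference study
#' with its group sizes and predictor count, for reconciliation against
#' [bartlett_chi2()].
#'
#' @format A data frame with columns `analysis`, `sex`, `predictors` (p),
#'   `n_a`, `n_b`, `wilks_lambda`, `chi2`.
#' @export
cvlt_wilks_tests <- data.frame(
  analysis = c("trials whole-group", "trials whole-group males",
               "trials whole-group females", "trials clusters males",
               "trials clusters females", "B3 males", "B4 males",
               "B3 females", "B4 females"),
  sex = c("all", "M", "F", "M", "F", "M", "M", "F", "F"),
  predictors = c(5, 5, 5, 5, 5, 1, 1, 1, 1),
  n_a = c(98, 20, 78, 11, 40, 11, 15, 56, 75),
  n_b = c(365, 99, 266, 46, 133, 48, 59, 152, 109),
  wilks_lambda = c(0.894, 0.893, 0.878, 0.421, 0.282, 0.406, 0.534,
                   0.372, 0.301),
  chi2 = c(51.25, 12.996, 44.064, 45.4, 213, 50.958, 44.820, 202.964,
           217.890)
)

#' Reference cohort cell sizes
#'
#' The study's gender-by-diagnosis cell sizes (98 healthy controls: 78 F /
#' 20 M; 365 MS patients: 266 F / 99 M), handy as `n_per_cell` for
#' [generate_cohort()] when a cohort of realistic shape is wanted.
#'
#' @return Named integer vector with names `"M.control"`, `"F.control"`,
#'   `"M.patient"`, `"F.patient"`.
#' @export
reference_cell_sizes <- function() {
  c(M.control = 20L, F.control = 78L, M.patient = 99L, F.patient = 266L)
}
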