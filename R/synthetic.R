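# Seeded synthetic cohorts with the latent structure the analysis
# assumes: gender x diagnosis cells, each a two-component mixture of
# lower/higher memory-functioning subjects whose trial scores follow the
# learning-curve model plus observation noise.

#' Default synthetic population specification
#'
#' One row per gender x diagnosis x subgroup. Subgroup coefficient means
#' are the published averaged-curve coefficients of the two-means B3
#' clusters (e.g. MS-male lower: B3 = 4.26, B4 = 9.81; healthy-male
#' higher: B3 = 7.50, B4 = 13.46; healthy-female higher: B3 = 8.56,
#' B4 = 14.43; MS-female lower: B3 = 5.06, B4 = 11.62). Between-subject
#' SDs default to 1.0 for B3/B4 and 0.15 for B2 (a rate near 0.65 with SD
#' 1 would be unrealistically dispersed under truncation at zero);
#' per-trial observation noise SD is 1.0 word. Patient cells split
#' 50/50 between subgroups; control cells use the published lower-cluster
#' proportions (males 9/20, females 22/78).
#'
#' @return A data frame of class `"lc_population_spec"` with columns
#'   `sex`, `diagnosis`, `subgroup`, `weight`, `b2_mean`, `b2_sd`,
#'   `b3_mean`, `b3_sd`, `b4_mean`, `b4_sd`, `noise_sd`.
#' @export
default_population_spec <- function() {
  ref <- cvlt_curve_fits[cvlt_curve_fits$source == "coef-cluster" &
                           cvlt_curve_fits$cluster_by == "B3", ]
  key <- paste(ref$sex, ref$diagnosis, ref$cluster)
  pick <- function(sex, diagnosis, cluster, field) {
    ref[[field]][key == paste(sex, diagnosis, cluster)]
  }
  cells <- expand.grid(subgroup = c("lower", "higher"),
                       diagnosis = c("control", "patient"),
                       sex = c("M", "F"), stringsAsFactors = FALSE)
  lower_weight <- c(`M.control` = 9 / 20, `F.control` = 22 / 78,
                    `M.patient` = 0.5, `F.patient` = 0.5)
  spec <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sx <- cells$sex[i]; dg <- cells$diagnosis[i]; sg <- cells$subgroup[i]
    lw <- lower_weight[[paste(sx, dg, sep = ".")]]
    data.frame(
      sex = sx, diagnosis = dg, subgroup = sg,
      weight = if (sg == "lower") lw else 1 - lw,
      b2_mean = pick(sx, dg, sg, "B2"), b2_sd = 0.15,
      b3_mean = pick(sx, dg, sg, "B3"), b3_sd = 1.0,
      b4_mean = pick(sx, dg, sg, "B4"), b4_sd = 1.0,
      noise_sd = 1.0
    )
  }))
  rownames(spec) <- NULL
  class(spec) <- c("lc_population_spec", "data.frame")
  spec
}

validate_population_spec <- function(spec) {
  req <- c("sex", "diagnosis", "subgroup", "weight", "b2_mean", "b2_sd",
           "b3_mean", "b3_sd", "b4_mean", "b4_sd", "noise_sd")
  miss <- setdiff(req, names(spec))
  if (length(miss) > 0) {
    stop("population spec is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sds <- unlist(spec[c("b2_sd", "b3_sd", "b4_sd", "noise_sd")])
  if (any(sds < 0)) stop("spec SDs must be >= 0", call. = FALSE)
  if (any(spec$weight < 0 | spec$weight > 1)) {
    stop("spec weights must lie in [0, 1]", call. = FALSE)
  }
  cellkey <- paste(spec$sex, spec$diagnosis)
  wsum <- tapply(spec$weight, cellkey, sum)
  if (any(abs(wsum - 1) > 1e-8)) {
    stop("subgroup weights must sum to 1 within each sex x diagnosis cell",
         call. = FALSE)
  }
  if (any(spec$b2_mean <= 0)) stop("b2_mean must be > 0", call. = FALSE)
  invisible(TRUE)
}

# Truncated-normal draw by resampling (avoids point masses at bounds).
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    tries <- tries + 1
  }
  if (length(bad) > 0) out[bad] <- pmin(pmax(out[bad], lower), upper)
  out
}

#' Generate a synthetic cohort
#'
#' For each subject: draw a latent lower/higher subgroup by the cell
#' weights, draw true coefficients `(B2, B3, B4)` from truncated normals
#' within the model bounds, evaluate the learning curve at trials 1-5 and
#' add per-trial observation noise. Gaussian noise is added then rounded
#' and clipped to `[0, max_count]`; the `"binomial"` alternative draws
#' `t_x ~ Binomial(max_count, y_x / max_count)`, which yields integer
#' counts with recall-level-dependent variance.
#'
#' @param spec a population spec as from [default_population_spec()].
#' @param n_per_cell subjects per sex x diagnosis cell: a single number,
#'   or a named vector like `c(M.control = 20, F.control = 78,
#'   M.patient = 99, F.patient = 266)` (see [reference_cell_sizes()]).
#' @param seed integer seed; the cohort is reproducible given the seed.
#' @param noise `"gaussian"` (default) or `"binomial"`.
#' @param round_counts round and clip trial scores to integers in
#'   `[0, max_count]`; disable (with gaussian noise) for exact
#'   parameter-recovery studies.
#' @param max_count list length, default 16.
#' @return A data frame of class `"lc_cohort"`: `subject_id`, `diagnosis`,
#'   `sex`, `t1`..`t5`, plus the latent truths `subgroup`, `B2`, `B3`,
#'   `B4` (drop them, or use [write_cohort_csv()], for a plain cohort
#'   table).
#' @export
generate_cohort <- function(spec = default_population_spec(),
                            n_per_cell = 50, seed = NULL,
                            noise = c("gaussian", "binomial"),
                            round_counts = TRUE, max_count = 16) {
  noise <- match.arg(noise)
  validate_population_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  cells <- unique(spec[c("sex", "diagnosis")])
  cellnames <- paste(cells$sex, cells$diagnosis, sep = ".")
  if (length(n_per_cell) == 1 && is.null(names(n_per_cell))) {
    n_cell <- stats::setNames(rep(as.integer(n_per_cell),
                                  nrow(cells)), cellnames)
  } else {
    miss <- setdiff(cellnames, names(n_per_cell))
    if (length(miss) > 0) {
      stop("n_per_cell is missing cells: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    n_cell <- as.integer(n_per_cell[cellnames])
    names(n_cell) <- cellnames
  }
  if (any(n_cell < 1)) stop("n_per_cell must be >= 1", call. = FALSE)

  bounds <- default_lc_bounds(max_count)
  rows <- list()
  idx <- 0
  for (ci in seq_len(nrow(cells))) {
    sx <- cells$sex[ci]; dg <- cells$diagnosis[ci]
    sub <- spec[spec$sex == sx & spec$diagnosis == dg, ]
    n <- n_cell[[paste(sx, dg, sep = ".")]]
    pick <- sample(seq_len(nrow(sub)), n, replace = TRUE,
                   prob = sub$weight)
    for (i in seq_len(n)) {
      sg <- sub[pick[i], ]
      idx <- idx + 1
      B2 <- rtrunc_norm(1, sg$b2_mean, sg$b2_sd,
                        bounds$lower[["B2"]] + 1e-6, bounds$upper[["B2"]])
      B3 <- rtrunc_norm(1, sg$b3_mean, sg$b3_sd,
                        bounds$lower[["B3"]], bounds$upper[["B3"]])
      B4 <- rtrunc_norm(1, sg$b4_mean, sg$b4_sd,
                        bounds$lower[["B4"]], bounds$upper[["B4"]])
      y <- evaluate_model(c(B2 = B2, B3 = B3, B4 = B4), 1:5)
      if (noise == "binomial") {
        t_obs <- stats::rbinom(5, max_count,
                               pmin(pmax(y / max_count, 0), 1))
      } else {
        t_obs <- y + stats::rnorm(5, 0, sg$noise_sd)
        if (round_counts) t_obs <- pmin(pmax(round(t_obs), 0), max_count)
        else t_obs <- pmin(pmax(t_obs, 0), max_count)
      }
      rows[[idx]] <- data.frame(
        subject_id = sprintf("S%04d", idx), diagnosis = dg, sex = sx,
        t1 = t_obs[1], t2 = t_obs[2], t3 = t_obs[3], t4 = t_obs[4],
        t5 = t_obs[5], subgroup = sg$subgroup, B2 = B2, B3 = B3, B4 = B4)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lc_cohort", "data.frame")
  out
}

#' Parameter-recovery report for a synthetic cohort
#'
#' Fits every subject's learning curve and compares the estimates with
#' the generating truths retained in the cohort: per-coefficient bias and
#' RMSE over the converged fits, plus the convergence rate.
#'
#' @param cohort an `"lc_cohort"` with truth columns `B2`, `B3`, `B4`.
#' @param max_count list length used in fitting bounds.
#' @return A list with `coefficients` (data frame of bias/RMSE per
#'   coefficient), `n`, `n_converged` and `convergence_rate`.
#' @export
recovery_report <- function(cohort, max_count = 16) {
  if (!all(c("B2", "B3", "B4") %in% names(cohort))) {
    stop("cohort must retain the true parameters (columns B2, B3, B4)",
         call. = FALSE)
  }
  tmat <- as.matrix(cohort[paste0("t", 1:5)])
  fits <- lapply(seq_len(nrow(cohort)), function(i) {
    fit_learning_curve(tmat[i, ], max_count = max_count)
  })
  conv <- vapply(fits, function(f) f$converged, TRUE)
  est <- t(vapply(fits[conv], function(f) f$params, numeric(3)))
  truth <- as.matrix(cohort[conv, c("B2", "B3", "B4")])
  err <- est - truth
  coefs <- data.frame(
    coefficient = c("B2", "B3", "B4"),
    bias = colMeans(err),
    rmse = sqrt(colMeans(err^2))
  )
  rownames(coefs) <- NULL
  list(coefficients = coefs, n = nrow(cohort), n_converged = sum(conv),
       convergence_rate = mean(conv))
}
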