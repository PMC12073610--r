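.rgb_index_names <- c("r", "g", "b", "ExG", "VEG", "VARI")
.target_names <- c("FvFm", "NDVI", "PRI")
.record_vars <- c(.rgb_index_names, "NDVI", "PRI", "FvFm")

#' Per-cell averages of an index-record table
#'
#' Collapses per-ROI records to one averaged value per (species, treatment,
#' day) cell and variable, dropping missing ROIs. These cell means are the
#' unit of all downstream correlation and regression analysis.
#'
#' @param records data frame with columns `species`, `treatment`, `day`,
#'   `roi` and the index variables (`r`, `g`, `b`, `ExG`, `VEG`, `VARI`,
#'   `NDVI`, `PRI`, `FvFm`).
#' @return Data frame with one row per (species, treatment, day) and a mean
#'   column per variable (`NA` when a cell has no non-missing ROI).
#' @export
daily_means <- function(records) {
  vars <- intersect(.record_vars, names(records))
  if (length(vars) == 0) stop("records contain none of the index variables")
  agg <- stats::aggregate(records[vars],
                          by = records[c("species", "treatment", "day")],
                          FUN = function(x) mean(x, na.rm = TRUE))
  agg[vars] <- lapply(agg[vars], nan_to_na)
  agg[order(agg$species, agg$treatment, agg$day), , drop = FALSE]
}

#' Two-sample Student's t-test with significance stars
#'
#' Pooled-variance Student's t-test (Welch's correction available via
#' `var.equal = FALSE`) comparing control against treated samples, as used to
#' flag per-day differences in the stress time courses. Stars follow the
#' usual figure convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' Degenerate input (both samples with zero variance) is guarded: equal means
#' give `t = 0, p = 1`; different means give `p = 0` with the `degenerate`
#' flag set.
#'
#' @param control,treated numeric vectors (each needs >= 2 non-missing
#'   values, else `NA` results).
#' @param var.equal pooled variance (TRUE, the default) or Welch.
#' @return A list with `statistic`, `p.value`, `stars`, `degenerate`.
#' @export
ttest_control_vs_treated <- function(control, treated, var.equal = TRUE) {
  control <- control[!is.na(control)]
  treated <- treated[!is.na(treated)]
  if (length(control) < 2 || length(treated) < 2) {
    return(list(statistic = NA_real_, p.value = NA_real_, stars = "",
                degenerate = FALSE))
  }
  if (stats::var(control) == 0 && stats::var(treated) == 0) {
    if (mean(control) == mean(treated)) {
      return(list(statistic = 0, p.value = 1, stars = "", degenerate = TRUE))
    }
    return(list(statistic = sign(mean(control) - mean(treated)) * Inf,
                p.value = 0, stars = "***", degenerate = TRUE))
  }
  tt <- stats::t.test(control, treated, var.equal = var.equal)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       stars = significance_stars(tt$p.value), degenerate = FALSE)
}

#' @rdname ttest_control_vs_treated
#' @param p p-value(s).
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Pearson correlation on paired averaged values
#'
#' Product-moment correlation with pairwise deletion of missing values;
#' requires at least 3 complete pairs.
#'
#' @param x,y numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`, or `NA` if fewer than 3
#'   complete pairs.
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) return(NA_real_)
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Critical absolute Pearson correlation
#'
#' Two-tailed significance threshold for |R| at level `alpha` and sample size
#' `n`, from the exact t-distribution relation
#' `r_c = t_c / sqrt(t_c^2 + n - 2)` with `t_c` the `1 - alpha/2` quantile of
#' Student's t on `n - 2` degrees of freedom. At `n = 12`, `alpha = 0.05`
#' this is 0.576 (0.58 to two decimals), the cutoff quoted for
#' drought-design correlation tables; at `n = 24` it is 0.404.
#'
#' @param n number of paired observations (>= 3).
#' @param alpha two-tailed significance level.
#' @return The critical |R| in `(0, 1)`.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (n < 3) stop("critical_r requires n >= 3")
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Ordinary least-squares line fit
#'
#' Simple linear regression `y = slope * x + intercept` with its coefficient
#' of determination; for a single regressor `R^2` equals the squared Pearson
#' correlation. Returns a missing model when fewer than 3 complete pairs
#' remain or `x` has zero variance.
#'
#' @param x,y numeric vectors of equal length (pairwise deletion).
#' @return A list with `slope`, `intercept`, `r`, `r2`, `n`, and the
#'   standard errors `se_slope`, `se_intercept` (for confidence intervals).
#' @export
linear_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  empty <- list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r2 = NA_real_, n = n, se_slope = NA_real_,
                se_intercept = NA_real_)
  if (n < 3) return(empty)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) return(empty)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (slope * x + intercept)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) ifelse(ss_res == 0, 1, 0) else 1 - ss_res / ss_tot
  sigma2 <- ss_res / (n - 2)
  list(slope = slope, intercept = intercept,
       r = pearson(x, y), r2 = r2, n = n,
       se_slope = sqrt(sigma2 / sxx),
       se_intercept = sqrt(sigma2 * (1 / n + mean(x)^2 / sxx)))
}

# treatment arms per stress set, as used for the correlation tables
.stress_sets <- list(
  drought = c("control", "drought"),
  salinization = c("control", "nacl100", "nacl200", "nacl400")
)

#' Correlation table of RGB indices against NDVI, PRI and Fv/Fm
#'
#' For each species and stress set (drought: control + drought arms, n = 12
#' cell means over 6 days; salinization: control + three NaCl arms, n = 24),
#' the Pearson correlation of each RGB index with each target over the
#' (treatment, day) cell means, flagged against [critical_r()].
#'
#' @param records per-ROI index records (see [daily_means()]), or an
#'   already-averaged cell-mean table.
#' @param alpha significance level for the critical-|R| flag.
#' @return Data frame with columns `species`, `stress_set`, `index`,
#'   `target`, `r`, `n`, `critical_r`, `significant`.
#' @export
index_correlations <- function(records, alpha = 0.05) {
  means <- if ("roi" %in% names(records)) daily_means(records) else records
  out <- list()
  for (sp in unique(means$species)) {
    for (set_name in names(.stress_sets)) {
      arms <- .stress_sets[[set_name]]
      sub <- means[means$species == sp & means$treatment %in% arms, ,
                   drop = FALSE]
      if (nrow(sub) < 3) next
      for (ix in intersect(.rgb_index_names, names(sub))) {
        for (tg in intersect(.target_names, names(sub))) {
          r <- pearson(sub[[ix]], sub[[tg]])
          n <- sum(!is.na(sub[[ix]]) & !is.na(sub[[tg]]))
          rc <- if (n >= 3) critical_r(n, alpha) else NA_real_
          out[[length(out) + 1]] <- data.frame(
            species = sp, stress_set = set_name, index = ix, target = tg,
            r = r, n = n, critical_r = rc,
            significant = !is.na(r) && !is.na(rc) && abs(r) > rc,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Per-day control-vs-treated t-tests along a stress time course
#'
#' @param records per-ROI index records.
#' @param species,treatment the stressed arm to compare against control.
#' @param variable index column to test.
#' @param var.equal pooled (default) or Welch t-test.
#' @return Data frame with one row per day: `day`, `statistic`, `p.value`,
#'   `stars`, `degenerate`.
#' @export
daily_ttests <- function(records, species, treatment, variable,
                         var.equal = TRUE) {
  sub <- records[records$species == species, , drop = FALSE]
  days <- sort(unique(sub$day))
  rows <- lapply(days, function(d) {
    ctrl <- sub[[variable]][sub$treatment == "control" & sub$day == d]
    trt <- sub[[variable]][sub$treatment == treatment & sub$day == d]
    tt <- ttest_control_vs_treated(ctrl, trt, var.equal = var.equal)
    data.frame(day = d, statistic = tt$statistic, p.value = tt$p.value,
               stars = tt$stars, degenerate = tt$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fit the RGB-index calibration models
#'
#' The core estimator: for each species and each (RGB index, target) pair it
#' fits an ordinary least-squares line to the per-(treatment, day) cell means
#' pooled over all treatment arms, yielding regressions that estimate NDVI,
#' PRI and Fv/Fm from an RGB index alone. With the full emulated design (5
#' treatments x 6 days) each fit uses n = 30 cell means. Models whose R^2
#' falls below `r2_floor` are flagged (kept, not dropped).
#'
#' @param records per-ROI index records (from [process_bundle()] /
#'   [pipeline_process()]) or a cell-mean table from [daily_means()].
#' @param indices RGB indices to use as regressors.
#' @param targets variables to estimate.
#' @param r2_floor flag threshold on R^2 (default 0.7).
#' @param alpha significance level used for the accompanying correlation
#'   table.
#' @return An object of class `"rgb_calibration"`: a list with `models`
#'   (data frame of slope, intercept, r, r2, n, flagged per species x index
#'   x target), `correlations` (from [index_correlations()]), `means` (the
#'   cell means used), `r2_floor` and `call`.
#' @seealso [predict.rgb_calibration()], [plot.rgb_calibration()]
#' @export
rgb_calibration <- function(records, indices = .rgb_index_names,
                            targets = .target_names, r2_floor = 0.7,
                            alpha = 0.05) {
  means <- if ("roi" %in% names(records)) daily_means(records) else records
  indices <- intersect(indices, names(means))
  targets <- intersect(targets, names(means))
  if (length(indices) == 0 || length(targets) == 0) {
    stop("records lack the requested index/target columns")
  }
  rows <- list()
  for (sp in unique(means$species)) {
    sub <- means[means$species == sp, , drop = FALSE]
    for (ix in indices) {
      for (tg in targets) {
        fit <- linear_fit(sub[[ix]], sub[[tg]])
        rows[[length(rows) + 1]] <- data.frame(
          species = sp, index = ix, target = tg,
          slope = fit$slope, intercept = fit$intercept,
          r = fit$r, r2 = fit$r2, n = fit$n,
          se_slope = fit$se_slope, se_intercept = fit$se_intercept,
          flagged = is.na(fit$r2) || fit$r2 < r2_floor,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(models = do.call(rbind, rows),
                 correlations = index_correlations(means, alpha = alpha),
                 means = means, r2_floor = r2_floor,
                 call = match.call()),
            class = "rgb_calibration")
}

#' @export
print.rgb_calibration <- function(x, ...) {
  m <- x$models
  cat("RGB-index calibration:", nrow(m), "linear models (",
      paste(unique(m$species), collapse = ", "), ")\n")
  cat(sprintf("R^2 floor %.2f: %d model(s) flagged\n",
              x$r2_floor, sum(m$flagged)))
  best <- m[order(-m$r2), c("species", "index", "target", "slope",
                            "intercept", "r2", "n")]
  cat("Top models by R^2:\n")
  print(utils::head(best, 6), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.rgb_calibration <- function(object, ...) {
  structure(list(models = object$models,
                 correlations = object$correlations,
                 r2_floor = object$r2_floor),
            class = "summary.rgb_calibration")
}

#' @export
print.summary.rgb_calibration <- function(x, ...) {
  cat("Calibration models:\n")
  print(x$models[c("species", "index", "target", "slope", "intercept",
                   "r2", "n", "flagged")], row.names = FALSE, digits = 4)
  cat("\nCorrelations (|R| vs critical value, ",
      "stars by two-tailed significance):\n", sep = "")
  ct <- x$correlations
  ct$stars <- ifelse(ct$significant, "*", "")
  print(ct, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.rgb_calibration <- function(object, ...) {
  object$models[c("species", "index", "target", "slope", "intercept")]
}

#' Predict NDVI, PRI or Fv/Fm from RGB-index values
#'
#' Applies the fitted per-species lines: `target = slope * index + intercept`.
#'
#' @param object an [rgb_calibration()] fit.
#' @param newdata data frame with columns `species` and the chosen index.
#' @param index which RGB index column of `newdata` to use (default `"ExG"`).
#' @param targets targets to predict (default all fitted).
#' @param ... unused.
#' @return `newdata` with one added column per predicted target, named
#'   `pred_<target>`.
#' @export
predict.rgb_calibration <- function(object, newdata, index = "ExG",
                                    targets = NULL, ...) {
  m <- object$models[object$models$index == index, , drop = FALSE]
  if (nrow(m) == 0) {
    stop("no calibration model for index '", index,
         "'; fitted indices: ",
         paste(unique(object$models$index), collapse = ", "))
  }
  if (is.null(targets)) targets <- unique(m$target)
  if (!index %in% names(newdata)) {
    stop("newdata lacks the index column '", index, "'")
  }
  if (!"species" %in% names(newdata)) stop("newdata lacks a species column")
  out <- newdata
  for (tg in targets) {
    mt <- m[m$target == tg, , drop = FALSE]
    if (nrow(mt) == 0) stop("no calibration model for target '", tg, "'")
    key <- match(newdata$species, mt$species)
    if (anyNA(key)) {
      stop("no calibration model for species: ",
           paste(unique(newdata$species[is.na(key)]), collapse = ", "))
    }
    out[[paste0("pred_", tg)]] <-
      mt$slope[key] * newdata[[index]] + mt$intercept[key]
  }
  out
}

#' Scatter plot of a calibration model
#'
#' Cell means of the chosen target against the chosen RGB index, with the
#' fitted line, one panel per species.
#'
#' @param x an [rgb_calibration()] fit.
#' @param index,target which model to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rgb_calibration <- function(x, index = "ExG", target = "NDVI", ...) {
  means <- x$means
  species <- unique(means$species)
  old <- graphics::par(mfrow = c(1, length(species)))
  on.exit(graphics::par(old))
  for (sp in species) {
    sub <- means[means$species == sp, , drop = FALSE]
    m <- x$models[x$models$species == sp & x$models$index == index &
                    x$models$target == target, , drop = FALSE]
    graphics::plot(sub[[index]], sub[[target]], xlab = index, ylab = target,
                   main = sprintf("%s: R2 = %.3f", sp, m$r2), ...)
    if (nrow(m) == 1 && !is.na(m$slope)) {
      graphics::abline(a = m$intercept, b = m$slope, col = "forestgreen")
    }
  }
  invisible(x)
}

#' Simulate cell means with a known affine index-target relation
#'
#' Generates `n` ExG-like cell means and a target variable that is a known
#' affine function of them plus Gaussian noise -- the standard parameter-
#' recovery check for [linear_fit()] / [rgb_calibration()].
#'
#' @param n number of cell means (default 30, a full 5-treatment x 6-day
#'   design).
#' @param slope,intercept true line.
#' @param sigma Gaussian noise sd on the target (default 0.02).
#' @param x_range range of the simulated index means.
#' @return Data frame with columns `x` and `y`.
#' @export
simulate_affine_calibration <- function(n = 30, slope = 0.78,
                                        intercept = 0.12, sigma = 0.02,
                                        x_range = c(0.2, 0.9)) {
  x <- stats::runif(n, x_range[1], x_range[2])
  data.frame(x = x, y = slope * x + intercept + stats::rnorm(n, 0, sigma))
}
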