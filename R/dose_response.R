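# Dose-response fitting: replicate pooling, constrained 3-/4-parameter
# log-logistic least squares with AICc model selection, smoothing-spline
# fallback, and trapezoid AUC over log10 concentration.

# Constraint boxes shared by both sigmoid models.
.HILL_BOUNDS <- c(-10, 0)
.LOG10_EC50_BOUNDS <- c(-11, -4)
.AUC_LO <- 1e-11
.AUC_HI <- 1e-4

#' Pool replicate measurements for one drug and cell line
#'
#' Replicate (concentration, activity) points are concatenated, never
#' averaged; fitting sees every pooled point. The result is sorted by
#' concentration then activity so that it does not depend on replicate file
#' order.
#'
#' @param ... data.frames each holding columns `concentration_M` and
#'   `activity_pct` (a single list of data.frames is also accepted).
#' @return a pooled `data.frame` with columns `concentration_M`,
#'   `activity_pct`.
#' @export
pool_replicates <- function(...) {
  reps <- list(...)
  if (length(reps) == 1 && is.list(reps[[1]]) && !is.data.frame(reps[[1]])) {
    reps <- reps[[1]]
  }
  if (length(reps) == 0) stopf("no replicate data supplied")
  reps <- lapply(reps, function(df) {
    if (!all(c("concentration_M", "activity_pct") %in% names(df))) {
      stopf("replicates need columns concentration_M and activity_pct")
    }
    df[, c("concentration_M", "activity_pct")]
  })
  pooled <- do.call(rbind, reps)
  pooled <- pooled[order(pooled$concentration_M, pooled$activity_pct), ]
  rownames(pooled) <- NULL
  pooled
}

#' Median activity at each tested concentration
#'
#' Medians over all pooled points at each distinct concentration (midpoint
#' convention for even counts). Their minimum and maximum bound the baseline
#' and plateau parameters during fitting.
#'
#' @param concentration molar concentrations (> 0), replicate points repeated.
#' @param activity matching % activity values.
#' @return list with `concentration` (ascending distinct values), `median`,
#'   `min_median`, `max_median`.
#' @export
concentration_medians <- function(concentration, activity) {
  if (length(concentration) == 0) stopf("empty dataset")
  if (length(concentration) != length(activity)) {
    stopf("concentration and activity must have equal length")
  }
  conc <- sort(unique(concentration))
  med <- vapply(conc, function(cc) {
    stats::median(activity[concentration == cc])
  }, numeric(1))
  list(concentration = conc, median = med,
       min_median = min(med), max_median = max(med))
}

#' Log-logistic dose-response curve
#'
#' `f(x) = y0 + (yFin - y0) / (1 + exp(hill * (ln x - ln ec50)))`. With
#' `hill <= 0` and `yFin >= y0` the curve rises from the zero-dose baseline
#' `y0` to the plateau `yFin`, crossing their midpoint at `ec50`.
#'
#' @param x concentrations (M).
#' @param y0 baseline response (%) at zero dose.
#' @param yFin maximal response (%).
#' @param hill slope (<= 0 for rising activity curves).
#' @param ec50 midpoint concentration (M).
#' @return curve values (%).
#' @export
sigmoid_curve <- function(x, y0, yFin, hill, ec50) {
  e <- exp(hill * (log(x) - log(ec50)))
  y <- y0 + (yFin - y0) / (1 + e)
  # exp() overflow at tiny x with steep slopes: the curve is at baseline there
  y[is.infinite(e)] <- y0
  y
}

#' Corrected Akaike information criterion for least squares
#'
#' Gaussian least-squares form with the error variance profiled out:
#' `AICc = n * ln(rss / n) + 2k + 2k(k + 1) / (n - k - 1)`.
#'
#' @param n number of points.
#' @param k number of model parameters.
#' @param rss residual sum of squares (> 0).
#' @return the AICc value.
#' @export
aicc <- function(n, k, rss) {
  if (n <= k + 1) stopf("AICc undefined: need n > k + 1 (n=%d, k=%d)", n, k)
  if (!is.finite(rss) || rss <= 0) stopf("rss must be a positive number")
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# Parameter boxes for one model given the concentration medians.
# three_param: y0 fixed at 0, yFin in [0, max_median];
# four_param:  y0 and yFin both in [min_median, max_median].
# Degenerate boxes (equal medians, or a non-positive max for the
# three-parameter plateau) are widened by a hair so the optimizer has room.
.sigmoid_box <- function(model, medians) {
  eps <- 1e-6
  if (model == "three_param") {
    up <- max(0, medians$max_median)
    list(lower = c(yFin = 0, hill = .HILL_BOUNDS[1],
                   l10ec50 = .LOG10_EC50_BOUNDS[1]),
         upper = c(yFin = max(up, eps), hill = .HILL_BOUNDS[2],
                   l10ec50 = .LOG10_EC50_BOUNDS[2]))
  } else {
    lo <- medians$min_median
    up <- medians$max_median
    if (up - lo < eps) up <- lo + eps
    list(lower = c(y0 = lo, yFin = lo, hill = .HILL_BOUNDS[1],
                   l10ec50 = .LOG10_EC50_BOUNDS[1]),
         upper = c(y0 = up, yFin = up, hill = .HILL_BOUNDS[2],
                   l10ec50 = .LOG10_EC50_BOUNDS[2]))
  }
}

#' Fit a constrained log-logistic dose-response model
#'
#' Bounded least squares of % activity against concentration for either the
#' three-parameter model (baseline `y0` fixed at zero) or the four-parameter
#' model (`y0` free). Constraints: hill slope in \[-10, 0\]; EC50 in
#' \[1e-11, 1e-4\] M; the three-parameter plateau `yFin` in \[0, max of the
#' per-concentration median activities\]; the four-parameter `y0` and `yFin`
#' both between the minimum and maximum of those medians.
#'
#' Optimization uses deterministic multi-starts (hill in -0.5/-2/-8 crossed
#' with EC50 at the 25th/50th/75th percentiles of tested concentrations) with
#' `optim(method = "L-BFGS-B")`; the best converged start is kept.
#'
#' @param concentration molar concentrations (> 0), pooled replicates.
#' @param activity matching % activity values.
#' @param model `"three_param"` or `"four_param"`.
#' @param medians optional precomputed [concentration_medians()] result.
#' @return an object of class `sigmoid_fit`: fields `model`, `y0`, `yFin`,
#'   `hill`, `ec50`, `rss`, `n`, `k`, `aicc`, `converged`.
#' @export
fit_sigmoid <- function(concentration, activity,
                        model = c("four_param", "three_param"),
                        medians = NULL) {
  model <- match.arg(model)
  if (any(concentration <= 0)) stopf("all concentrations must be > 0")
  n <- length(activity)
  k <- if (model == "three_param") 3L else 4L
  n_distinct <- length(unique(concentration))
  if (n_distinct < 2) stopf("need >= 2 distinct concentrations to fit")
  if (n < k + 2) stopf("need >= %d points for the %s model", k + 2, model)

  medians <- medians %||% concentration_medians(concentration, activity)
  box <- .sigmoid_box(model, medians)
  lx <- log(concentration)

  obj <- if (model == "three_param") {
    function(p) {
      r <- activity - sigmoid_curve(concentration, 0, p[1], p[2], 10^p[3])
      sum(r * r)
    }
  } else {
    function(p) {
      r <- activity - sigmoid_curve(concentration, p[1], p[2], p[3], 10^p[4])
      sum(r * r)
    }
  }

  hill_starts <- clamp(c(-0.5, -2, -8), .HILL_BOUNDS[1], .HILL_BOUNDS[2])
  ec_starts <- clamp(log10(stats::quantile(concentration,
                                           c(0.25, 0.5, 0.75),
                                           names = FALSE)),
                     .LOG10_EC50_BOUNDS[1], .LOG10_EC50_BOUNDS[2])
  yfin0 <- clamp(medians$max_median,
                 box$lower[["yFin"]], box$upper[["yFin"]])
  y00 <- if (model == "four_param") {
    clamp(medians$median[1], box$lower[["y0"]], box$upper[["y0"]])
  }

  # Best converged start wins; a non-converged minimum is only reported
  # (flagged) when no start converged at all.
  best <- NULL
  for (h0 in hill_starts) {
    for (e0 in ec_starts) {
      p0 <- if (model == "three_param") c(yfin0, h0, e0) else
        c(y00, yfin0, h0, e0)
      res <- tryCatch(
        stats::optim(p0, obj, method = "L-BFGS-B",
                     lower = box$lower, upper = box$upper,
                     control = list(maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(res) || !is.finite(res$value)) next
      res$ok <- res$convergence == 0
      if (is.null(best) ||
          (res$ok > best$ok) ||
          (res$ok == best$ok && res$value < best$value)) {
        best <- res
      }
    }
  }

  if (is.null(best)) {
    return(structure(list(model = model, y0 = NA_real_, yFin = NA_real_,
                          hill = NA_real_, ec50 = NA_real_, rss = NA_real_,
                          n = n, k = k, aicc = NA_real_, converged = FALSE),
                     class = "sigmoid_fit"))
  }

  p <- best$par
  if (model == "three_param") {
    y0 <- 0; yFin <- p[1]; hill <- p[2]; ec50 <- 10^p[3]
  } else {
    y0 <- p[1]; yFin <- p[2]; hill <- p[3]; ec50 <- 10^p[4]
  }
  rss <- best$value
  structure(
    list(model = model, y0 = y0, yFin = yFin, hill = hill, ec50 = ec50,
         rss = rss, n = n, k = k,
         aicc = if (rss > 0) aicc(n, k, rss) else -Inf,
         converged = isTRUE(best$ok)),
    class = "sigmoid_fit"
  )
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "%s log-logistic fit (%s): y0=%.2f yFin=%.2f hill=%.3f ec50=%.3g M rss=%.4g AICc=%.3f\n",
    x$model, if (x$converged) "converged" else "NOT converged",
    x$y0, x$yFin, x$hill, x$ec50, x$rss, x$aicc))
  invisible(x)
}

#' Select between the three- and four-parameter fits
#'
#' Keeps the converged fit with the lowest AICc. If only one fit converged,
#' that one is returned; near ties (|difference| < 1e-9) go to the model with
#' fewer parameters. Returns `NULL` when neither fit converged, signalling
#' the spline fallback.
#'
#' @param fit3,fit4 `sigmoid_fit` objects (either may be `NULL` when not
#'   attempted).
#' @return the selected `sigmoid_fit`, or `NULL`.
#' @export
select_model <- function(fit3, fit4) {
  ok3 <- !is.null(fit3) && isTRUE(fit3$converged)
  ok4 <- !is.null(fit4) && isTRUE(fit4$converged)
  if (!ok3 && !ok4) return(NULL)
  if (ok3 && !ok4) return(fit3)
  if (ok4 && !ok3) return(fit4)
  if (fit4$aicc < fit3$aicc - 1e-9) fit4 else fit3
}

#' Smoothing-spline fallback curve
#'
#' When no sigmoid fit is acceptable, a cross-validated cubic smoothing
#' spline of % activity against log10 concentration supplies the curve used
#' for AUC. Outside the observed concentration range the curve is evaluated
#' flat (constant extrapolation), so the AUC integration window is always
#' covered. Requires >= 4 distinct concentrations.
#'
#' @param concentration molar concentrations (> 0).
#' @param activity matching % activity values.
#' @return an object of class `dr_spline` wrapping the `smooth.spline` fit
#'   and the observed log10-concentration range.
#' @export
fit_spline_fallback <- function(concentration, activity) {
  if (any(concentration <= 0)) stopf("all concentrations must be > 0")
  u <- log10(concentration)
  if (length(unique(u)) < 4) {
    stopf("spline fallback needs >= 4 distinct concentrations")
  }
  ss <- stats::smooth.spline(u, activity)
  fitted <- stats::predict(ss, u)$y
  structure(
    list(spline = ss, u_range = range(u),
         rss = sum((activity - fitted)^2), n = length(activity)),
    class = "dr_spline"
  )
}

#' Evaluate a fitted dose-response curve
#'
#' @param fit a `sigmoid_fit` or `dr_spline`.
#' @param concentration molar concentrations at which to evaluate.
#' @return curve values (% activity).
#' @export
predict_curve <- function(fit, concentration) UseMethod("predict_curve")

#' @export
predict_curve.sigmoid_fit <- function(fit, concentration) {
  sigmoid_curve(concentration, fit$y0, fit$yFin, fit$hill, fit$ec50)
}

#' @export
predict_curve.dr_spline <- function(fit, concentration) {
  u <- clamp(log10(concentration), fit$u_range[1], fit$u_range[2])
  stats::predict(fit$spline, u)$y
}

#' Trapezoid area under the dose-response curve
#'
#' Integrates the fitted curve over log10 concentration on a uniform grid
#' (default 701 points, 100 per decade) between 1e-11 and 1e-4 M. Units are
#' %-activity x log10(M) decades; a curve pinned at 100% across the 7-decade
#' window scores 700. Higher AUC means more activity.
#'
#' @param fit a `sigmoid_fit` or `dr_spline`.
#' @param lo,hi integration bounds in molar.
#' @param n_grid number of grid points.
#' @return the AUC (numeric scalar).
#' @export
compute_auc <- function(fit, lo = .AUC_LO, hi = .AUC_HI, n_grid = 701) {
  if (lo >= hi) stopf("need lo < hi for AUC bounds")
  u <- seq(log10(lo), log10(hi), length.out = n_grid)
  y <- predict_curve(fit, 10^u)
  du <- u[2] - u[1]
  sum((y[-1] + y[-n_grid]) / 2) * du
}

#' EC50 of a fitted sigmoid
#'
#' Returns the fitted midpoint concentration: the dose at which the curve is
#' halfway between `y0` and `yFin`. This inflection EC50 is reported even
#' when the plateau stays below 50% absolute activity. Spline fits and
#' non-converged fits have no EC50 (`NA`).
#'
#' @param fit a `sigmoid_fit` (or `dr_spline`, yielding `NA`).
#' @return EC50 in molar, or `NA`.
#' @export
ec50_from_fit <- function(fit) {
  if (inherits(fit, "dr_spline")) return(NA_real_)
  if (!isTRUE(fit$converged)) return(NA_real_)
  fit$ec50
}

#' Fit one dose-response curve with model selection and fallback
#'
#' Full single-curve pipeline: fit the three- and four-parameter constrained
#' log-logistic models, select by AICc, and fall back to the smoothing
#' spline when neither sigmoid converges or when the selected sigmoid fits
#' far worse than the spline (residual sum of squares more than
#' `spline_guard` times the spline's, with root-mean-square error above 2%
#' so that near-perfect fits are never displaced). AUC is computed from the
#' accepted curve over `[auc_lo, auc_hi]`.
#'
#' @param concentration molar concentrations (> 0), pooled replicates.
#' @param activity matching % activity values.
#' @param compound_id,cell_line identifiers carried into the summary.
#' @param auc_lo,auc_hi AUC integration bounds (M).
#' @param spline_guard rss ratio above which a sigmoid fit is deemed
#'   pathological and the spline takes over.
#' @return an object of class `curve_summary`: `compound_id`, `cell_line`,
#'   `fit_kind` (`"sigmoid"`, `"spline"` or `"unfit"`), `fit` (the curve
#'   object), `model`, parameters, `ec50`, `auc`, `rss`, `aicc`, `converged`.
#' @export
fit_dose_response <- function(concentration, activity,
                              compound_id = NA_character_,
                              cell_line = NA_character_,
                              auc_lo = .AUC_LO, auc_hi = .AUC_HI,
                              spline_guard = 10) {
  medians <- concentration_medians(concentration, activity)
  n <- length(activity)

  fit3 <- if (n >= 5) {
    tryCatch(fit_sigmoid(concentration, activity, "three_param", medians),
             error = function(e) NULL)
  }
  fit4 <- if (n >= 6) {
    tryCatch(fit_sigmoid(concentration, activity, "four_param", medians),
             error = function(e) NULL)
  }
  sel <- select_model(fit3, fit4)

  spl <- tryCatch(fit_spline_fallback(concentration, activity),
                  error = function(e) NULL)

  use_spline <- is.null(sel) ||
    (!is.null(spl) && sel$rss > spline_guard * spl$rss &&
       sqrt(sel$rss / sel$n) > 2)

  if (!use_spline) {
    out <- list(compound_id = compound_id, cell_line = cell_line,
                fit_kind = "sigmoid", fit = sel, model = sel$model,
                y0 = sel$y0, yFin = sel$yFin, hill = sel$hill,
                ec50 = ec50_from_fit(sel),
                auc = compute_auc(sel, auc_lo, auc_hi),
                rss = sel$rss, aicc = sel$aicc, converged = TRUE)
  } else if (!is.null(spl)) {
    out <- list(compound_id = compound_id, cell_line = cell_line,
                fit_kind = "spline", fit = spl, model = NA_character_,
                y0 = NA_real_, yFin = NA_real_, hill = NA_real_,
                ec50 = NA_real_,
                auc = compute_auc(spl, auc_lo, auc_hi),
                rss = spl$rss, aicc = NA_real_, converged = TRUE)
  } else {
    out <- list(compound_id = compound_id, cell_line = cell_line,
                fit_kind = "unfit", fit = NULL, model = NA_character_,
                y0 = NA_real_, yFin = NA_real_, hill = NA_real_,
                ec50 = NA_real_, auc = NA_real_, rss = NA_real_,
                aicc = NA_real_, converged = FALSE)
  }
  structure(out, class = "curve_summary")
}

#' @export
print.curve_summary <- function(x, ...) {
  cat(sprintf("Curve %s x %s [%s]: AUC=%.1f EC50=%.3g M\n",
              x$compound_id, x$cell_line, x$fit_kind, x$auc, x$ec50))
  invisible(x)
}

#' Fit every drug x cell-line curve in an activity table
#'
#' Pools replicate rows per (compound, cell line), fits each curve with
#' [fit_dose_response()], and returns one summary row per pair.
#'
#' @param activities `data.frame` with columns `compound_id`, `cell_line`,
#'   `concentration_M`, `activity_pct` (replicate rows repeated).
#' @param ... passed to [fit_dose_response()].
#' @return a `data.frame` with columns `compound_id, cell_line, fit_kind,
#'   model, y0, yFin, hill, ec50_M, rss, aicc, auc, converged`.
#' @export
fit_screen <- function(activities, ...) {
  need <- c("compound_id", "cell_line", "concentration_M", "activity_pct")
  if (!all(need %in% names(activities))) {
    stopf("activities need columns: %s", paste(need, collapse = ", "))
  }
  groups <- split(activities,
                  list(activities$compound_id, activities$cell_line),
                  drop = TRUE, sep = "\r")
  rows <- lapply(groups, function(df) {
    pooled <- pool_replicates(df)
    cs <- fit_dose_response(pooled$concentration_M, pooled$activity_pct,
                            compound_id = df$compound_id[1],
                            cell_line = df$cell_line[1], ...)
    data.frame(compound_id = cs$compound_id, cell_line = cs$cell_line,
               fit_kind = cs$fit_kind, model = cs$model, y0 = cs$y0,
               yFin = cs$yFin, hill = cs$hill, ec50_M = cs$ec50,
               rss = cs$rss, aicc = cs$aicc, auc = cs$auc,
               converged = cs$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_id, out$cell_line), ]
  rownames(out) <- NULL
  out
}
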