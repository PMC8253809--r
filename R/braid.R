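# Two-drug response surfaces: a kappa-parameterized combined-dose model with
# Loewe-additive null (kappa = 0), surface fitting, interaction
# classification, isoboles, and the index of achievable efficacy (IAE).

#' Construct response-surface parameters
#'
#' The surface combines two Hill-type single agents through a combined dose.
#' With `sigma = sqrt(n_a * n_b)`,
#' `D_A = (dose_a / ec50_a)^(n_a / sigma)`,
#' `D_B = (dose_b / ec50_b)^(n_b / sigma)` and
#' `D = D_A + D_B + kappa * sqrt(D_A * D_B)`, the effect is
#' `E0 + (Ef - E0) * D^sigma / (1 + D^sigma)`. `kappa` indexes the
#' interaction: negative is antagonistic, zero reduces to Loewe additivity
#' (for equal slopes), positive is synergistic. `kappa` must exceed -2, the
#' algebraic limit below which the combined dose can turn negative.
#'
#' @param E0 effect at zero dose (%).
#' @param Ef maximal joint effect (%), > `E0`.
#' @param ec50_a,ec50_b single-agent midpoints (M), > 0.
#' @param n_a,n_b single-agent Hill slopes, > 0.
#' @param kappa interaction parameter in (-2, 100].
#' @return an object of class `braid_params`.
#' @export
braid_params <- function(E0, Ef, ec50_a, ec50_b, n_a, n_b, kappa) {
  if (!is.finite(kappa) || kappa <= -2 || kappa > 100) {
    stopf("kappa must lie in (-2, 100]")
  }
  if (Ef <= E0) stopf("Ef must exceed E0")
  if (ec50_a <= 0 || ec50_b <= 0) stopf("EC50s must be positive")
  if (n_a <= 0 || n_b <= 0) stopf("Hill slopes must be positive")
  structure(list(E0 = E0, Ef = Ef, ec50_a = ec50_a, ec50_b = ec50_b,
                 n_a = n_a, n_b = n_b, kappa = kappa),
            class = "braid_params")
}

#' @export
print.braid_params <- function(x, ...) {
  cat(sprintf(
    "Response surface: E0=%.1f Ef=%.1f EC50A=%.3g EC50B=%.3g nA=%.2f nB=%.2f kappa=%.2f\n",
    x$E0, x$Ef, x$ec50_a, x$ec50_b, x$n_a, x$n_b, x$kappa))
  invisible(x)
}

#' Evaluate the combination response surface
#'
#' Vectorized over dose pairs (recycled). At `dose_b = 0` the surface reduces
#' exactly to drug A's single-agent Hill curve (slope `n_a`, midpoint
#' `ec50_a`), and symmetrically for drug B.
#'
#' @param params `braid_params`.
#' @param dose_a,dose_b doses in molar (>= 0).
#' @return effect values (%), bounded in `[E0, Ef)`.
#' @export
braid_effect <- function(params, dose_a, dose_b) {
  stopifnot(inherits(params, "braid_params"))
  if (any(dose_a < 0) || any(dose_b < 0)) stopf("doses must be >= 0")
  sigma <- sqrt(params$n_a * params$n_b)
  DA <- (dose_a / params$ec50_a)^(params$n_a / sigma)
  DB <- (dose_b / params$ec50_b)^(params$n_b / sigma)
  D <- pmax(DA + DB + params$kappa * sqrt(DA * DB), 0)
  Ds <- D^sigma
  frac <- ifelse(is.infinite(Ds), 1, Ds / (1 + Ds))
  params$E0 + (params$Ef - params$E0) * frac
}

# Single-agent Hill fit used to initialize the surface fit: the rising Hill
# curve is the log-logistic model with slope -n, so the constrained
# dose-response fitter is reused on the nonzero-dose edge points.
.edge_hill_init <- function(dose, effect) {
  keep <- dose > 0
  fit <- tryCatch(
    fit_sigmoid(dose[keep], effect[keep], "four_param"),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged) {
    return(list(ec50 = stats::median(dose[keep]), n = 1,
                E0 = min(effect), Ef = max(effect)))
  }
  list(ec50 = fit$ec50, n = max(0.25, -fit$hill), E0 = fit$y0, Ef = fit$yFin)
}

#' Fit the response surface to a combination grid
#'
#' Bounded least squares over (E0, Ef, EC50A, EC50B, nA, nB, kappa) on %
#' activity from a two-drug dose grid normalized on the linear scale. The
#' grid must contain both single-agent edges (rows with one zero dose) and at
#' least 9 interior cells. Starts are built from independent Hill fits to the
#' two edges crossed with kappa in {-1, 0, 2}; the best converged start wins.
#'
#' @param grid `data.frame` with columns `dose_a_M`, `dose_b_M`,
#'   `activity_pct` (replicate rows repeated).
#' @param kappa_starts initial kappa values for the multi-start.
#' @return an object of class `braid_fit`: `params` (`braid_params`), `rss`,
#'   `n_cells`, `converged`.
#' @export
fit_braid <- function(grid, kappa_starts = c(-1, 0, 2)) {
  need <- c("dose_a_M", "dose_b_M", "activity_pct")
  if (!all(need %in% names(grid))) {
    stopf("grid needs columns: %s", paste(need, collapse = ", "))
  }
  a <- grid$dose_a_M; b <- grid$dose_b_M; y <- grid$activity_pct
  edge_a <- a > 0 & b == 0
  edge_b <- b > 0 & a == 0
  interior <- a > 0 & b > 0
  if (!any(edge_a) || !any(edge_b)) {
    stopf("grid must include both single-agent edges (zero-dose rows)")
  }
  if (length(unique(paste(a[interior], b[interior]))) < 9) {
    stopf("grid needs >= 9 interior dose combinations")
  }

  ia <- .edge_hill_init(a[edge_a], y[edge_a])
  ib <- .edge_hill_init(b[edge_b], y[edge_b])
  E0_0 <- if (any(a == 0 & b == 0)) mean(y[a == 0 & b == 0]) else
    min(ia$E0, ib$E0)
  Ef_0 <- max(ia$Ef, ib$Ef, y[interior])

  # Parameters: (E0, dE = Ef - E0, log10 ec50_a, log10 ec50_b,
  #              log n_a, log n_b, kappa); dE > 0 keeps Ef above E0.
  l10a <- range(log10(a[a > 0])); l10b <- range(log10(b[b > 0]))
  lower <- c(-50, 5, l10a[1] - 3, l10b[1] - 3, log(0.2), log(0.2), -1.99)
  upper <- c(50, 250, l10a[2] + 3, l10b[2] + 3, log(10), log(10), 100)

  obj <- function(p) {
    pr <- list(E0 = p[1], Ef = p[1] + p[2],
               ec50_a = 10^p[3], ec50_b = 10^p[4],
               n_a = exp(p[5]), n_b = exp(p[6]), kappa = p[7])
    class(pr) <- "braid_params"
    r <- y - braid_effect(pr, a, b)
    sum(r * r)
  }

  p0_base <- c(clamp(E0_0, lower[1], upper[1]),
               clamp(Ef_0 - E0_0, lower[2], upper[2]),
               clamp(log10(ia$ec50), lower[3], upper[3]),
               clamp(log10(ib$ec50), lower[4], upper[4]),
               clamp(log(ia$n), lower[5], upper[5]),
               clamp(log(ib$n), lower[6], upper[6]),
               0)
  best <- NULL
  for (k0 in kappa_starts) {
    p0 <- p0_base
    p0[7] <- clamp(k0, lower[7], upper[7])
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 1000)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    res$ok <- res$convergence == 0
    if (is.null(best) || (res$ok > best$ok) ||
        (res$ok == best$ok && res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    return(structure(list(params = NULL, rss = NA_real_,
                          n_cells = length(y), converged = FALSE),
                     class = "braid_fit"))
  }
  p <- best$par
  structure(
    list(params = braid_params(p[1], p[1] + p[2], 10^p[3], 10^p[4],
                               exp(p[5]), exp(p[6]), p[7]),
         rss = best$value, n_cells = length(y),
         converged = isTRUE(best$ok)),
    class = "braid_fit"
  )
}

#' @export
print.braid_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Response-surface fit: NOT converged\n")
  } else {
    print(x$params)
    cat(sprintf("  rss=%.4g over %d measurements; interaction: %s\n",
                x$rss, x$n_cells, classify_interaction(x)))
  }
  invisible(x)
}

#' Classify the drug interaction from a fitted surface
#'
#' Sign of the fitted kappa with a small dead zone: synergistic when
#' `kappa > tol`, antagonistic when `kappa < -tol`, additive otherwise.
#'
#' @param fit `braid_fit` (must have converged).
#' @param tol half-width of the additive band (default 0.1).
#' @return one of `"antagonistic"`, `"additive"`, `"synergistic"`.
#' @export
classify_interaction <- function(fit, tol = 0.1) {
  if (!isTRUE(fit$converged)) stopf("cannot classify a non-converged fit")
  k <- fit$params$kappa
  if (k > tol) "synergistic" else if (k < -tol) "antagonistic" else "additive"
}

#' Iso-effect contour (isobole) of a response surface
#'
#' Traces the dose pairs producing a fixed effect level. For effect level e
#' with p = (e - E0)/(Ef - E0), the combined dose on the contour is
#' `D* = (p/(1-p))^(1/sigma)`; drug A's share is swept from 0 to D* and drug
#' B's share solved from the quadratic in `sqrt(D_B)`. For `kappa = 0` and
#' equal slopes the contour is the straight Loewe additivity line between the
#' single-agent iso-effective doses.
#'
#' @param params `braid_params`.
#' @param effect_level target effect (%), strictly between `E0` and `Ef`.
#' @param n_points number of polyline vertices.
#' @return `data.frame` with columns `dose_a_M`, `dose_b_M`, `effect_pct`.
#'   Unattainable levels give an empty contour (0 rows).
#' @export
isobole <- function(params, effect_level, n_points = 101) {
  stopifnot(inherits(params, "braid_params"))
  if (effect_level <= params$E0 || effect_level >= params$Ef) {
    return(data.frame(dose_a_M = numeric(0), dose_b_M = numeric(0),
                      effect_pct = numeric(0)))
  }
  sigma <- sqrt(params$n_a * params$n_b)
  p <- (effect_level - params$E0) / (params$Ef - params$E0)
  Dstar <- (p / (1 - p))^(1 / sigma)
  DA <- Dstar * seq(0, 1, length.out = n_points)
  disc <- params$kappa^2 * DA + 4 * (Dstar - DA)
  sB <- (-params$kappa * sqrt(DA) + sqrt(pmax(disc, 0))) / 2
  DB <- pmax(sB, 0)^2
  data.frame(
    dose_a_M = params$ec50_a * DA^(sigma / params$n_a),
    dose_b_M = params$ec50_b * DB^(sigma / params$n_b),
    effect_pct = effect_level
  )
}

#' Index of achievable efficacy (IAE)
#'
#' Measures how much of a capped dose window reaches a minimal efficacy
#' threshold (by default a 50% effect at concentrations <= 1 uM). The surface
#' is evaluated on a log10-uniform grid spanning four decades below `cmax` in
#' each drug; with achieving fraction f (cells at or above threshold),
#' `IAE = sqrt(1 / (1 - f))`, capped at 1000 when every cell achieves the
#' threshold. A combination that never reaches the threshold scores exactly
#' 1; higher IAE means a more efficacious combination.
#'
#' @param params `braid_params`.
#' @param threshold effect threshold (%), default 50.
#' @param cmax concentration cap (M), default 1e-6.
#' @param n_grid grid points per axis (default 201).
#' @return list with `threshold_effect`, `cmax`, `iae`, `achieving_fraction`.
#' @export
compute_iae <- function(params, threshold = 50, cmax = 1e-6, n_grid = 201) {
  stopifnot(inherits(params, "braid_params"))
  u <- 10^seq(log10(cmax * 1e-4), log10(cmax), length.out = n_grid)
  eff <- outer(u, u, function(da, db) braid_effect(params, da, db))
  f <- mean(eff >= threshold)
  iae <- if (f >= 1) 1e3 else min(sqrt(1 / (1 - f)), 1e3)
  list(threshold_effect = threshold, cmax = cmax, iae = iae,
       achieving_fraction = f)
}

#' Full synergy analysis of one combination grid
#'
#' Fits the response surface, classifies the interaction, computes the IAE
#' and traces reference isoboles.
#'
#' @param grid combination grid `data.frame` (see [fit_braid()]).
#' @param threshold IAE effect threshold (%).
#' @param cmax IAE concentration cap (M).
#' @param isobole_levels effect levels (%) for reference contours.
#' @return list with `fit`, `interaction`, `iae`, `isoboles` (named list of
#'   contours).
#' @export
analyze_synergy <- function(grid, threshold = 50, cmax = 1e-6,
                            isobole_levels = c(50, 90)) {
  fit <- fit_braid(grid)
  if (!fit$converged) {
    return(list(fit = fit, interaction = NA_character_, iae = NULL,
                isoboles = NULL))
  }
  iae <- compute_iae(fit$params, threshold = threshold, cmax = cmax)
  isos <- lapply(isobole_levels, function(lv) isobole(fit$params, lv))
  names(isos) <- paste0("level_", isobole_levels)
  list(fit = fit, interaction = classify_interaction(fit), iae = iae,
       isoboles = isos)
}
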