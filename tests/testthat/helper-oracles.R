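# Independent oracles used to validate the fitted pipeline. These deliberately
# use brute force or closed forms, never the code paths they check.

# Dense grid search over the (hill, log10 ec50) constraint box for the
# three-parameter model; the plateau is solved by linear least squares at
# each grid node (the model is linear in yFin given the shape) and clamped
# to its box. Returns the best residual sum of squares found.
oracle_grid_rss3 <- function(concentration, activity, max_median,
                             n_hill = 200, n_ec = 200) {
  hills <- seq(-10, 0, length.out = n_hill)
  lec <- seq(-11, -4, length.out = n_ec)
  lx <- log(concentration)
  yy <- sum(activity^2)
  up <- max(0, max_median)
  best <- Inf
  for (h in hills) {
    g <- 1 / (1 + exp(outer(lx, lec * log(10), function(a, b) h * (a - b))))
    num <- colSums(g * activity)
    den <- colSums(g * g)
    yf <- pmin(pmax(num / den, 0), up)
    rss <- yy - 2 * yf * num + yf^2 * den
    best <- min(best, min(rss))
  }
  best
}

# Closed-form integral of the log-logistic curve over u = log10(x):
# with c = -hill * ln(10), f(u) = y0 + (yFin - y0) / (1 + exp(-c (u - u50)))
# integrates to y0 (H - L) + (yFin - y0)/c [softplus(c(H-u50)) - softplus(c(L-u50))].
oracle_logistic_auc <- function(y0, yFin, hill, ec50,
                                lo = 1e-11, hi = 1e-4) {
  L <- log10(lo); H <- log10(hi); u50 <- log10(ec50)
  cc <- -hill * log(10)
  softplus <- function(t) ifelse(t > 30, t, log1p(exp(t)))
  y0 * (H - L) +
    (yFin - y0) / cc * (softplus(cc * (H - u50)) - softplus(cc * (L - u50)))
}

# Brute-force UPGMA (average linkage) agglomeration on a distance matrix;
# returns the ordered merge heights.
oracle_upgma_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) {
      for (j in seq_len(i - 1)) {
        d <- D[active[i], active[j]]
        if (d < bh) { bh <- d; best <- c(i, j) }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, bh)
    # UPGMA update: size-weighted mean distance to the merged cluster
    for (k in setdiff(active, c(i, j))) {
      dk <- (sizes[i] * D[i, k] + sizes[j] * D[j, k]) / (sizes[i] + sizes[j])
      D[i, k] <- D[k, i] <- dk
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

# Control well values with an exact sample mean and (n-1) sd, for
# closed-form z-prime cases: two wells at mean +/- sd/sqrt(2).
ctrl_pair <- function(mean, sd) mean + c(-1, 1) * sd / sqrt(2)

# Minimal single plate: layout + linear-scale reads built from explicit
# well values (rlu = value), 1-based coordinates.
toy_plate <- function(neg, pos, cmp_values,
                      conc = 3.5e-5 / 3^(seq_along(cmp_values) - 1),
                      plate_id = "P1", cell_line = "LX") {
  n <- length(neg) + length(pos) + length(cmp_values)
  roles <- c(rep("negative_control", length(neg)),
             rep("positive_control", length(pos)),
             rep("compound", length(cmp_values)))
  layout <- data.frame(
    plate_id = plate_id, row = 1L, col = seq_len(n), role = roles,
    compound_id = c(rep(NA_character_, length(neg) + length(pos)),
                    rep("DRUG1", length(cmp_values))),
    concentration_M = c(rep(NA_real_, length(neg) + length(pos)), conc),
    stringsAsFactors = FALSE
  )
  reads <- data.frame(
    plate_id = plate_id, cell_line = cell_line, row = 1L, col = seq_len(n),
    rlu = c(neg, pos, cmp_values), stringsAsFactors = FALSE
  )
  list(layout = layout, reads = reads)
}

# A random but well-conditioned response-surface parameter set.
rand_params <- function() {
  braid_params(E0 = stats::runif(1, -5, 10),
               Ef = stats::runif(1, 60, 120),
               ec50_a = 10^stats::runif(1, -8.5, -6.5),
               ec50_b = 10^stats::runif(1, -8.5, -6.5),
               n_a = stats::runif(1, 0.5, 4),
               n_b = stats::runif(1, 0.5, 4),
               kappa = stats::runif(1, -1.5, 5))
}

# True AUC of a ground-truth curve, going through the public curve evaluator
# on a sigmoid object built directly from the truth parameters.
truth_auc <- function(truth) {
  mapply(function(y0, yF, h, e) {
    f <- structure(list(y0 = y0, yFin = yF, hill = h, ec50 = e,
                        converged = TRUE), class = "sigmoid_fit")
    compute_auc(f)
  }, truth$y0, truth$yFin, truth$hill, truth$ec50)
}
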