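# Synthetic screen generator: ground-truth dose-response curves, 384-well
# plate layouts with DMSO-like negative and staurosporine-like positive
# control wells, seeded noisy luminescence reads, and combination grids
# generated from a known response surface. Every pipeline stage can be
# validated against the truth tables these functions return.

# Unit-mean multiplicative log-normal noise at a given coefficient of
# variation; luminescence noise scales with signal.
.ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Sample a ground-truth table for a synthetic screen
#'
#' Draws one true log-logistic curve per (drug, cell line): log10 EC50
#' uniform in `ec50_log10_range`, hill slope uniform in `hill_range`, plateau
#' `yFin` uniform in `yfin_range`, baseline `y0 = 0` except for a designated
#' fraction of curves given a nonzero baseline (used to exercise
#' four-parameter model selection). Records whose EC50 lies inside the tested
#' dilution window are flagged `recoverable`.
#'
#' @param n_drugs,n_lines screen dimensions.
#' @param seed integer seed (optional).
#' @param ec50_log10_range,hill_range,yfin_range truth sampling ranges.
#' @param baseline_fraction fraction of curves with `y0 = baseline_y0`.
#' @param baseline_y0 nonzero baseline (%), default 20.
#' @param dilution dilution series defining the recoverable window.
#' @return `data.frame` with columns `compound_id, cell_line, y0, yFin,
#'   hill, ec50, recoverable`.
#' @export
sample_screen_truth <- function(n_drugs, n_lines, seed = NULL,
                                ec50_log10_range = c(-9, -5.5),
                                hill_range = c(-4, -0.5),
                                yfin_range = c(30, 110),
                                baseline_fraction = 0, baseline_y0 = 20,
                                dilution = build_dilution_series(35e-6, 10, 3)) {
  if (n_drugs == 0 || n_lines == 0) {
    return(data.frame(compound_id = character(0), cell_line = character(0),
                      y0 = numeric(0), yFin = numeric(0), hill = numeric(0),
                      ec50 = numeric(0), recoverable = logical(0)))
  }
  with_seed(seed, {
    drugs <- sprintf("D%03d", seq_len(n_drugs))
    lines <- sprintf("L%02d", seq_len(n_lines))
    truth <- expand.grid(compound_id = drugs, cell_line = lines,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(truth)
    truth$y0 <- ifelse(stats::runif(n) < baseline_fraction, baseline_y0, 0)
    truth$yFin <- truth$y0 +
      stats::runif(n, yfin_range[1], yfin_range[2])
    truth$hill <- stats::runif(n, hill_range[1], hill_range[2])
    truth$ec50 <- 10^stats::runif(n, ec50_log10_range[1],
                                  ec50_log10_range[2])
    rng <- range(dilution$concentrations)
    truth$recoverable <- truth$ec50 >= rng[1] & truth$ec50 <= rng[2]
    truth
  })
}

#' Build a 384-well plate layout for dilution series
#'
#' Packs each compound's descending dilution series row-major into columns
#' 1-22 of a 16 x 24 plate and reserves column 23 for 16 negative-control
#' (DMSO) wells and column 24 for 16 positive-control (staurosporine) wells.
#' A 10-point series therefore allows up to 35 compounds per plate.
#'
#' @param plate_id plate identifier.
#' @param compound_ids compounds placed on this plate.
#' @param dilution `dilution_series` shared by all compounds.
#' @return a layout `data.frame` (see [read_plate_layout()] for the schema).
#' @export
build_screen_layout <- function(plate_id, compound_ids,
                                dilution = build_dilution_series(35e-6, 10, 3)) {
  n_pts <- dilution$n_points
  capacity <- (16 * 22) %/% n_pts
  if (length(compound_ids) > capacity) {
    stopf("plate %s holds at most %d series of %d points", plate_id,
          capacity, n_pts)
  }
  wells <- data.frame(
    plate_id = plate_id,
    row = rep(NA_integer_, length(compound_ids) * n_pts),
    col = NA_integer_,
    role = "compound",
    compound_id = rep(compound_ids, each = n_pts),
    concentration_M = rep(dilution$concentrations, length(compound_ids)),
    stringsAsFactors = FALSE
  )
  idx <- seq_len(nrow(wells)) - 1L
  wells$row <- idx %/% 22L + 1L
  wells$col <- idx %% 22L + 1L
  controls <- data.frame(
    plate_id = plate_id,
    row = rep(1:16, 2),
    col = rep(c(23L, 24L), each = 16),
    role = rep(c("negative_control", "positive_control"), each = 16),
    compound_id = NA_character_,
    concentration_M = NA_real_,
    stringsAsFactors = FALSE
  )
  validate_layout(rbind(wells, controls))
}

#' Simulate luminescence reads for one plate
#'
#' Control wells are drawn around their true means with multiplicative
#' log-normal noise. Compound-well RLU is placed so that the plate's own
#' normalization recovers the true activity exactly at zero noise: on the
#' log2 scale `rlu = neg_mean * (pos_mean/neg_mean)^(a/100)`, on the linear
#' scale `rlu = neg_mean - (a/100) * (neg_mean - pos_mean)`, where `a` is the
#' true % activity at the well's concentration; noise then multiplies the
#' noiseless RLU.
#'
#' @param layout plate layout (single plate).
#' @param truth truth table from [sample_screen_truth()].
#' @param cell_line line assayed on this plate.
#' @param neg_mean,pos_mean true control RLU means.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param scale the normalization scale the screen will be analysed on
#'   (`"log2"` for single agents, `"linear"` for combinations).
#' @param seed integer seed (optional).
#' @return a reads `data.frame` (`plate_id, cell_line, row, col, rlu`).
#' @export
simulate_plate <- function(layout, truth, cell_line, neg_mean = 1e6,
                           pos_mean = 1e5, cv = 0.05,
                           scale = c("log2", "linear"), seed = NULL) {
  scale <- match.arg(scale)
  layout <- validate_layout(layout)
  if (length(unique(layout$plate_id)) != 1) {
    stopf("simulate_plate expects a single-plate layout")
  }
  with_seed(seed, {
    rlu <- numeric(nrow(layout))
    is_neg <- layout$role == "negative_control"
    is_pos <- layout$role == "positive_control"
    is_cmp <- layout$role == "compound"
    rlu[is_neg] <- neg_mean
    rlu[is_pos] <- pos_mean
    if (any(is_cmp)) {
      key <- paste(layout$compound_id[is_cmp], cell_line)
      ti <- match(key, paste(truth$compound_id, truth$cell_line))
      if (anyNA(ti)) {
        stopf("layout compounds missing from the truth table for line %s",
              cell_line)
      }
      act <- sigmoid_curve(layout$concentration_M[is_cmp],
                           truth$y0[ti], truth$yFin[ti],
                           truth$hill[ti], truth$ec50[ti])
      rlu[is_cmp] <- if (scale == "log2") {
        neg_mean * (pos_mean / neg_mean)^(act / 100)
      } else {
        neg_mean - (act / 100) * (neg_mean - pos_mean)
      }
    }
    keep <- layout$role != "empty"
    data.frame(
      plate_id = layout$plate_id[keep],
      cell_line = cell_line,
      row = layout$row[keep],
      col = layout$col[keep],
      rlu = rlu[keep] * .ln_noise(sum(keep), cv),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a full factorial drug screen
#'
#' Generates the study design end to end: one truth curve per (drug, line),
#' triplicate 10-point threefold dilution series from a 35 uM top
#' concentration by default, packed onto 384-well plates (one plate per line,
#' replicate and 35-compound chunk) with 16 + 16 control wells, and noisy
#' luminescence reads. Optionally one line is made pan-sensitive by shifting
#' its whole true curve up by a constant kill, and a fraction of curves get a
#' nonzero baseline.
#'
#' @param n_drugs,n_lines screen dimensions.
#' @param dilution dilution series tested for every drug.
#' @param replicates replicate plates per (line, chunk).
#' @param seed integer seed.
#' @param outlier_line index (1..n_lines) of a line to make uniformly
#'   hypersensitive, or `NULL`.
#' @param outlier_extra_activity constant % activity added to the outlier
#'   line's true curves (default 20).
#' @param baseline_fraction passed to [sample_screen_truth()].
#' @param neg_mean,pos_mean,cv control means and noise level.
#' @param truth optional pre-built truth table (overrides sampling).
#' @return list with `layout` (all plates), `reads`, `truth`, `dilution`.
#' @export
simulate_screen <- function(n_drugs, n_lines,
                            dilution = build_dilution_series(35e-6, 10, 3),
                            replicates = 3, seed = NULL,
                            outlier_line = NULL,
                            outlier_extra_activity = 20,
                            baseline_fraction = 0,
                            neg_mean = 1e6, pos_mean = 1e5, cv = 0.05,
                            truth = NULL) {
  with_seed(seed, {
    if (is.null(truth)) {
      truth <- sample_screen_truth(n_drugs, n_lines,
                                   baseline_fraction = baseline_fraction,
                                   dilution = dilution)
    }
    if (nrow(truth) == 0) {
      return(list(layout = NULL, reads = NULL, truth = truth,
                  dilution = dilution))
    }
    lines <- sort(unique(truth$cell_line))
    drugs <- sort(unique(truth$compound_id))
    if (!is.null(outlier_line)) {
      ol <- lines[outlier_line]
      sel <- truth$cell_line == ol
      truth$y0[sel] <- truth$y0[sel] + outlier_extra_activity
      truth$yFin[sel] <- truth$yFin[sel] + outlier_extra_activity
      attr(truth, "outlier_line") <- ol
    }
    capacity <- (16 * 22) %/% dilution$n_points
    chunks <- split(drugs, (seq_along(drugs) - 1) %/% capacity)
    layouts <- list(); reads <- list()
    for (li in lines) {
      for (r in seq_len(replicates)) {
        for (ci in seq_along(chunks)) {
          pid <- sprintf("%s_r%d_p%02d", li, r, ci)
          lay <- build_screen_layout(pid, chunks[[ci]], dilution)
          layouts[[pid]] <- lay
          reads[[pid]] <- simulate_plate(lay, truth, li,
                                         neg_mean = neg_mean,
                                         pos_mean = pos_mean, cv = cv)
        }
      }
    }
    list(layout = do.call(rbind, c(layouts, make.row.names = FALSE)),
         reads = do.call(rbind, c(reads, make.row.names = FALSE)),
         truth = truth, dilution = dilution)
  })
}

#' Simulate a two-drug combination grid
#'
#' Evaluates a known response surface on the dose grid (zero-dose edges are
#' always included) and adds Gaussian noise in % activity units, emulating
#' the linear-scale normalization used for combination screens.
#'
#' @param params true `braid_params`.
#' @param doses_a,doses_b nonzero dose ladders (M); 0 is added to each.
#' @param noise_sd additive noise standard deviation (% activity).
#' @param replicates measurements per grid cell.
#' @param seed integer seed.
#' @return a grid `data.frame`: `dose_a_M, dose_b_M, activity_pct,
#'   replicate_id`.
#' @export
simulate_combination_grid <- function(params, doses_a, doses_b,
                                      noise_sd = 0, replicates = 1,
                                      seed = NULL) {
  stopifnot(inherits(params, "braid_params"))
  doses_a <- sort(unique(c(0, doses_a)))
  doses_b <- sort(unique(c(0, doses_b)))
  cells <- expand.grid(dose_a_M = doses_a, dose_b_M = doses_b,
                       KEEP.OUT.ATTRS = FALSE)
  with_seed(seed, {
    grid <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      g <- cells
      g$activity_pct <- braid_effect(params, g$dose_a_M, g$dose_b_M) +
        stats::rnorm(nrow(g), sd = noise_sd)
      g$replicate_id <- r
      g
    }))
    rownames(grid) <- NULL
    grid
  })
}
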