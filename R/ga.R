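#' Genetic-algorithm configuration for GA-PLS variable selection
#'
#' Defaults follow the standard GA-PLS recipe for spectral data: 50
#' chromosomes, window width 1 for FTIR and 8 for Raman, at most 200
#' generations, bit-flip mutation at 0.01, double (two-point) crossover and
#' 50 replicate runs, with internal venetian-blind cross-validated RMSECV as
#' the fitness. Internals the recipe leaves open are fixed here: tournament
#' selection of size 2, elitism of 1, early stop after 30 stagnant
#' generations, a 10-LV cap inside the fitness and 10 inner CV folds.
#'
#' @param population Number of chromosomes.
#' @param window_width Contiguous variables per window (1 for FTIR, 8 for
#'   Raman; the last window may be short).
#' @param max_generations Generation cap.
#' @param mutation_rate Per-bit flip probability.
#' @param crossover Crossover type (`"double"` = two-point).
#' @param replicate_runs Independent GA repetitions aggregated into
#'   selection frequencies.
#' @param tournament_size,elitism,early_stop,p_init GA internals: tournament
#'   size, elite count, stagnant-generation stop, initial bit probability.
#' @param lv_cap,inner_folds Fitness internals: LV cap and venetian-blind
#'   fold count of the inner cross-validation.
#' @param freq_threshold Selection-frequency cut for the final subset;
#'   `NULL` scans the deciles and keeps the smallest cut whose subset
#'   minimises calibration RMSECV.
#' @return List of class `"ga_config"`.
#' @export
ga_config <- function(population = 50, window_width = 1,
                      max_generations = 200, mutation_rate = 0.01,
                      crossover = "double", replicate_runs = 50,
                      tournament_size = 2, elitism = 1, early_stop = 30,
                      p_init = 0.3, lv_cap = 10, inner_folds = 10,
                      freq_threshold = NULL) {
  stopifnot(population >= 2, window_width >= 1, max_generations >= 1,
            mutation_rate >= 0, mutation_rate <= 1, replicate_runs >= 1)
  structure(list(population = population, window_width = window_width,
                 max_generations = max_generations,
                 mutation_rate = mutation_rate, crossover = crossover,
                 replicate_runs = replicate_runs,
                 tournament_size = tournament_size, elitism = elitism,
                 early_stop = early_stop, p_init = p_init, lv_cap = lv_cap,
                 inner_folds = inner_folds, freq_threshold = freq_threshold),
            class = "ga_config")
}

# Partition variable indices into contiguous windows of the given width.
variable_windows <- function(n_var, width) {
  starts <- seq(1, n_var, by = width)
  lapply(starts, function(s) seq(s, min(s + width - 1, n_var)))
}

# RMSECV-based fitness of a window subset (lower is better); all-zero
# chromosomes get +Inf and can never be selected.
ga_fitness_fun <- function(X, y, windows, cfg) {
  n <- nrow(X)
  cache <- new.env(parent = emptyenv())
  function(chrom) {
    if (!any(chrom)) return(Inf)
    key <- paste(which(chrom), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    cols <- unlist(windows[chrom], use.names = FALSE)
    folds <- min(cfg$inner_folds, n)
    cap <- min(cfg$lv_cap, length(cols), n - ceiling(n / folds) - 1)
    val <- if (cap < 1) Inf else {
      cv <- venetian_blinds_cv(X[, cols, drop = FALSE], y,
                               max_lv = cap, n_folds = folds)
      min(cv$rmsecv)
    }
    cache[[key]] <- val
    val
  }
}

# One GA run; returns the best chromosome, its fitness and the per-generation
# best-fitness trace (non-increasing thanks to elitism).
ga_run <- function(fitness, n_win, cfg, seed) {
  local_seed(seed, {
    pop <- matrix(stats::runif(cfg$population * n_win) < cfg$p_init,
                  nrow = cfg$population)
    empty <- rowSums(pop) == 0
    if (any(empty)) {                     # give empty chromosomes one bit
      pop[cbind(which(empty), sample.int(n_win, sum(empty), replace = TRUE))] <- TRUE
    }
    fit <- apply(pop, 1, fitness)
    trace <- numeric(0)
    stagnant <- 0L
    best_prev <- Inf
    for (g in seq_len(cfg$max_generations)) {
      ord <- order(fit)
      elite_idx <- ord[seq_len(cfg$elitism)]
      new_pop <- matrix(FALSE, cfg$population, n_win)
      new_pop[seq_len(cfg$elitism), ] <- pop[elite_idx, , drop = FALSE]
      row <- cfg$elitism
      pick <- function() {
        cand <- sample.int(cfg$population, cfg$tournament_size, replace = TRUE)
        cand[which.min(fit[cand])]
      }
      while (row < cfg$population) {
        p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
        if (n_win >= 2) {                  # double (two-point) crossover
          cuts <- sort(sample.int(n_win - 1, 2, replace = TRUE))
          seg <- seq(cuts[1] + 1, cuts[2])
          if (cuts[1] < cuts[2]) {
            tmp <- p1[seg]; p1[seg] <- p2[seg]; p2[seg] <- tmp
          }
        }
        for (child in list(p1, p2)) {
          if (row >= cfg$population) break
          if (cfg$mutation_rate > 0) {
            flip <- stats::runif(n_win) < cfg$mutation_rate
            child <- xor(child, flip)
          }
          row <- row + 1
          new_pop[row, ] <- child
        }
      }
      pop <- new_pop
      fit <- apply(pop, 1, fitness)
      best <- min(fit)
      trace <- c(trace, best)
      if (best < best_prev - 1e-12) {
        stagnant <- 0L
        best_prev <- best
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= cfg$early_stop) break
      }
    }
    b <- which.min(fit)
    list(best = pop[b, ], fitness = fit[b], trace = trace)
  })
}

#' GA-PLS variable selection
#'
#' Evolves bit-vectors over contiguous variable windows with internal
#' cross-validated PLS RMSECV as the fitness, repeats the evolution over
#' independent replicate runs, and aggregates the per-window selection
#' frequency of the run-best chromosomes. The final subset keeps the
#' windows whose frequency reaches the configured cut (or, by default, the
#' smallest decile cut whose subset minimises calibration RMSECV).
#'
#' @param X,y Calibration data matrix and response (prediction samples must
#'   not be passed here).
#' @param cfg A [ga_config()].
#' @param seed Master seed; replicate run `r` uses a seed derived from
#'   `(seed, r)`, and the whole result is reproducible.
#' @return List of class `"ga_result"`: `frequency` (per window),
#'   `selected_windows`, `selected_variables` (column indices), `windows`,
#'   `threshold`, `run_fitness`, `traces`.
#' @export
ga_select <- function(X, y, cfg = ga_config(), seed = 1) {
  X <- as.matrix(X)
  windows <- variable_windows(ncol(X), cfg$window_width)
  n_win <- length(windows)
  fitness <- ga_fitness_fun(X, y, windows, cfg)
  runs <- lapply(seq_len(cfg$replicate_runs), function(r) {
    ga_run(fitness, n_win, cfg, derive_seed(seed, 7L, r))
  })
  best_mat <- do.call(rbind, lapply(runs, `[[`, "best"))
  freq <- colMeans(best_mat)
  if (is.null(cfg$freq_threshold)) {
    cuts <- seq(0.1, 1, by = 0.1)
    cand <- lapply(cuts, function(ct) freq >= ct)
    ok <- vapply(cand, any, logical(1))
    cuts <- cuts[ok]; cand <- cand[ok]
    if (length(cand) == 0) {              # nothing recurrent: take best run
      chrom <- runs[[which.min(vapply(runs, `[[`, numeric(1), "fitness"))]]$best
      threshold <- NA_real_
    } else {
      fits <- vapply(cand, fitness, numeric(1))
      threshold <- cuts[which.min(fits)]  # ties -> smallest cut
      chrom <- freq >= threshold
    }
  } else {
    threshold <- cfg$freq_threshold
    chrom <- freq >= threshold
    if (!any(chrom)) stop("no window reaches the frequency threshold")
  }
  structure(
    list(frequency = freq, selected_windows = which(chrom),
         selected_variables = sort(unlist(windows[chrom], use.names = FALSE)),
         windows = windows, threshold = threshold,
         run_fitness = vapply(runs, `[[`, numeric(1), "fitness"),
         traces = lapply(runs, `[[`, "trace"), config = cfg),
    class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> %d/%d windows selected (threshold %s), %d variables; best run RMSECV %.4g\n",
    length(x$selected_windows), length(x$windows), format(x$threshold),
    length(x$selected_variables), min(x$run_fitness)))
  invisible(x)
}

#' Build and evaluate a chronological-age regression model
#'
#' The full modelling pipeline: Kennard-Stone split of the samples into
#' calibration and prediction sets, optional GA variable selection on the
#' calibration set only, venetian-blind cross-validation on the calibration
#' set to fix the number of latent variables, a final PLS fit, and
#' evaluation on the untouched prediction set. Prediction samples take part
#' in neither selection nor calibration (asserted).
#'
#' @param X Samples x variables matrix (spectral channels or outcome panel).
#' @param y Chronological ages, years.
#' @param use_ga Run GA-PLS variable selection?
#' @param cfg [ga_config()] used when `use_ga = TRUE`.
#' @param calibration_fraction Kennard-Stone calibration fraction.
#' @param n_folds Venetian-blind folds for LV selection (default 20).
#' @param max_lv LV scan cap; default `min(15, floor(n_cal / 10))`, bounded
#'   by the variable count and fold capacity.
#' @param seed Seed for the GA (the rest of the pipeline is deterministic).
#' @param variable_labels Optional labels (e.g. wavenumbers) stored with the
#'   selected variables.
#' @return List of class `"age_model_report"`: `summary` (one-row data frame
#'   `method`, `vns`, `lvs`, `r2cv`, `rmsecv`, `r2pred`, `rmsep`), `model`,
#'   `cv`, `split`, `ga` (or `NULL`), `selected_variables`, `predictions`.
#' @export
build_age_model <- function(X, y, use_ga = FALSE, cfg = ga_config(),
                            calibration_fraction = 0.7, n_folds = 20,
                            max_lv = NULL, seed = 1,
                            variable_labels = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  split <- kennard_stone_split(X, calibration_fraction)
  stopifnot(length(intersect(split$calibration, split$prediction)) == 0)
  Xc <- X[split$calibration, , drop = FALSE]
  yc <- y[split$calibration]

  ga <- NULL
  vars <- seq_len(ncol(X))
  if (use_ga) {
    ga <- ga_select(Xc, yc, cfg, seed = seed)
    vars <- ga$selected_variables
  }
  n_cal <- nrow(Xc)
  folds <- min(n_folds, n_cal)
  cap <- min(15, floor(n_cal / 10))
  cap <- min(cap, length(vars), n_cal - ceiling(n_cal / folds) - 1)
  if (!is.null(max_lv)) cap <- min(max_lv, cap)
  cap <- max(cap, 1)
  cv <- venetian_blinds_cv(Xc[, vars, drop = FALSE], yc,
                           max_lv = cap, n_folds = folds)
  lv <- cv$chosen_lv
  model <- pls_fit(Xc[, vars, drop = FALSE], yc, lv)
  y_hat <- pls_predict(model, X[split$prediction, vars, drop = FALSE])
  pm <- regression_metrics(y[split$prediction], y_hat)
  summary_row <- data.frame(
    method = if (use_ga) "GA-PLS" else "PLS",
    vns = length(vars), lvs = lv,
    r2cv = cv$r2cv[lv], rmsecv = cv$rmsecv[lv],
    r2pred = pm$r2, rmsep = pm$rmse,
    stringsAsFactors = FALSE)
  structure(
    list(summary = summary_row, model = model, cv = cv, split = split,
         ga = ga, selected_variables = vars,
         selected_labels = if (!is.null(variable_labels))
           variable_labels[vars] else vars,
         predictions = data.frame(index = split$prediction,
                                  age = y[split$prediction],
                                  predicted = y_hat)),
    class = "age_model_report")
}

#' @export
print.age_model_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<age_model_report> %s: VNs %d, LVs %d | R2CV %.3f RMSECV %.4g | R2Pred %.3f RMSEP %.4g\n",
    s$method, s$vns, s$lvs, s$r2cv, s$rmsecv, s$r2pred, s$rmsep))
  invisible(x)
}
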