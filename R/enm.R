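#' Spatially thin occurrence points
#'
#' Greedy sequential pass in input order: a point is kept iff no previously
#' kept point lies within `min_dist`. Reduces clustering and uneven sampling
#' effort before model fitting.
#'
#' @param occ data.frame with `x`, `y` (metres); extra columns preserved.
#' @param min_dist Minimum separation in metres (default 50).
#' @return The thinned data.frame, input order preserved.
#' @export
thin_occurrences <- function(occ, min_dist = 50) {
  occ <- as.data.frame(occ)
  if (min_dist < 0) stop("`min_dist` must be >= 0", call. = FALSE)
  n <- nrow(occ)
  if (n <= 1L) return(occ)
  keep <- logical(n)
  kx <- ky <- numeric(0)
  for (i in seq_len(n)) {
    if (!length(kx) ||
        all((kx - occ$x[i])^2 + (ky - occ$y[i])^2 >= min_dist^2)) {
      keep[i] <- TRUE
      kx <- c(kx, occ$x[i]); ky <- c(ky, occ$y[i])
    }
  }
  occ[keep, , drop = FALSE]
}

#' Sample pseudo-absence sets
#'
#' Draws `n_sets` independent sets of `n` pseudo-absence points from cell
#' centres of the non-nodata cells of `frame`. The `disk` method restricts
#' the draw to cells strictly farther than `min_dist` from every presence;
#' `random` uses all non-nodata cells.
#'
#' @param frame `grid_raster` defining eligible cells (NA = ineligible).
#' @param occ Presence data.frame with `x`, `y` (may be empty for `random`).
#' @param n Points per set.
#' @param n_sets Number of sets.
#' @param method `"random"` or `"disk"`.
#' @param min_dist Exclusion radius for the disk method (m).
#' @param seed Integer seed.
#' @return List of `n_sets` data.frames with `x`, `y`, `cell`.
#' @export
sample_pseudo_absences <- function(frame, occ, n, n_sets = 1L,
                                   method = c("random", "disk"),
                                   min_dist = 50, seed = 1L) {
  method <- match.arg(method)
  stopifnot_raster(frame)
  eligible <- which(!is.na(frame$values))
  if (method == "disk" && nrow(as.data.frame(occ)) > 0) {
    cc <- cell_centers(frame, eligible)
    d <- rep(Inf, length(eligible))
    occ <- as.data.frame(occ)
    for (j in seq_len(nrow(occ)))
      d <- pmin(d, sqrt((cc$x - occ$x[j])^2 + (cc$y - occ$y[j])^2))
    eligible <- eligible[d > min_dist]
  }
  if (length(eligible) < n)
    stop(sprintf("infeasible: %d eligible cells for %d pseudo-absences",
                 length(eligible), n), call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_sets), function(k) {
      cells <- if (length(eligible) == 1L) eligible else
        sample(eligible, n, replace = FALSE)
      cc <- cell_centers(frame, cells)
      data.frame(x = cc$x, y = cc$y, cell = cc$cell)
    })
  })
}

#' Presence / pseudo-absence weights
#'
#' Presences get weight 1 and pseudo-absences `n_presence / n_pa`, so the
#' two classes carry exactly equal total weight in the fit.
#'
#' @param n_presence,n_pa Class sizes (> 0).
#' @return List with `presence` and `pa` weights.
#' @export
compute_weights <- function(n_presence, n_pa) {
  if (n_presence <= 0 || n_pa <= 0)
    stop("both class sizes must be positive", call. = FALSE)
  list(presence = 1, pa = n_presence / n_pa)
}

#' Stratified train / evaluation split
#'
#' Random split stratified by class: `round(fraction * n)` points of each
#' class go to training, the rest to evaluation.
#'
#' @param labels 0/1 vector.
#' @param fraction Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `eval`.
#' @export
split_train_eval <- function(labels, fraction = 0.7, seed = 1L) {
  labels <- as.integer(labels)
  tab <- table(labels)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need >= 2 points in each class", call. = FALSE)
  with_seed(seed, {
    train <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == as.integer(cl))
      train <- c(train, sample(idx, round(fraction * length(idx))))
    }
    train <- sort(train)
    list(train = train, eval = setdiff(seq_along(labels), train))
  })
}

#' Rank-based AUC-ROC
#'
#' Mann-Whitney formulation: the probability that a random presence is
#' scored above a random (pseudo-)absence, ties counting one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 vector.
#' @return AUC in [0, 1].
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True Skill Statistic
#'
#' Maximum over candidate thresholds (the distinct score values) of
#' sensitivity + specificity - 1, with prediction positive when
#' `score >= threshold`. Ties on TSS are broken by the lower threshold.
#'
#' @inheritParams auc_roc
#' @return List with `tss` and `threshold`.
#' @export
tss <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("TSS undefined: both classes must be present", call. = FALSE)
  thr <- sort(unique(scores))
  best <- -Inf; best_thr <- thr[1]
  for (t in thr) {
    pos <- scores >= t
    val <- sum(pos & labels == 1L) / n1 + sum(!pos & labels == 0L) / n0 - 1
    if (val > best) { best <- val; best_thr <- t }
  }
  list(tss = best, threshold = best_thr)
}

# --- learner registry -------------------------------------------------------

.learners <- new.env(parent = emptyenv())

#' Pluggable learner registry
#'
#' Single-model algorithms are pluggable: a learner is a pair of functions
#' `fit(x, y, weights, seed)` -> opaque model and `predict(model, x)` ->
#' probabilities in [0, 1]. Two families ship by default: `"glm"` (weighted
#' logistic regression) and `"rf"` (probability random forest via ranger).
#'
#' @param id Learner label.
#' @param fit,predict Learner functions (see Details).
#' @return `register_learner` returns `id` invisibly; `list_learners` the
#'   registered labels.
#' @export
register_learner <- function(id, fit, predict) {
  stopifnot(is.character(id), length(id) == 1L,
            is.function(fit), is.function(predict))
  assign(id, list(fit = fit, predict = predict), envir = .learners)
  invisible(id)
}

#' @rdname register_learner
#' @export
list_learners <- function() sort(ls(.learners))

get_learner <- function(id) {
  if (!exists(id, envir = .learners, inherits = FALSE))
    stop(sprintf("unknown learner '%s'; see list_learners()", id),
         call. = FALSE)
  get(id, envir = .learners, inherits = FALSE)
}

register_default_learners <- function() {
  register_learner(
    "glm",
    fit = function(x, y, weights, seed = NULL) {
      dat <- cbind(as.data.frame(x), .y = y)
      # non-integer class weights trigger a harmless binomial warning
      suppressWarnings(stats::glm(.y ~ ., data = dat,
                                  family = stats::binomial(),
                                  weights = weights))
    },
    predict = function(model, x) {
      # rank-deficient fits (constant covariates) warn harmlessly
      unname(suppressWarnings(stats::predict(model,
                                             newdata = as.data.frame(x),
                                             type = "response")))
    })
  register_learner(
    "rf",
    fit = function(x, y, weights, seed = NULL) {
      ranger::ranger(x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
                     probability = TRUE, num.trees = 200,
                     case.weights = weights,
                     seed = if (is.null(seed)) 1L else seed,
                     num.threads = 1L)
    },
    predict = function(model, x) {
      unname(stats::predict(model, data = as.data.frame(x),
                            num.threads = 1L)$predictions[, "1"])
    })
}

#' Fit one single-model run
#'
#' @param learner_id Registered learner label.
#' @param x Covariate data.frame.
#' @param y 0/1 response.
#' @param weights Per-point weights (default all 1).
#' @param seed Seed passed to stochastic learners.
#' @return An object of class `model_run` with a `predict(newdata)` closure.
#' @export
fit_single_model <- function(learner_id, x, y, weights = NULL, seed = 1L) {
  learner <- get_learner(learner_id)
  x <- as.data.frame(x)
  if (ncol(x) < 1L) stop("need >= 1 covariate", call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("degenerate training data: only one class present", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(y))
  model <- learner$fit(x, y, weights, seed)
  structure(
    list(learner_id = learner_id, model = model,
         predict = function(newdata) {
           p <- learner$predict(model, newdata)
           pmin(pmax(p, 0), 1)
         },
         tss = NA_real_, auc = NA_real_,
         pa_set_index = NA_integer_, run_index = NA_integer_),
    class = "model_run")
}

#' Permutation importance of a variable
#'
#' Mean over `n_perm` permutations of `1 - r`, where `r` is the Pearson
#' correlation between predictions on the original data and on data with the
#' variable permuted. 0 by convention when predictions are constant.
#'
#' @param run A `model_run`.
#' @param x Covariate data.frame.
#' @param variable Column name to permute.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Non-negative importance.
#' @export
permutation_importance <- function(run, x, variable, n_perm = 5L, seed = 1L) {
  x <- as.data.frame(x)
  if (!variable %in% names(x))
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  p0 <- run$predict(x)
  if (stats::sd(p0) == 0) return(0)
  with_seed(seed, {
    vals <- vapply(seq_len(n_perm), function(i) {
      xp <- x
      xp[[variable]] <- sample(xp[[variable]])
      p1 <- run$predict(xp)
      r <- suppressWarnings(stats::cor(p0, p1))
      1 - if (is.na(r)) 0 else r
    }, numeric(1))
    mean(vals)
  })
}

#' Correlation-aware variable selection
#'
#' Variables are clustered by single linkage on `1 - |Pearson r|`, cutting
#' so that any pair with `|r| >= corr_threshold` falls in one cluster;
#' within each cluster the variable with the highest mean permutation
#' importance across the requested learners is retained. Input order is
#' preserved in the output.
#'
#' @param x Labelled covariate data.frame (candidates as columns).
#' @param y 0/1 response used to fit the importance models.
#' @param weights Optional per-point weights.
#' @param corr_threshold Absolute-correlation grouping threshold.
#' @param learners Learner labels used for the importance average.
#' @param n_perm Permutations per importance estimate.
#' @param seed Integer seed.
#' @return Character vector of retained variable names.
#' @export
select_variables <- function(x, y, weights = NULL, corr_threshold = 0.7,
                             learners = c("glm", "rf"), n_perm = 3L,
                             seed = 1L) {
  x <- as.data.frame(x)
  vars <- names(x)
  if (length(vars) < 1L) stop("need >= 1 candidate variable", call. = FALSE)
  if (length(vars) == 1L) return(vars)
  cm <- suppressWarnings(abs(stats::cor(x)))
  cm[is.na(cm)] <- 0
  grp <- stats::cutree(stats::hclust(stats::as.dist(1 - cm),
                                     method = "single"),
                       h = 1 - corr_threshold)
  imp <- matrix(0, length(vars), length(learners),
                dimnames = list(vars, learners))
  for (j in seq_along(learners)) {
    run <- fit_single_model(learners[j], x, y, weights, seed = seed + j)
    for (v in vars)
      imp[v, j] <- permutation_importance(run, x, v, n_perm = n_perm,
                                          seed = seed + j)
  }
  mean_imp <- rowMeans(imp)
  keep <- vapply(unique(grp), function(g) {
    members <- vars[grp == g]
    members[which.max(mean_imp[members])]
  }, character(1))
  vars[vars %in% keep]
}

#' Number of single-model runs in an ensemble design
#'
#' The pipeline enumerates exactly `n_learners * n_pa_sets * n_runs` runs;
#' eight algorithms with five PA sets and five runs give 200 models, with
#' ten PA sets 400 models.
#'
#' @param n_learners,n_pa_sets,n_runs Positive integers.
#' @return The product, as an integer count.
#' @export
count_model_runs <- function(n_learners, n_pa_sets, n_runs) {
  v <- c(n_learners, n_pa_sets, n_runs)
  if (any(v <= 0) || any(v != round(v)))
    stop("all design counts must be positive integers", call. = FALSE)
  as.integer(n_learners) * as.integer(n_pa_sets) * as.integer(n_runs)
}

#' Enumerate the single-model run specifications
#'
#' @param learners Character vector of learner labels.
#' @param n_pa_sets,n_runs Design counts.
#' @return data.frame with one row per run: `learner_id`, `pa_set`, `run`.
#' @export
enumerate_model_runs <- function(learners, n_pa_sets, n_runs) {
  grid <- expand.grid(run = seq_len(n_runs), pa_set = seq_len(n_pa_sets),
                      learner_id = learners, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid[, c("learner_id", "pa_set", "run")]
}

#' TSS-gated ensemble of single-model runs
#'
#' Keeps the runs with TSS strictly above `tss_cutoff`; the ensemble mean
#' surface is their unweighted cellwise mean and the uncertainty surface the
#' cellwise coefficient of variation (population standard deviation / mean,
#' 0 where the mean is 0).
#'
#' @param runs List of `model_run` objects, each carrying a numeric `tss`
#'   and a prediction `surface` (`grid_raster`).
#' @param frame Frame of the prediction surfaces.
#' @param tss_cutoff Gate (default 0.7).
#' @return An object of class `ensemble_model`.
#' @export
build_ensemble <- function(runs, frame, tss_cutoff = 0.7) {
  stopifnot_raster(frame)
  tss_vals <- vapply(runs, function(r) r$tss, numeric(1))
  pass <- which(tss_vals > tss_cutoff)
  if (!length(pass))
    stop("empty ensemble: no run has TSS above the cutoff", call. = FALSE)
  preds <- lapply(runs[pass], function(r) {
    check_same_frame(frame, r$surface, "prediction surfaces")
    r$surface$values
  })
  arr <- simplify2array(preds)
  if (length(pass) == 1L) {
    mean_v <- preds[[1]]
    cv_v <- matrix(0, nrow(mean_v), ncol(mean_v))
    cv_v[is.na(mean_v)] <- NA
  } else {
    mean_v <- apply(arr, c(1, 2), mean)
    sd_v <- apply(arr, c(1, 2), function(z)
      sqrt(mean((z - mean(z))^2)))  # population sd
    cv_v <- ifelse(mean_v == 0, 0, sd_v / mean_v)
  }
  structure(
    list(members = runs, passing = pass, tss_cutoff = tss_cutoff,
         mean_surface = grid_raster(mean_v, frame$origin, frame$cell_size,
                                    frame$crs),
         cv_surface = grid_raster(cv_v, frame$origin, frame$cell_size,
                                  frame$crs)),
    class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d/%d runs pass TSS > %g\n",
              length(x$passing), length(x$members), x$tss_cutoff))
  invisible(x)
}

#' Fit a TSS-gated ensemble over a covariate stack
#'
#' The full single-species workflow for one scale: extract covariates at
#' presence cells, draw pseudo-absence sets, enumerate
#' `learners x n_sets x n_runs` single-model runs, split 70/30 per run,
#' weight classes equally, fit, score TSS and AUC on the held-out fraction,
#' and gate the ensemble. Presence cells are deduplicated (one occurrence
#' per cell) before fitting.
#'
#' @param covariates Named list of aligned `grid_raster` layers.
#' @param occ Presence data.frame with `x`, `y`.
#' @param learners Learner labels (default both shipped families).
#' @param n_pa Pseudo-absences per set.
#' @param n_sets,n_runs Ensemble design counts.
#' @param pa_method `"random"` or `"disk"`.
#' @param pa_min_dist Disk exclusion radius (m).
#' @param split_fraction Training fraction (default 0.7).
#' @param tss_cutoff Ensemble gate (default 0.7).
#' @param thin_dist Optional thinning distance applied to `occ` first.
#' @param seed Integer seed.
#' @return An `ensemble_model` with a run `ledger` data.frame
#'   (learner, pa_set, run, tss, auc), the `calibration` covariate table at
#'   presence cells, and training medians/ranges for response curves.
#' @export
run_enm <- function(covariates, occ, learners = c("glm", "rf"),
                    n_pa = 1000L, n_sets = 2L, n_runs = 2L,
                    pa_method = "random", pa_min_dist = 50,
                    split_fraction = 0.7, tss_cutoff = 0.7,
                    thin_dist = NULL, seed = 1L) {
  frame <- covariates[[1]]
  for (cv in covariates) check_same_frame(frame, cv, "covariates")
  if (!is.null(thin_dist)) occ <- thin_occurrences(occ, thin_dist)
  pres_cells <- unique(xy_to_cell(frame, occ$x, occ$y)$cell)
  pres_cells <- pres_cells[!is.na(pres_cells)]
  if (length(pres_cells) < 3L)
    stop("too few presence cells on the frame", call. = FALSE)
  cell_x <- as.data.frame(lapply(covariates, function(r) as.vector(r$values)))
  mask <- grid_raster(ifelse(is.na(cell_x[[1]]), NA, 0),
                      frame$origin, frame$cell_size)
  pa_sets <- sample_pseudo_absences(mask, occ, n = n_pa, n_sets = n_sets,
                                    method = pa_method,
                                    min_dist = pa_min_dist, seed = seed)
  spec <- enumerate_model_runs(learners, n_sets, n_runs)
  w <- compute_weights(length(pres_cells), n_pa)
  runs <- vector("list", nrow(spec))
  for (k in seq_len(nrow(spec))) {
    pa_cells <- pa_sets[[spec$pa_set[k]]]$cell
    cells <- c(pres_cells, pa_cells)
    y <- c(rep(1L, length(pres_cells)), rep(0L, length(pa_cells)))
    wts <- c(rep(w$presence, length(pres_cells)), rep(w$pa, length(pa_cells)))
    run_seed <- seed + 7919L * k
    sp <- split_train_eval(y, split_fraction, seed = run_seed)
    xx <- cell_x[cells, , drop = FALSE]
    run <- fit_single_model(spec$learner_id[k], xx[sp$train, , drop = FALSE],
                            y[sp$train], wts[sp$train], seed = run_seed)
    ev_scores <- run$predict(xx[sp$eval, , drop = FALSE])
    run$tss <- tss(ev_scores, y[sp$eval])$tss
    run$auc <- auc_roc(ev_scores, y[sp$eval])
    run$pa_set_index <- spec$pa_set[k]
    run$run_index <- spec$run[k]
    p <- rep(NA_real_, nrow(cell_x))
    ok <- !is.na(cell_x[[1]])
    p[ok] <- run$predict(cell_x[ok, , drop = FALSE])
    run$surface <- grid_raster(matrix(p, nrow(frame$values)),
                               frame$origin, frame$cell_size, frame$crs)
    runs[[k]] <- run
  }
  ens <- build_ensemble(runs, frame, tss_cutoff)
  ens$ledger <- data.frame(spec,
                           tss = vapply(runs, `[[`, numeric(1), "tss"),
                           auc = vapply(runs, `[[`, numeric(1), "auc"))
  ens$calibration <- cell_x[pres_cells, , drop = FALSE]
  ens$training_medians <- vapply(cell_x[pres_cells, , drop = FALSE],
                                 stats::median, numeric(1), na.rm = TRUE)
  ens$training_ranges <- lapply(cell_x[pres_cells, , drop = FALSE], range,
                                na.rm = TRUE)
  ens$presence_cells <- pres_cells
  ens
}

#' Project an ensemble onto new covariates
#'
#' Predicts every TSS-passing member on a (possibly future-scenario)
#' covariate stack and averages, yielding the ensemble mean surface under
#' those conditions.
#'
#' @param ensemble An `ensemble_model` from [run_enm()].
#' @param covariates Named list of aligned `grid_raster` layers with the
#'   same variable names as used in fitting.
#' @return A `grid_raster` of mean probabilities.
#' @export
project_ensemble <- function(ensemble, covariates) {
  frame <- covariates[[1]]
  for (cv in covariates) check_same_frame(frame, cv, "covariates")
  cell_x <- as.data.frame(lapply(covariates, function(r) as.vector(r$values)))
  ok <- stats::complete.cases(cell_x)
  acc <- matrix(0, nrow(frame$values), ncol(frame$values))
  for (k in ensemble$passing) {
    p <- rep(NA_real_, nrow(cell_x))
    p[ok] <- ensemble$members[[k]]$predict(cell_x[ok, , drop = FALSE])
    acc <- acc + matrix(p, nrow(frame$values))
  }
  grid_raster(acc / length(ensemble$passing), frame$origin, frame$cell_size,
              frame$crs)
}

#' Evaluation-strip response curve
#'
#' Varies one variable over its observed training range at `n_points`,
#' holding all other variables at their training medians, and reports the
#' ensemble mean prediction at each point.
#'
#' @param ensemble An `ensemble_model` from [run_enm()].
#' @param variable Variable name.
#' @param n_points Number of evaluation points.
#' @return data.frame with `value` and `prediction`.
#' @export
response_curve <- function(ensemble, variable, n_points = 25L) {
  med <- ensemble$training_medians
  if (!variable %in% names(med))
    stop(sprintf("unknown variable '%s'", variable), call. = FALSE)
  rng <- ensemble$training_ranges[[variable]]
  grid <- seq(rng[1], rng[2], length.out = n_points)
  newdata <- as.data.frame(lapply(med, rep, times = n_points))
  newdata[[variable]] <- grid
  preds <- sapply(ensemble$passing, function(k)
    ensemble$members[[k]]$predict(newdata))
  data.frame(value = grid, prediction = rowMeans(as.matrix(preds)))
}
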