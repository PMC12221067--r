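#' Hybrid dipper-throated / grey-wolf feature selection (DGWO)
#'
#' A wrapper selector: agents move in the continuous unit cube, their
#' positions are thresholded into binary feature masks, and each mask is
#' scored by the cross-validated classification error of a reference
#' classifier. Each iteration flips a coin: below the switch threshold the
#' whole swarm takes a grey-wolf siege step guided by the three best agents
#' (alpha, beta, delta); otherwise it takes a dipper-throated flying-bird
#' step with persistent speeds pulled towards the current and global best.
#'
#' @name dgwo
NULL

clip01 <- function(x) {
  y <- pmin(1, pmax(0, x))
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

#' Dipper-throated swimming-bird update
#'
#' `BL(t+1) = BLbest - c1 * |c2 * BLbest - BL|`, clipped to \[0,1\]. The
#' best position is a fixed point when c2 = 1. This is the exploitation
#' move of the pure dipper-throated baseline; the hybrid loop itself only
#' branches between grey-wolf and flying-bird updates.
#'
#' @param position,best numeric vectors of equal length.
#' @param c1,c2 adaptive coefficients.
#' @return Updated position vector.
#' @export
dto_swim_update <- function(position, best, c1, c2) {
  stopifnot(length(position) == length(best))
  clip01(best - c1 * abs(c2 * best - position))
}

#' Dipper-throated flying-bird update
#'
#' `BS(t+1) = c3*BS + c4*r1*(BLbest - BL) + c5*r1*(BLGbest - BL)`;
#' `BL(t+1) = BL + BS(t+1)`, clipped to \[0,1\]. At the global optimum with
#' zero speed the agent stays put.
#'
#' @param position,speed,best,gbest numeric vectors of equal length.
#' @param c3 inertia weight; `c4`, `c5` pull constants; `r1` a draw in
#'   \[0,1\].
#' @param c4,c5,r1 see above.
#' @return List with `position` and `speed`.
#' @export
dto_fly_update <- function(position, speed, best, gbest, c3, c4, c5, r1) {
  stopifnot(length(position) == length(speed))
  new_speed <- c3 * speed + c4 * r1 * (best - position) +
    c5 * r1 * (gbest - position)
  list(position = clip01(position + new_speed), speed = new_speed)
}

#' Grey-wolf siege step
#'
#' Every agent moves to the mean of three candidate positions computed from
#' the alpha, beta and delta leaders: `d_k = |c_k * x_k - x|`,
#' `x_k' = x_k - a_k * d_k`, with `a_k = 2*l*r1 - l` and `c_k = 2*r2` drawn
#' per component, then `x(t+1) = (x1' + x2' + x3')/3`, clipped to \[0,1\].
#' With coincident leaders and l = 0 the whole swarm collapses onto the
#' leader.
#'
#' @param positions n x d matrix of agent positions.
#' @param leaders 3 x d matrix: rows alpha, beta, delta (the three best
#'   agents by fitness).
#' @param l exploration coefficient in \[0, 2\] (shrinks linearly over the
#'   run).
#' @param runif_fn RNG function used for the per-component draws (replace
#'   for deterministic hand checks).
#' @return n x d matrix of updated positions.
#' @export
gwo_step <- function(positions, leaders, l, runif_fn = stats::runif) {
  positions <- as.matrix(positions)
  leaders <- as.matrix(leaders)
  if (nrow(leaders) < 3) stop("gwo_step: need 3 evaluated leaders")
  n <- nrow(positions); d <- ncol(positions)
  acc <- matrix(0, n, d)
  for (k in 1:3) {
    r1 <- matrix(runif_fn(n * d), n, d)
    r2 <- matrix(runif_fn(n * d), n, d)
    a <- 2 * l * r1 - l
    cc <- 2 * r2
    lead <- matrix(leaders[k, ], n, d, byrow = TRUE)
    dist <- abs(cc * lead - positions)
    acc <- acc + (lead - a * dist)
  }
  clip01(acc / 3)
}

#' Threshold a continuous position into a feature mask
#'
#' `mask_j = 1` iff `position_j > threshold` (strict inequality).
#'
#' @param position numeric vector in \[0,1\]^d.
#' @param threshold scalar in (0,1).
#' @return Integer 0/1 vector.
#' @export
binarize_position <- function(position, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("binarize_position: threshold must be in (0,1)")
  }
  as.integer(position > threshold)
}

# Deterministic stratified fold assignment.
stratified_folds <- function(labels, k, seed) {
  if (any(table(labels) < k)) {
    stop("stratified folds: a class has fewer than k = ", k, " members")
  }
  folds <- integer(length(labels))
  rng <- make_rng(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[rng$sample(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Small local RNG so fold shuffling never disturbs the caller's RNG stream.
make_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  env$sample <- function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- sample.int(n)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
  env
}

# Nearest-centroid prediction, columns standardised on the training fold.
nearest_centroid_predict <- function(X_train, y_train, X_test) {
  mu <- colMeans(X_train)
  sd <- apply(X_train, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  Zt <- sweep(sweep(X_train, 2, mu), 2, sd, "/")
  Zs <- sweep(sweep(X_test, 2, mu), 2, sd, "/")
  classes <- sort(unique(y_train))
  cents <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(Zt[y_train == cl, , drop = FALSE])
  }))
  d2 <- sq_dist(Zs, cents)
  classes[max.col(-d2, ties.method = "first")]
}

#' Classification-error fitness of a feature mask
#'
#' Error = 1 - stratified k-fold cross-validated accuracy of the reference
#' classifier on the selected columns (nearest centroid, standardised per
#' training fold, by default; any `evaluator(X_train, y_train, X_test) ->
#' predictions` callback may replace it). The empty mask scores 1.0 by
#' convention. Fold assignment is fixed by `fold_seed`, so the fitness is a
#' deterministic function of (mask, table, seed).
#'
#' @param mask 0/1 vector, one entry per feature column of `table`.
#' @param table a labelled [feature_table()].
#' @param k folds (default 3).
#' @param fold_seed seed fixing the fold assignment.
#' @param evaluator optional classifier callback.
#' @return Scalar error in \[0, 1\].
#' @export
fitness_classification_error <- function(mask, table, k = 3, fold_seed = 1,
                                         evaluator = NULL) {
  y <- ft_labels(table)
  if (is.null(y)) stop("fitness: feature table has no labels")
  if (length(unique(y)) < 2) stop("fitness: labels are single-class")
  X <- ft_values(table)
  if (length(mask) != ncol(X)) {
    stop("fitness: mask length ", length(mask), " != feature count ", ncol(X))
  }
  if (sum(mask) == 0) return(1.0)
  if (is.null(evaluator)) evaluator <- nearest_centroid_predict
  Xs <- X[, mask == 1, drop = FALSE]
  folds <- stratified_folds(y, k, fold_seed)
  wrong <- 0L
  for (f in seq_len(k)) {
    te <- folds == f
    pred <- evaluator(Xs[!te, , drop = FALSE], y[!te], Xs[te, , drop = FALSE])
    wrong <- wrong + sum(pred != y[te])
  }
  wrong / length(y)
}

#' Run the DGWO feature selector
#'
#' Initialises `n_agents` positions uniformly in the unit cube (seeded),
#' then per iteration draws R ~ U(0,1): R below the switch threshold takes
#' a grey-wolf step for the whole swarm, otherwise a flying-bird step with
#' persistent speeds. Coefficients follow the declared schedules (c1 linear
#' 2 to 0, c2 = 2r per draw, c3 linear 0.9 to 0.4, c4 = c5 = 1.5, grey-wolf
#' l linear 2 to 0). Every agent's binarized mask is scored each iteration;
#' fitness ties are broken by fewer selected features, then lower agent
#' index. The result records the best-ever mask and the monotone
#' best-so-far trace. Fully deterministic given (seed, config, table).
#'
#' @param table a labelled [feature_table()].
#' @param config the `dgwo` block of a [pipeline_config()] (or a list of
#'   overrides for it).
#' @param evaluator optional classifier callback (see
#'   [fitness_classification_error()]).
#' @return An object of class `dgwo_selection`: `mask`, `feature_names`,
#'   `best_position`, `best_fitness`, `fitness_trace`, `n_selected`,
#'   `config`.
#' @export
dgwo_select <- function(table, config = pipeline_config()$dgwo,
                        evaluator = NULL) {
  cfg <- utils::modifyList(pipeline_config()$dgwo, as.list(config))
  d <- length(ft_names(table))
  if (d == 0) stop("dgwo_select: no features")
  if (cfg$n_agents < 4) stop("dgwo_select: need at least 4 agents")
  if (cfg$max_iter < 1) stop("dgwo_select: max_iter must be >= 1")
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  set.seed(seed)
  fold_seed <- seed + 104729L  # distinct fixed stream for fold assignment
  fit_of <- function(pos) {
    fitness_classification_error(binarize_position(pos,
                                                   cfg$binarize_threshold),
                                 table, k = cfg$cv_folds,
                                 fold_seed = fold_seed, evaluator = evaluator)
  }
  pos <- matrix(stats::runif(cfg$n_agents * d), cfg$n_agents, d)
  speed <- matrix(0, cfg$n_agents, d)
  fitness <- apply(pos, 1, fit_of)
  nsel <- rowSums(pos > cfg$binarize_threshold)
  rank_order <- function() order(fitness, nsel, seq_along(fitness))
  ord <- rank_order()
  gbest_pos <- pos[ord[1], ]
  gbest_fit <- fitness[ord[1]]
  gbest_nsel <- nsel[ord[1]]
  trace <- numeric(cfg$max_iter)
  for (t in seq_len(cfg$max_iter)) {
    frac <- (t - 1) / max(1, cfg$max_iter - 1)
    c1 <- cfg$c1_start + frac * (cfg$c1_end - cfg$c1_start)
    c3 <- cfg$c3_start + frac * (cfg$c3_end - cfg$c3_start)
    l <- cfg$a_start + frac * (cfg$a_end - cfg$a_start)
    ord <- rank_order()
    R <- stats::runif(1)
    if (R < cfg$switch_threshold) {
      pos <- gwo_step(pos, pos[ord[1:3], , drop = FALSE], l)
    } else {
      best <- pos[ord[1], ]
      r1 <- stats::runif(cfg$n_agents)
      for (i in seq_len(cfg$n_agents)) {
        if (identical(cfg$position_update, "algorithm1")) {
          z <- stats::runif(1); r2 <- stats::runif(1); r3 <- stats::runif(1)
          new_speed <- c3 * speed[i, ] + cfg$c4 * r1[i] * (best - pos[i, ]) +
            cfg$c5 * r1[i] * (gbest_pos - pos[i, ])
          pos[i, ] <- clip01(r1[i] + z * r2 + (1 - z) * r3 + new_speed)
          speed[i, ] <- new_speed
        } else {
          upd <- dto_fly_update(pos[i, ], speed[i, ], best, gbest_pos,
                                c3, cfg$c4, cfg$c5, r1[i])
          pos[i, ] <- upd$position
          speed[i, ] <- upd$speed
        }
      }
    }
    fitness <- apply(pos, 1, fit_of)
    nsel <- rowSums(pos > cfg$binarize_threshold)
    ord <- rank_order()
    better <- fitness[ord[1]] < gbest_fit ||
      (fitness[ord[1]] == gbest_fit && nsel[ord[1]] < gbest_nsel)
    if (better) {
      gbest_pos <- pos[ord[1], ]
      gbest_fit <- fitness[ord[1]]
      gbest_nsel <- nsel[ord[1]]
    }
    trace[t] <- gbest_fit
  }
  mask <- binarize_position(gbest_pos, cfg$binarize_threshold)
  structure(
    list(mask = mask,
         all_features = ft_names(table),
         feature_names = ft_names(table)[mask == 1],
         best_position = gbest_pos,
         best_fitness = gbest_fit,
         fitness_trace = trace,
         n_selected = sum(mask),
         config = cfg),
    class = "dgwo_selection")
}

#' @export
print.dgwo_selection <- function(x, ...) {
  cat("<dgwo_selection> ", x$n_selected, " feature(s) selected | best error ",
      signif(x$best_fitness, 4), "\n", sep = "")
  invisible(x)
}

#' Exhaustive-search oracle over feature masks
#'
#' Enumerates all nonempty masks (feature count must be at most 16) with
#' the same evaluator and fold seed as the selector, returning the minimum;
#' ties resolve to fewer features, then lexicographically smaller mask.
#' Used as the independent optimum against which [dgwo_select()] is scored.
#'
#' @param table a labelled [feature_table()].
#' @param k,fold_seed,evaluator as in [fitness_classification_error()].
#' @return List with `mask` and `fitness`.
#' @export
exhaustive_best_mask <- function(table, k = 3, fold_seed = 1,
                                 evaluator = NULL) {
  d <- length(ft_names(table))
  if (d > 16) stop("exhaustive_best_mask: refusing d = ", d, " > 16")
  n_masks <- 2^d - 1
  masks <- matrix(0L, n_masks, d)
  for (j in seq_len(d)) {
    masks[, j] <- bitwAnd(seq_len(n_masks), bitwShiftL(1L, j - 1L)) > 0L
  }
  fits <- apply(masks, 1, fitness_classification_error, table = table,
                k = k, fold_seed = fold_seed, evaluator = evaluator)
  key <- apply(masks, 1, paste, collapse = "")
  ord <- order(fits, rowSums(masks), key)
  list(mask = masks[ord[1], ], fitness = fits[ord[1]])
}
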