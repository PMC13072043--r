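#' Particle-swarm hyperparameter tuning
#'
#' Canonical global-best PSO over the three GCN hyperparameters
#' (hidden dimension, learning rate, dropout): velocities start at zero,
#' each iteration applies
#' `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` element-wise with
#' fresh uniform `r1, r2`, positions are hard-clipped to the bounds and the
#' hidden dimension is rounded to an integer. Fitness is the validation
#' accuracy of a short training run; the search stops after the iteration
#' cap or when the global best has stagnated (improvement below `delta`)
#' for `stagnation_iters` consecutive iterations.
#'
#' @name pso_tuner
NULL

#' Hyperparameter search bounds
#'
#' Defaults: hidden units `[128, 768]` (integer), Adam learning rate
#' `[1e-4, 1e-2]`, dropout `[0, 0.5]`.
#'
#' @param hid,lr,p length-2 numeric `c(lower, upper)` intervals.
#' @return a `search_bounds` object (3 x 2 matrix, rows hid/lr/p).
#' @export
search_bounds <- function(hid = c(128, 768), lr = c(1e-4, 1e-2),
                          p = c(0, 0.5)) {
  b <- rbind(hid = hid, lr = lr, p = p)
  if (any(b[, 1] >= b[, 2])) stopf("each lower bound must be < upper bound")
  structure(b, class = c("search_bounds", "matrix"))
}

#' Swarm configuration
#'
#' Defaults follow the reference tuning recipe: 30 particles, 50 iterations,
#' inertia 0.7, cognitive and social coefficients 1.5, stagnation tolerance
#' 1e-4 over 5 iterations, 5-epoch short training runs, seed 42.
#'
#' @param n_particles swarm size (>= 2).
#' @param max_iters iteration cap.
#' @param w inertia weight in (0, 1).
#' @param c1,c2 cognitive / social coefficients (> 0).
#' @param stagnation_delta minimal global-best improvement counted as
#'   progress.
#' @param stagnation_iters consecutive stagnant iterations before stopping.
#' @param fitness_epochs epochs of the short training run (E_short).
#' @param fitness_metric `"best"` epoch validation accuracy within the short
#'   run (default) or `"last"`.
#' @param seed master seed.
#' @return a `swarm_config` list.
#' @export
swarm_config <- function(n_particles = 30L, max_iters = 50L, w = 0.7,
                         c1 = 1.5, c2 = 1.5, stagnation_delta = 1e-4,
                         stagnation_iters = 5L, fitness_epochs = 5L,
                         fitness_metric = c("best", "last"), seed = 42L) {
  if (n_particles < 2L) stopf("need at least 2 particles")
  if (w <= 0 || w >= 1) stopf("inertia w must lie in (0, 1)")
  if (c1 <= 0 || c2 <= 0) stopf("c1 and c2 must be > 0")
  structure(list(n_particles = as.integer(n_particles),
                 max_iters = as.integer(max_iters), w = w, c1 = c1, c2 = c2,
                 stagnation_delta = stagnation_delta,
                 stagnation_iters = as.integer(stagnation_iters),
                 fitness_epochs = as.integer(fitness_epochs),
                 fitness_metric = match.arg(fitness_metric),
                 seed = as.integer(seed)), class = "swarm_config")
}

.clip_round <- function(x, bounds) {
  x <- pmin(pmax(x, bounds[, 1]), bounds[, 2])
  x[1] <- round(x[1])  # hid integral
  x
}

#' Initialize the swarm
#'
#' Positions uniform within bounds (hid rounded), all velocities zero,
#' personal bests at the initial positions; deterministic given the seed.
#'
#' @param bounds a [search_bounds()].
#' @param cfg a [swarm_config()].
#' @return `swarm_state`: `positions`, `velocities` (n x 3 matrices),
#'   `pbest`, `pbest_val`.
#' @export
init_swarm <- function(bounds, cfg) {
  n <- cfg$n_particles
  pos <- with_seed(derive_seed(cfg$seed, 8L), {
    sapply(1:3, function(j) stats::runif(n, bounds[j, 1], bounds[j, 2]))
  })
  pos[, 1] <- round(pos[, 1])
  colnames(pos) <- rownames(bounds)
  structure(list(positions = pos, velocities = pos * 0, pbest = pos,
                 pbest_val = rep(NA_real_, n)), class = "swarm_state")
}

#' One particle update
#'
#' Velocity and position update of the canonical PSO recurrence with hard
#' clipping to the bounds and integral hidden dimension. `r1`/`r2` default
#' to fresh element-wise uniforms from the current RNG stream.
#'
#' @param position,velocity,pbest numeric 3-vectors.
#' @param gbest global best position.
#' @param cfg a [swarm_config()].
#' @param bounds a [search_bounds()].
#' @param r1,r2 optional uniform 3-vectors (for deterministic tests).
#' @return list `position`, `velocity`.
#' @export
update_particle <- function(position, velocity, pbest, gbest, cfg, bounds,
                            r1 = stats::runif(3), r2 = stats::runif(3)) {
  v <- cfg$w * velocity + cfg$c1 * r1 * (pbest - position) +
    cfg$c2 * r2 * (gbest - position)
  x <- .clip_round(position + v, bounds)
  list(position = x, velocity = v)
}

#' Fitness of one hyperparameter candidate
#'
#' Trains the GCN with `(hid, lr, p)` for `fitness_epochs` epochs under a
#' fixed derived seed and returns validation accuracy in `[0, 1]` (best
#' epoch within the short run by default). Training divergence yields
#' fitness 0 with a warning so the search continues.
#'
#' @param position numeric 3-vector `(hid, lr, p)`.
#' @param data a `graph_dataset` with a validation mask.
#' @param cfg a [swarm_config()].
#' @param eval_seed training seed for this evaluation (default derived from
#'   `cfg$seed`).
#' @return validation accuracy.
#' @export
evaluate_fitness <- function(position, data, cfg, eval_seed = NULL) {
  eval_seed <- eval_seed %||% derive_seed(cfg$seed, 9L)
  tc <- train_config(learning_rate = position[2],
                     max_epochs = cfg$fitness_epochs,
                     patience = cfg$fitness_epochs,  # no early stop in E_short
                     seed = eval_seed)
  res <- tryCatch({
    p0 <- init_params(ncol(data$X), as.integer(round(position[1])),
                      length(data$class_names), dropout_p = position[3],
                      seed = eval_seed)
    train_gcn(data, p0, tc)
  }, error = function(e) {
    warnf("fitness evaluation failed (%s); candidate penalized",
          conditionMessage(e))
    NULL
  })
  if (is.null(res)) return(0)
  if (cfg$fitness_metric == "best") res$best_val_acc
  else res$history$val_acc[nrow(res$history)]
}

#' Run the particle-swarm search
#'
#' @param fitness function `position -> scalar` to maximize. For GCN tuning
#'   use [make_gcn_fitness()] or [tune_gcn()].
#' @param bounds a [search_bounds()].
#' @param cfg a [swarm_config()].
#' @return list `best_position`, `best_fitness`, `trace` (data.frame with
#'   iteration 0 = initial evaluation, gbest position and value per
#'   iteration), `stopped_iteration` (NA if the cap was reached),
#'   `iterations_run`.
#' @export
optimize_swarm <- function(fitness, bounds, cfg = swarm_config()) {
  sw <- init_swarm(bounds, cfg)
  n <- cfg$n_particles
  sw$pbest_val <- vapply(seq_len(n),
                         function(i) fitness(sw$positions[i, ]), numeric(1))
  gi <- which.max(sw$pbest_val)
  gbest <- sw$positions[gi, ]; gbest_val <- sw$pbest_val[gi]
  trace <- data.frame(iteration = 0L, hid = gbest[1], lr = gbest[2],
                      p = gbest[3], gbest_val = gbest_val)
  stagnant <- 0L; stopped <- NA_integer_; iters <- 0L
  with_seed(derive_seed(cfg$seed, 10L), {
    for (t in seq_len(cfg$max_iters)) {
      if (stagnant >= cfg$stagnation_iters) { stopped <- t; break }
      prev <- gbest_val
      for (i in seq_len(n)) {
        up <- update_particle(sw$positions[i, ], sw$velocities[i, ],
                              sw$pbest[i, ], gbest, cfg, bounds)
        sw$positions[i, ] <- up$position
        sw$velocities[i, ] <- up$velocity
        val <- fitness(up$position)
        if (val > sw$pbest_val[i]) {
          sw$pbest[i, ] <- up$position; sw$pbest_val[i] <- val
          if (val > gbest_val) { gbest <- up$position; gbest_val <- val }
        }
      }
      iters <- t
      trace <- rbind(trace, data.frame(iteration = t, hid = gbest[1],
                                       lr = gbest[2], p = gbest[3],
                                       gbest_val = gbest_val))
      if (gbest_val - prev < cfg$stagnation_delta) {
        stagnant <- stagnant + 1L
      } else stagnant <- 0L
    }
  })
  list(best_position = gbest, best_fitness = gbest_val, trace = trace,
       stopped_iteration = stopped, iterations_run = iters)
}

#' Deterministic GCN fitness closure for the swarm
#'
#' Each candidate is trained under a seed derived from the swarm seed and
#' the rounded candidate position, so identical positions always receive
#' identical fitness and the global-best trace is exactly monotone.
#'
#' @param data a `graph_dataset`.
#' @param cfg a [swarm_config()].
#' @return function `position -> validation accuracy`.
#' @export
make_gcn_fitness <- function(data, cfg) {
  function(position) {
    key <- sum(round(c(position[1], position[2] * 1e6,
                       position[3] * 1e4))) %% 65521
    evaluate_fitness(position, data, cfg,
                     eval_seed = derive_seed(cfg$seed, 11L + key))
  }
}

#' Tune GCN hyperparameters on a graph dataset
#'
#' @param data a `graph_dataset`.
#' @param bounds a [search_bounds()].
#' @param cfg a [swarm_config()].
#' @return as [optimize_swarm()].
#' @export
tune_gcn <- function(data, bounds = search_bounds(), cfg = swarm_config()) {
  optimize_swarm(make_gcn_fitness(data, cfg), bounds, cfg)
}

#' Write a swarm trace as JSON lines
#' @param result an [optimize_swarm()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_swarm_trace <- function(result, path) {
  lines <- vapply(seq_len(nrow(result$trace)), function(i) {
    jsonlite::toJSON(as.list(result$trace[i, ]), auto_unbox = TRUE,
                     digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
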