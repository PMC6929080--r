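#' Parameter bounds for differential evolution
#'
#' @param lower,upper Numeric vectors of per-dimension limits.
#' @param step Discretization grid per dimension (0 = continuous). Values
#'   are snapped to `lower + k * step`.
#' @return A `de_bounds` list.
#' @export
de_bounds <- function(lower, upper, step = 0) {
  d <- length(lower)
  if (length(upper) != d) stop("lower/upper length mismatch")
  if (any(upper < lower)) stop("upper must be >= lower")
  step <- rep_len(step, d)
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 step = as.numeric(step), d = d), class = "de_bounds")
}

.de_snap <- function(x, bounds) {
  x <- pmin(pmax(x, bounds$lower), bounds$upper)
  g <- bounds$step > 0
  if (any(g)) {
    k <- round((x[g] - bounds$lower[g]) / bounds$step[g])
    x[g] <- pmin(bounds$lower[g] + k * bounds$step[g], bounds$upper[g])
  }
  x
}

#' Initialize a differential-evolution population
#'
#' Each of the `N` vectors is drawn uniformly per dimension within the
#' bounds (on the discretization grid when one is set).
#'
#' @param bounds A [de_bounds()].
#' @param N Population size, must be greater than 4.
#' @param seed RNG seed; the state is fully reproducible.
#' @return A `de_state`: `population` (N x D matrix), `fitness` (NA until
#'   evaluated), `generation`.
#' @export
de_init <- function(bounds, N, seed = 1L) {
  if (N <= 4) stop("population size must be greater than four")
  draw_one <- function() {
    x <- numeric(bounds$d)
    for (j in seq_len(bounds$d)) {
      if (bounds$step[j] > 0) {
        # uniform over the grid points (endpoint-snapping a continuous draw
        # would halve the probability of the boundary values)
        ng <- floor((bounds$upper[j] - bounds$lower[j]) / bounds$step[j])
        k <- sample.int(ng + 1L, 1L) - 1L
        x[j] <- min(bounds$lower[j] + k * bounds$step[j], bounds$upper[j])
      } else {
        x[j] <- stats::runif(1, bounds$lower[j], bounds$upper[j])
      }
    }
    x
  }
  pop <- with_local_seed(seed, function() t(replicate(N, draw_one())))
  if (bounds$d == 1L) pop <- matrix(pop, ncol = 1L)
  structure(list(population = pop, fitness = rep(NA_real_, N),
                 generation = 0L, bounds = bounds, N = N),
            class = "de_state")
}

#' Mutation: donor vector
#'
#' `v = x_{r1} + F * (x_{r2} - x_{r3})` with `r1, r2, r3` distinct and
#' different from the target index, clipped to bounds and snapped to the
#' grid.
#'
#' @param state A `de_state`.
#' @param i Target index.
#' @param F Mutation factor in `[0, 2]`.
#' @param r Optional `c(r1, r2, r3)` (drawn at random when omitted).
#' @return Donor vector.
#' @export
de_mutate <- function(state, i, F = 0.8, r = NULL) {
  if (F < 0 || F > 2) stop("F must be in [0, 2]")
  if (state$N < 5) stop("population too small for mutation")
  if (is.null(r)) r <- sample(setdiff(seq_len(state$N), i), 3L)
  if (length(unique(c(r, i))) != 4L) stop("r1, r2, r3 must be distinct and != i")
  p <- state$population
  .de_snap(p[r[1], ] + F * (p[r[2], ] - p[r[3], ]), state$bounds)
}

#' Recombination: trial vector
#'
#' Per dimension the donor component is taken with probability `CR`; the
#' dimension `Irand` always comes from the donor so the trial never equals
#' the target.
#'
#' @param target,donor Parameter vectors.
#' @param CR Crossover probability in `[0, 1]`.
#' @param Irand Forced donor dimension (random when omitted).
#' @return Trial vector.
#' @export
de_crossover <- function(target, donor, CR = 0.9, Irand = NULL) {
  if (CR < 0 || CR > 1) stop("CR must be in [0, 1]")
  D <- length(target)
  if (is.null(Irand)) Irand <- sample.int(D, 1L)
  take <- stats::runif(D) <= CR
  take[Irand] <- TRUE
  ifelse(take, donor, target)
}

#' Selection: greedy survivor
#'
#' The trial replaces the target iff its fitness is less than or equal to
#' the target's. A failing fitness evaluation counts as `+Inf`.
#'
#' @param target,trial Parameter vectors.
#' @param fitness_fn Function vector -> scalar.
#' @param f_target Optional cached target fitness.
#' @return List `vector`, `fitness`, `accepted`.
#' @export
de_select <- function(target, trial, fitness_fn, f_target = NULL) {
  safe <- function(x) tryCatch({
    v <- fitness_fn(x); if (!is.finite(v)) Inf else v
  }, error = function(e) Inf)
  if (is.null(f_target)) f_target <- safe(target)
  f_trial <- safe(trial)
  if (f_trial <= f_target)
    list(vector = trial, fitness = f_trial, accepted = TRUE)
  else
    list(vector = target, fitness = f_target, accepted = FALSE)
}

#' Run differential evolution
#'
#' Classic DE/rand/1/bin with greedy selection on a bounded, optionally
#' discretized search space. Stops at `max_gen` generations or after
#' `stagnation_gens` generations without a best-fitness improvement larger
#' than `stagnation_tol`.
#'
#' @param fitness_fn Function vector -> scalar (lower is better).
#' @param bounds A [de_bounds()].
#' @param N Population size (> 4). Default follows the published
#'   configuration of 150 individuals.
#' @param F Mutation factor. @param CR Crossover probability.
#' @param max_gen Generation cap (default 200).
#' @param seed RNG seed; runs are fully reproducible.
#' @param stagnation_gens,stagnation_tol Early-stop rule.
#' @return List: `best` vector, `best_fitness`, `history` (best fitness per
#'   generation, non-increasing), `population`, `generations`.
#' @export
run_de <- function(fitness_fn, bounds, N = 150, F = 0.8, CR = 0.9,
                   max_gen = 200, seed = 1L,
                   stagnation_gens = 30, stagnation_tol = 1e-3) {
  state <- de_init(bounds, N, seed)
  with_local_seed(seed + 1L, function() {
    safe <- function(x) tryCatch({
      v <- fitness_fn(x); if (!is.finite(v)) Inf else v
    }, error = function(e) Inf)
    fit <- apply(state$population, 1L, safe)
    history <- numeric(0)
    since_improve <- 0L
    for (g in seq_len(max_gen)) {
      for (i in seq_len(N)) {
        donor <- de_mutate(state, i, F)
        trial <- de_crossover(state$population[i, ], donor, CR)
        f_trial <- safe(trial)
        if (f_trial <= fit[i]) {
          state$population[i, ] <- trial
          fit[i] <- f_trial
        }
      }
      best_now <- min(fit)
      if (g > 1 && (history[g - 1] - best_now) > stagnation_tol)
        since_improve <- 0L
      else if (g > 1) since_improve <- since_improve + 1L
      history <- c(history, best_now)
      if (since_improve >= stagnation_gens) break
    }
    b <- which.min(fit)
    list(best = state$population[b, ], best_fitness = fit[b],
         history = history, population = state$population,
         generations = length(history))
  })
}

#' Search space of the ten tunable pipeline parameters
#'
#' Order: median_k, loc_window_up, loc_window_down, snake_alpha, snake_beta,
#' snake_edge_weight, canny_high, canny_low, canny_kernel, tophat_kernel.
#' Kernels move on odd grids, Canny limits in steps of 10, the edge weight
#' in steps of 0.1.
#'
#' @return A [de_bounds()] for the 10-dimensional space.
#' @export
pipeline_bounds <- function() {
  de_bounds(
    lower = c(3,  3,  3,  1,   1,   0.1, 10,  10,  3,  3),
    upper = c(31, 15, 15, 100, 100, 5,   250, 250, 7,  31),
    step  = c(2,  2,  2,  1,   1,   0.1, 10,  10,  2,  2))
}

#' Build a pipeline configuration from a DE parameter vector
#'
#' @param x Length-10 vector in the [pipeline_bounds()] order.
#' @param base Configuration supplying the non-tuned parameters.
#' @return A full configuration list; `canny_low`/`canny_high` are swapped
#'   if needed to keep `low <= high`.
#' @export
config_from_vector <- function(x, base = default_config()) {
  stopifnot(length(x) == 10)
  base$median_k <- as.integer(x[1])
  base$loc_window_up <- x[2]
  base$loc_window_down <- x[3]
  base$snake_alpha <- x[4]
  base$snake_beta <- x[5]
  base$snake_edge_weight <- x[6]
  hi <- x[7]; lo <- x[8]
  base$canny_high <- max(hi, lo); base$canny_low <- min(hi, lo)
  base$canny_kernel <- as.integer(x[9])
  base$tophat_kernel <- as.integer(x[10])
  base
}

#' Segmentation fitness of a configuration on a ground-truthed dataset
#'
#' Runs the full pipeline under `config` on every image and scores the mean
#' per-image MAE of all matched curves (lens outer, cornea, and the inner
#' limit when both sides have one), adding a penalty of 100 px for each
#' misclassified layer count or failed image. Lower is better; failures are
#' penalized, never raised.
#'
#' @param config Pipeline configuration (or length-10 vector, see
#'   [config_from_vector()]).
#' @param dataset List of `list(image, truth)` as from [generate_dataset()].
#' @param penalty Penalty per misclassification/failure, px.
#' @return Scalar fitness.
#' @export
fitness_segmentation <- function(config, dataset, penalty = 100) {
  if (length(dataset) == 0L) stop("dataset must be non-empty")
  if (is.numeric(config) && is.null(names(config)))
    config <- config_from_vector(config)
  per_image <- vapply(dataset, function(item) {
    res <- tryCatch(oct_segment(item$image, config = config),
                    error = function(e) NULL)
    if (is.null(res)) return(penalty)
    score <- 0
    truth <- item$truth
    if (res$layers$layer_count != truth$layer_count) score <- score + penalty
    pairs <- list(c("scl_outer", "scl_outer"), c("cornea", "cornea"))
    if (!is.null(res$layers$scl_inner) && !is.null(truth$curves$scl_inner))
      pairs <- c(pairs, list(c("scl_inner", "scl_inner")))
    maes <- vapply(pairs, function(p) {
      pr <- res$layers[[p[1]]]; tr <- truth$curves[[p[2]]]
      if (is.null(pr) || is.null(tr)) return(penalty)
      e <- tryCatch(curve_error(pr, tr), error = function(e) NULL)
      if (is.null(e)) penalty else e["mae"]
    }, numeric(1))
    score + mean(maes)
  }, numeric(1))
  mean(per_image)
}
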