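#' Define the discrete (K, PF) search space
#'
#' The grey wolf optimizer searches a finite grid: integer mode counts
#' `k_min..k_max` in steps of `k_step`, penalty factors `pf_min..pf_max` in
#' steps of `pf_step`. The defaults match the standard per-epoch EEG setting
#' (K from 2 to 6 in steps of 1, PF from 10 to 5000 in steps of 10).
#'
#' @param k_min,k_max,k_step Integer bounds and step for the mode count.
#' @param pf_min,pf_max,pf_step Bounds and step for the penalty factor.
#' @return A list of class `gwo_search_space`.
#' @export
gwo_search_space <- function(k_min = 2, k_max = 6, k_step = 1,
                             pf_min = 10, pf_max = 5000, pf_step = 10) {
  if (k_min > k_max || pf_min > pf_max) abort("min must not exceed max.")
  if (k_step <= 0 || pf_step <= 0) abort("steps must be positive.")
  structure(list(k_min = k_min, k_max = k_max, k_step = k_step,
                 pf_min = pf_min, pf_max = pf_max, pf_step = pf_step),
            class = "gwo_search_space")
}

space_grid <- function(space) {
  list(k = seq(space$k_min, space$k_max, by = space$k_step),
       pf = seq(space$pf_min, space$pf_max, by = space$pf_step))
}

# clamp to bounds, then snap to the nearest grid point
snap_position <- function(position, space) {
  k <- min(max(position[1], space$k_min), space$k_max)
  k <- space$k_min + round((k - space$k_min) / space$k_step) * space$k_step
  pf <- min(max(position[2], space$pf_min), space$pf_max)
  pf <- space$pf_min + round((pf - space$pf_min) / space$pf_step) * space$pf_step
  c(min(k, space$k_max), min(pf, space$pf_max))
}

#' Linearly decaying exploration coefficient
#'
#' The scalar `a` controlling the exploration/exploitation balance decreases
#' linearly from 2 (first iteration) to 0 (last iteration).
#'
#' @param iteration 0-based iteration index.
#' @param n_iter Total number of iterations.
#' @return `2 * (1 - iteration / (n_iter - 1))`; 2 when `n_iter` is 1.
#' @export
gwo_coefficient_a <- function(iteration, n_iter) {
  if (any(iteration < 0) || any(iteration >= n_iter)) {
    abort("`iteration` must satisfy 0 <= iteration < n_iter.")
  }
  if (n_iter == 1) return(rep(2, length(iteration)))
  2 * (1 - iteration / (n_iter - 1))
}

#' Leader-guided position update
#'
#' Proposes a new position for one wolf from the three leaders: per leader L
#' and dimension, with fresh uniform draws `r1, r2`, the coefficients are
#' `A = a * (2 r1 - 1)` and `C = 2 r2`; the guided position is
#' `X_L' = X_L - A * |C * X_L - X|`, and the candidate is the centroid of the
#' three guided positions, clamped to the bounds and snapped to the grid.
#' Uses the current RNG stream; seed at the caller for reproducibility.
#'
#' @param position Numeric `c(k, pf)` current position.
#' @param leaders 3 x 2 matrix with rows alpha, beta, delta and columns
#'   (k, pf).
#' @param a Exploration coefficient in `[0, 2]` (see [gwo_coefficient_a()]).
#' @param space A [gwo_search_space()].
#' @return Numeric `c(k, pf)` on the grid.
#' @export
gwo_update_position <- function(position, leaders, a, space) {
  leaders <- as.matrix(leaders)
  stopifnot(nrow(leaders) == 3, ncol(leaders) == 2)
  guided <- matrix(0, 3, 2)
  for (l in 1:3) {
    for (d in 1:2) {
      r1 <- stats::runif(1)
      r2 <- stats::runif(1)
      A <- a * (2 * r1 - 1)
      C <- 2 * r2
      D <- abs(C * leaders[l, d] - position[d])
      guided[l, d] <- leaders[l, d] - A * D
    }
  }
  snap_position(colMeans(guided), space)
}

#' Grey wolf optimizer over a (K, PF) grid
#'
#' Minimizes `objective(k, pf)` over the discrete search space by the grey
#' wolf optimizer: `n_wolves` candidate solutions are initialized uniformly
#' on the grid; each iteration, the three best solutions so far (alpha, beta,
#' delta) guide every wolf's proposed move ([gwo_update_position()]) with the
#' linearly decaying coefficient of [gwo_coefficient_a()]. With
#' `greedy = TRUE` (default) a wolf moves only when the proposal improves its
#' fitness; the canonical always-move variant is available with
#' `greedy = FALSE`. The returned best is the argmin over every evaluation
#' ever made, including rejected proposals.
#'
#' Objective values are memoized per grid position (the objective must be
#' deterministic given a position); failed evaluations are logged and the
#' proposing wolf keeps its previous position.
#'
#' @param objective Function of `(k, pf)` returning a scalar to minimize.
#' @param space A [gwo_search_space()].
#' @param n_wolves Pack size (>= 4; default 20).
#' @param n_iter Number of optimization loops (default 20).
#' @param seed Integer seed for full reproducibility.
#' @param greedy Accept a move only when it improves the wolf's fitness.
#' @param memoize Cache objective values per grid position.
#' @return An object of class `gwo`: list with `best_k`, `best_pf`,
#'   `best_fitness`, `trace` (tibble: iteration, wolf, rank, k, pf, fitness;
#'   iteration 0 is the initialization), `n_evaluations`,
#'   `converged_iteration` (first iteration attaining the final best).
#' @examples
#' g <- gwo_minimize(function(k, pf) (k - 4)^2 + ((pf - 2500) / 10)^2,
#'                   gwo_search_space(), seed = 1)
#' glance(g)
#' @export
gwo_minimize <- function(objective, space = gwo_search_space(),
                         n_wolves = 20, n_iter = 20, seed = NULL,
                         greedy = TRUE, memoize = TRUE) {
  if (n_wolves < 4) abort("`n_wolves` must be at least 4 (three leaders plus followers).")
  if (n_iter < 1) abort("`n_iter` must be at least 1.")
  run <- function() gwo_run(objective, space, n_wolves, n_iter, greedy, memoize)
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$seed <- seed
  out
}

gwo_run <- function(objective, space, n_wolves, n_iter, greedy, memoize) {
  grid <- space_grid(space)
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  best <- list(k = NA_real_, pf = NA_real_, fitness = Inf)
  n_failed <- 0L

  evaluate <- function(pos) {
    key <- paste(pos[1], pos[2], sep = "|")
    if (memoize && !is.null(cache[[key]])) return(cache[[key]])
    val <- tryCatch(objective(pos[1], pos[2]),
                    error = function(e) NA_real_)
    n_evals <<- n_evals + 1L
    if (!is.finite(val)) {
      n_failed <<- n_failed + 1L
      val <- NA_real_
    } else if (val < best$fitness) {
      best <<- list(k = pos[1], pf = pos[2], fitness = val)
    }
    if (memoize) cache[[key]] <- val
    val
  }

  # seeded-uniform initialization on the grid
  pos <- cbind(
    grid$k[sample.int(length(grid$k), n_wolves, replace = TRUE)],
    grid$pf[sample.int(length(grid$pf), n_wolves, replace = TRUE)])
  fitness <- apply(pos, 1, evaluate)
  fitness[is.na(fitness)] <- Inf

  rank_wolves <- function(fitness) {
    ord <- order(fitness, seq_along(fitness))  # ties by earlier wolf index
    ranks <- rep("omega", length(fitness))
    ranks[ord[1:3]] <- c("alpha", "beta", "delta")
    list(ord = ord, ranks = ranks)
  }
  rk <- rank_wolves(fitness)

  trace <- vector("list", n_iter + 1)
  record <- function(iteration, rk) {
    tibble::tibble(iteration = iteration, wolf = seq_len(n_wolves),
                   rank = rk$ranks, k = pos[, 1], pf = pos[, 2],
                   fitness = fitness)
  }
  trace[[1]] <- record(0L, rk)
  best_history <- numeric(n_iter + 1)
  best_history[1] <- best$fitness

  for (i in seq_len(n_iter)) {
    a <- gwo_coefficient_a(i - 1, n_iter)
    leaders <- pos[rk$ord[1:3], , drop = FALSE]
    for (w in seq_len(n_wolves)) {
      cand <- gwo_update_position(pos[w, ], leaders, a, space)
      val <- evaluate(cand)
      accept <- !is.na(val) && (!greedy || val < fitness[w])
      if (accept) {
        pos[w, ] <- cand
        fitness[w] <- val
      }
    }
    rk <- rank_wolves(fitness)
    trace[[i + 1]] <- record(i, rk)
    best_history[i + 1] <- best$fitness
  }

  structure(list(
    best_k = best$k, best_pf = best$pf, best_fitness = best$fitness,
    trace = dplyr::bind_rows(trace),
    n_evaluations = n_evals,
    n_failed = n_failed,
    converged_iteration = which(best_history == best$fitness)[1] - 1L,
    space = space, n_wolves = n_wolves, n_iter = n_iter,
    greedy = greedy), class = "gwo")
}

#' @export
print.gwo <- function(x, ...) {
  cat(sprintf(
    "<gwo> best K = %g, PF = %g, fitness = %.7f (%d evaluations, %d wolves x %d loops)\n",
    x$best_k, x$best_pf, x$best_fitness, x$n_evaluations, x$n_wolves, x$n_iter))
  invisible(x)
}

#' @describeIn gwo_minimize Full per-iteration trace as a tibble.
#' @param x A `gwo` object.
#' @param ... Unused.
#' @export
tidy.gwo <- function(x, ...) x$trace

#' @describeIn gwo_minimize One-row summary of the optimization.
#' @export
glance.gwo <- function(x, ...) {
  tibble::tibble(best_k = x$best_k, best_pf = x$best_pf,
                 best_fitness = x$best_fitness,
                 n_evaluations = x$n_evaluations,
                 converged_iteration = x$converged_iteration)
}

#' Convergence accounting of a GWO run
#'
#' Expresses the alpha leader's K, PF and fitness at every iteration as a
#' percentage of their final converged values (100% once converged), the
#' standard way to tabulate how early each quantity settles.
#'
#' @param x A `gwo` object.
#' @return Tibble with columns `iteration`, `k`, `pf`, `fitness`,
#'   `k_pct`, `pf_pct`, `fitness_pct`.
#' @export
gwo_convergence <- function(x) {
  lead <- dplyr::filter(x$trace, .data$rank == "alpha")
  final <- dplyr::slice_tail(lead, n = 1)
  dplyr::transmute(lead,
    iteration = .data$iteration,
    k = .data$k, pf = .data$pf, fitness = .data$fitness,
    k_pct = 100 * .data$k / final$k,
    pf_pct = 100 * .data$pf / final$pf,
    fitness_pct = 100 * .data$fitness / final$fitness)
}

#' @describeIn gwo_minimize Per-wolf trajectories of K, PF and fitness.
#' @param object A `gwo` object.
#' @export
autoplot.gwo <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace, cols = c("k", "pf", "fitness"),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, levels = c("k", "pf", "fitness"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     group = .data$wolf,
                                     colour = .data$rank == "omega")) +
    ggplot2::geom_line(alpha = 0.5, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "grey60", `FALSE` = "firebrick")) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Grey wolf optimizer trajectories")
}
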