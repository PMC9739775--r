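# The three network trainers: BFGS with Armijo backtracking, multistart
# global optimization, and a modified real-coded genetic algorithm with
# tournament selection, arithmetic crossover, annealed non-uniform
# mutation, a trial-point step and periodic local search.

#' Armijo line-search parameters
#'
#' @param s initial trial step (> 0).
#' @param lambda backtracking factor in (0, 1).
#' @param sigma sufficient-decrease constant in (0, 1).
#' @param max_backtracks maximum number of trial steps.
#' @return an `armijo_params` list.
#' @export
armijo_params <- function(s = 1, lambda = 0.5, sigma = 1e-4,
                          max_backtracks = 50L) {
  if (s <= 0) stop("s must be positive")
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  if (sigma <= 0 || sigma >= 1) stop("sigma must be in (0, 1)")
  structure(list(s = s, lambda = lambda, sigma = sigma,
                 max_backtracks = as.integer(max_backtracks)),
            class = "armijo_params")
}

linesearch_error <- function(msg) {
  stop(errorCondition(msg, class = c("epiwindow_linesearch_error", "error")))
}

#' Armijo backtracking line search
#'
#' Returns the first step in the sequence `s, s*lambda, s*lambda^2, ...`
#' satisfying the sufficient-decrease condition
#' `f(x) - f(x + a*d) >= -sigma * a * t(g) %*% d`.
#'
#' @param f objective function.
#' @param xk current point.
#' @param gk gradient at `xk`.
#' @param dk descent direction (`t(gk) %*% dk < 0` required).
#' @param params an [armijo_params()].
#' @param fk `f(xk)`, recomputed when omitted.
#' @return list with `step`, `f_new` and the number of `trials`.
#' @export
armijo_step <- function(f, xk, gk, dk, params = armijo_params(),
                        fk = f(xk)) {
  slope <- sum(gk * dk)
  if (slope >= 0) stop("not a descent direction: t(g) %*% d = ", slope)
  a <- params$s
  for (trial in seq_len(params$max_backtracks)) {
    f_new <- f(xk + a * dk)
    if (is.finite(f_new) && (fk - f_new) >= -params$sigma * a * slope) {
      return(list(step = a, f_new = f_new, trials = trial))
    }
    a <- a * params$lambda
  }
  linesearch_error(sprintf(
    "Armijo line search failed after %d backtracks (slope %.3g)",
    params$max_backtracks, slope))
}

#' BFGS update of the Hessian approximation
#'
#' `B+ = B + y y' / (y's) - B s s' B / (s' B s)`, which forces the
#' secant equation `B+ s = y` and preserves symmetric positive
#' definiteness whenever the curvature condition `s'y > 0` holds. When
#' the curvature condition fails the update is skipped (damped-update
#' safeguard) and `B` is returned unchanged.
#'
#' @param B current symmetric positive-definite approximation.
#' @param s step vector `x_{k+1} - x_k`.
#' @param y gradient difference `g_{k+1} - g_k`.
#' @return the updated matrix.
#' @export
bfgs_update <- function(B, s, y) {
  sy <- sum(s * y)
  if (sy <= 0) return(B)
  Bs <- as.vector(B %*% s)
  sBs <- sum(s * Bs)
  if (sBs <= 0) return(B)
  B + tcrossprod(y) / sy - tcrossprod(Bs) / sBs
}

#' Quasi-Newton minimization (BFGS with Armijo line search)
#'
#' Iterates `x_{k+1} = x_k + a_k d_k` with direction from
#' `B_k d_k = -g_k` (solved by Cholesky factorization rather than by
#' forming the inverse) and the Armijo step. `B_0` is the identity.
#' Stops when the Euclidean gradient norm falls below `grad_tol` or
#' after `max_iter` iterations; the objective is monotonically
#' non-increasing. If bounds are supplied, iterates are projected onto
#' the box. Line-search failure returns the best point found with
#' `converged = FALSE`.
#'
#' @param f objective function.
#' @param g gradient function.
#' @param x0 starting point.
#' @param grad_tol gradient-norm stopping tolerance (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @param armijo an [armijo_params()].
#' @param lower,upper optional box bounds (recycled scalars allowed).
#' @param step0_scaling when TRUE (default), the trial step on a fresh
#'   Hessian model (first iteration, or right after a reset to steepest
#'   descent) starts at `min(s, 1/||g||)` instead of `s`; with `B = I`
#'   the raw step `-g` can be arbitrarily long, and on objectives with
#'   saturating flat regions (sigmoid networks) a huge greedy first
#'   step can land on a plateau the iteration never leaves.
#' @return list with `x`, `f`, `gradient_norm`, `iterations`,
#'   `converged`.
#' @export
bfgs_minimize <- function(f, g, x0, grad_tol = 1e-6, max_iter = 200L,
                          armijo = armijo_params(),
                          lower = NULL, upper = NULL,
                          step0_scaling = TRUE) {
  project <- function(x) {
    if (!is.null(lower)) x <- pmax(x, lower)
    if (!is.null(upper)) x <- pmin(x, upper)
    x
  }
  x <- project(as.numeric(x0))
  d <- length(x)
  fx <- f(x)
  gx <- g(x)
  B <- diag(d)
  iterations <- 0L
  fresh_model <- TRUE
  for (k in seq_len(max_iter)) {
    gnorm <- sqrt(sum(gx^2))
    if (gnorm < grad_tol) {
      return(list(x = x, f = fx, gradient_norm = gnorm,
                  iterations = iterations, converged = TRUE))
    }
    dk <- tryCatch({
      ch <- chol(B)
      -backsolve(ch, forwardsolve(t(ch), gx))
    }, error = function(e) NULL)
    if (is.null(dk) || sum(gx * dk) >= 0 || !all(is.finite(dk))) {
      B <- diag(d)       # reset to steepest descent on a bad model
      dk <- -gx
      fresh_model <- TRUE
    }
    step_params <- armijo
    if (step0_scaling && fresh_model && gnorm > 1) {
      step_params <- armijo_params(s = armijo$s / gnorm,
                                   lambda = armijo$lambda,
                                   sigma = armijo$sigma,
                                   max_backtracks = armijo$max_backtracks)
    }
    ls <- tryCatch(armijo_step(f, x, gx, dk, step_params, fk = fx),
                   epiwindow_linesearch_error = function(e) NULL)
    if (is.null(ls)) {
      return(list(x = x, f = fx, gradient_norm = gnorm,
                  iterations = iterations, converged = FALSE))
    }
    x_new <- project(x + ls$step * dk)
    g_new <- g(x_new)
    f_new <- f(x_new)
    if (f_new > fx) {       # projection can only help; guard regardless
      return(list(x = x, f = fx, gradient_norm = gnorm,
                  iterations = iterations, converged = FALSE))
    }
    B <- bfgs_update(B, x_new - x, g_new - gx)
    x <- x_new; fx <- f_new; gx <- g_new
    iterations <- k
    fresh_model <- FALSE
  }
  gnorm <- sqrt(sum(gx^2))
  list(x = x, f = fx, gradient_norm = gnorm,
       iterations = iterations, converged = gnorm < grad_tol)
}

#' Multistart global minimization
#'
#' Draws `n_starts` uniform points from the box `[lower, upper]`,
#' refines each with [bfgs_minimize()], and collects the distinct local
#' minima found: a refined point joins the set only if it is farther
#' than `dedupe_tol_x` (Euclidean) from every member (with
#' `dedupe_tol_f` as a secondary objective-value check). Only converged
#' local searches contribute.
#'
#' @param f objective function.
#' @param g gradient function.
#' @param lower,upper box bounds (vectors or scalars with `dim` set by
#'   the longer of the two).
#' @param n_starts number of random starts (default 25).
#' @param seed integer seed fixing the sample of starting points.
#' @param dedupe_tol_x x-distance below which two minima are the same.
#' @param dedupe_tol_f objective-gap companion tolerance.
#' @param grad_tol,max_iter,armijo local-solver settings.
#' @param keep_unconverged when TRUE, local searches that stopped
#'   before reaching `grad_tol` (iteration cap, line-search stall) are
#'   still eligible for `best`; they never enter `minima`. Useful for
#'   objectives like neural-network training where the gradient norm
#'   rarely reaches tight tolerances but the best point found is what
#'   matters.
#' @param sample_lower,sample_upper optional sub-box from which the
#'   starting points are drawn (defaults to the full `[lower, upper]`
#'   box); local searches still roam the full box. For sigmoid-network
#'   training a small starting box keeps the initial units out of
#'   saturation.
#' @return list with `minima` (list of `x`, `f`), `best` and the number
#'   of converged `n_converged` starts.
#' @export
multistart_minimize <- function(f, g, lower, upper, n_starts = 25L,
                                seed = NULL, dedupe_tol_x = 1e-3,
                                dedupe_tol_f = 1e-6, grad_tol = 1e-6,
                                max_iter = 200L, armijo = armijo_params(),
                                keep_unconverged = FALSE,
                                sample_lower = lower,
                                sample_upper = upper) {
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds")
  sample_lower <- rep_len(as.numeric(sample_lower), d)
  sample_upper <- rep_len(as.numeric(sample_upper), d)
  starts <- with_seed_or_not(seed, {
    matrix(stats::runif(n_starts * d, rep(sample_lower, each = n_starts),
                        rep(sample_upper, each = n_starts)),
           nrow = n_starts)
  })
  minima <- list()
  fallback <- NULL
  n_converged <- 0L
  for (i in seq_len(n_starts)) {
    res <- bfgs_minimize(f, g, starts[i, ], grad_tol = grad_tol,
                         max_iter = max_iter, armijo = armijo,
                         lower = lower, upper = upper)
    if (!res$converged) {
      if (keep_unconverged && (is.null(fallback) || res$f < fallback$f)) {
        fallback <- list(x = res$x, f = res$f)
      }
      next
    }
    n_converged <- n_converged + 1L
    duplicate <- any(vapply(minima, function(m) {
      sqrt(sum((m$x - res$x)^2)) <= dedupe_tol_x &&
        abs(m$f - res$f) <= max(dedupe_tol_f, dedupe_tol_f * abs(m$f))
    }, logical(1)))
    if (!duplicate) minima[[length(minima) + 1L]] <- list(x = res$x, f = res$f)
  }
  if (!length(minima) && is.null(fallback)) {
    stop("no local search converged; cannot report minima")
  }
  best <- fallback
  if (length(minima)) {
    fs <- vapply(minima, function(m) m$f, numeric(1))
    cand <- minima[[which.min(fs)]]
    if (is.null(best) || cand$f <= best$f) best <- cand
  }
  list(minima = minima, best = best, n_converged = n_converged)
}

#' Genetic-algorithm configuration
#'
#' @param N population size.
#' @param m offspring per generation (default `round(0.9 * N)`).
#' @param pm per-component mutation probability.
#' @param itermax maximum number of generations.
#' @param e stopping tolerance on the best-to-worst fitness spread.
#' @param kls local-search period in generations.
#' @param tournament_size tournament size for parent selection.
#' @param local_search run BFGS from the best member every `kls`
#'   generations.
#' @param local_max_iter iteration cap for those local searches.
#' @return a `ga_config` list.
#' @export
ga_config <- function(N = 200L, m = NULL, pm = 0.05, itermax = 200L,
                      e = 1e-6, kls = 20L, tournament_size = 4L,
                      local_search = TRUE, local_max_iter = 50L) {
  N <- as.integer(N)
  m <- as.integer(m %||% round(0.9 * N))
  if (N < 2L) stop("population size N must be at least 2")
  if (m < 1L || m >= N) stop("offspring count m must satisfy 1 <= m < N")
  if (pm < 0 || pm > 1) stop("pm must be in [0, 1]")
  if (e < 0) stop("e must be non-negative")
  if (kls < 1L) stop("kls must be >= 1")
  structure(list(N = N, m = m, pm = pm, itermax = as.integer(itermax),
                 e = e, kls = as.integer(kls),
                 tournament_size = as.integer(tournament_size),
                 local_search = isTRUE(local_search),
                 local_max_iter = as.integer(local_max_iter)),
            class = "ga_config")
}

clip_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Arithmetic crossover of two real-coded parents
#'
#' Per component `i` with coefficient `a_i ~ U[-0.5, 1.5]`:
#' `child1_i = a_i x_i + (1 - a_i) y_i` and
#' `child2_i = a_i y_i + (1 - a_i) x_i`. Offspring are clipped to the
#' box when bounds are supplied.
#'
#' @param x,y parent vectors of equal length.
#' @param a crossover coefficients (drawn uniformly when omitted;
#'   injectable for testing).
#' @param lower,upper optional box bounds.
#' @return list of two offspring vectors.
#' @export
ga_crossover <- function(x, y, a = stats::runif(length(x), -0.5, 1.5),
                         lower = NULL, upper = NULL) {
  if (length(x) != length(y)) stop("parents must have the same dimension")
  c1 <- a * x + (1 - a) * y
  c2 <- a * y + (1 - a) * x
  if (!is.null(lower) || !is.null(upper)) {
    c1 <- clip_box(c1, lower, upper)
    c2 <- clip_box(c2, lower, upper)
  }
  list(c1, c2)
}

#' Annealed non-uniform mutation
#'
#' Each component mutates independently with probability `pm`. A
#' mutated component moves toward its upper bound (`t = 0`) by
#' `Delta(iter, r_i - x_i)` or toward its lower bound (`t = 1`) by
#' `Delta(iter, x_i - l_i)`, where
#' `Delta(iter, y) = y * (1 - r^(1 - iter/itermax))` with
#' `r ~ U[0, 1]`. The magnitude anneals to zero as `iter` approaches
#' `itermax`, and the result always stays inside `[l_i, r_i]`.
#'
#' @param x chromosome (inside the box).
#' @param iter current generation (0 to `itermax`).
#' @param itermax maximum generations.
#' @param lower,upper box bounds.
#' @param pm per-component mutation probability.
#' @param mask,t_draw,r_draw optional pre-drawn randomness (logical
#'   mutation mask, direction bits in {0, 1}, and uniforms), injectable
#'   for testing.
#' @return mutated vector.
#' @export
ga_mutate <- function(x, iter, itermax, lower, upper, pm = 0.05,
                      mask = NULL, t_draw = NULL, r_draw = NULL) {
  n <- length(x)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  mask <- mask %||% (stats::runif(n) < pm)
  if (!any(mask)) return(x)
  t_draw <- t_draw %||% (stats::runif(n) < 0.5)
  r_draw <- r_draw %||% stats::runif(n)
  expo <- 1 - iter / itermax
  shrink <- 1 - r_draw^expo
  up <- mask & !t_draw
  dn <- mask & t_draw
  x[up] <- x[up] + (upper[up] - x[up]) * shrink[up]
  x[dn] <- x[dn] - (x[dn] - lower[dn]) * shrink[dn]
  clip_box(x, lower, upper)
}

#' Trial point around the best chromosome
#'
#' `xt_i = (1 + gamma_i) * best_i - gamma_i * y_i` with
#' `gamma_i ~ U[-0.5, 0.5]`, clipped to the box; the caller replaces
#' the worst population member only when the trial point is at least as
#' good.
#'
#' @param x_best current best chromosome.
#' @param y a random population member.
#' @param gamma coefficients (drawn uniformly when omitted).
#' @param lower,upper optional box bounds.
#' @return trial vector.
#' @export
ga_trial_point <- function(x_best, y,
                           gamma = stats::runif(length(x_best), -0.5, 0.5),
                           lower = NULL, upper = NULL) {
  if (length(x_best) != length(y)) stop("points must have the same dimension")
  xt <- (1 + gamma) * x_best - gamma * y
  if (!is.null(lower) || !is.null(upper)) xt <- clip_box(xt, lower, upper)
  xt
}

#' Tournament selection
#'
#' Draws `size` members uniformly with replacement and returns the
#' index of the fittest (lowest objective value).
#'
#' @param fitness vector of objective values for the population.
#' @param size tournament size.
#' @return the selected population index.
#' @export
tournament_select <- function(fitness, size = 4L) {
  contenders <- sample.int(length(fitness), size, replace = TRUE)
  contenders[which.min(fitness[contenders])]
}

#' Modified real-coded genetic algorithm
#'
#' Per generation: check the stopping rule (best-to-worst fitness
#' spread at most `e`, or the generation cap); create `m` offspring from
#' tournament-selected parents by arithmetic crossover; mutate them
#' with the annealed non-uniform operator; replace the `m` worst
#' members; attempt one trial point around the best member (accepted
#' only if at least as good as the current worst); and every `kls`
#' generations refine the best member with [bfgs_minimize()], keeping
#' the result if it improves. The population size is constant and the
#' best fitness is non-increasing.
#'
#' @param f objective function.
#' @param lower,upper box bounds defining the search region.
#' @param config a [ga_config()].
#' @param seed integer seed fixing all randomness.
#' @param g gradient for the periodic local search; central finite
#'   differences are used when omitted.
#' @return list with `x`, `f`, `generations` and a per-generation
#'   `history` data frame (`generation`, `best`, `worst`, `pop_size`).
#' @export
ga_minimize <- function(f, lower, upper, config = ga_config(),
                        seed = NULL, g = NULL) {
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds")
  if (is.null(g)) {
    g <- function(x) {
      h <- pmax(1e-6, 1e-6 * abs(x))
      vapply(seq_along(x), function(i) {
        e <- numeric(length(x)); e[i] <- h[i]
        (f(x + e) - f(x - e)) / (2 * h[i])
      }, numeric(1))
    }
  }
  with_seed_or_not(seed, {
    N <- config$N
    pop <- matrix(stats::runif(N * d, rep(lower, each = N), rep(upper, each = N)),
                  nrow = N)
    fit <- apply(pop, 1L, f)
    history <- data.frame(generation = integer(0), best = numeric(0),
                          worst = numeric(0), pop_size = integer(0))
    iter <- 0L
    while (iter < config$itermax) {
      if (abs(max(fit) - min(fit)) <= config$e) break
      iter <- iter + 1L
      offspring <- matrix(0, nrow = config$m, ncol = d)
      made <- 0L
      while (made < config$m) {
        p1 <- tournament_select(fit, config$tournament_size)
        p2 <- tournament_select(fit, config$tournament_size)
        kids <- ga_crossover(pop[p1, ], pop[p2, ], lower = lower, upper = upper)
        for (kid in kids) {
          if (made >= config$m) break
          made <- made + 1L
          offspring[made, ] <- ga_mutate(kid, iter, config$itermax,
                                         lower, upper, pm = config$pm)
        }
      }
      worst_idx <- order(fit, decreasing = TRUE)[seq_len(config$m)]
      pop[worst_idx, ] <- offspring
      fit[worst_idx] <- apply(offspring, 1L, f)

      best_idx <- which.min(fit)
      y <- pop[sample.int(N, 1L), ]
      xt <- ga_trial_point(pop[best_idx, ], y, lower = lower, upper = upper)
      ft <- f(xt)
      worst <- which.max(fit)
      if (ft <= fit[worst]) {
        pop[worst, ] <- xt
        fit[worst] <- ft
      }

      if (config$local_search && iter %% config$kls == 0L) {
        best_idx <- which.min(fit)
        ls <- bfgs_minimize(f, g, pop[best_idx, ],
                            max_iter = config$local_max_iter,
                            lower = lower, upper = upper)
        if (ls$f < fit[best_idx]) {
          pop[best_idx, ] <- ls$x
          fit[best_idx] <- ls$f
        }
      }
      history <- rbind(history, data.frame(
        generation = iter, best = min(fit), worst = max(fit),
        pop_size = nrow(pop)))
    }
    best_idx <- which.min(fit)
    list(x = pop[best_idx, ], f = fit[best_idx], generations = iter,
         history = history)
  })
}
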