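# --- Armijo line search ---------------------------------------------------

test_that("Armijo backtracking returns the documented steps on worked examples", {
  f <- function(x) x^2
  # from x = 1 along d = -2: a = 1 rejected (decrease 0), a = 0.5 accepted
  res <- armijo_step(f, 1, gk = 2, dk = -2,
                     armijo_params(s = 1, lambda = 0.5, sigma = 1e-4))
  expect_identical(res$step, 0.5)
  expect_equal(res$f_new, 0)
  # linear objective: the very first trial already satisfies the condition
  res2 <- armijo_step(function(x) -x, 0, gk = -1, dk = 1, armijo_params(s = 1))
  expect_identical(res2$step, 1)
  # an ascent direction violates the precondition
  expect_error(armijo_step(f, 1, gk = 2, dk = 2), "descent")
})

test_that("Armijo failure raises a typed condition after max_backtracks", {
  # a function that never decreases along the direction
  f <- function(x) abs(x)
  expect_error(
    armijo_step(f, 0, gk = -1, dk = 1, armijo_params(max_backtracks = 5)),
    class = "epiwindow_linesearch_error")
})

# --- BFGS update algebra --------------------------------------------------

test_that("the BFGS update fixes the identity and satisfies the secant equation", {
  e1 <- c(1, 0, 0)
  expect_equal(bfgs_update(diag(3), e1, e1), diag(3), tolerance = 1e-14)
  withr::with_seed(1, {
    for (rep in 1:50) {
      A <- matrix(rnorm(25), 5)
      B <- crossprod(A) + diag(5) * 0.5  # SPD
      s <- rnorm(5)
      y <- rnorm(5)
      if (sum(s * y) <= 0) y <- -y      # enforce curvature
      B1 <- bfgs_update(B, s, y)
      expect_equal(as.vector(B1 %*% s), y, tolerance = 1e-10)
      expect_equal(B1, t(B1), tolerance = 1e-10)
      expect_gt(min(eigen(B1, symmetric = TRUE, only.values = TRUE)$values), 0)
    }
  })
})

test_that("a failed curvature condition skips the update", {
  B <- diag(2)
  expect_identical(bfgs_update(B, c(1, 0), c(-1, 0)), B)
})

# --- BFGS minimization ----------------------------------------------------

test_that("BFGS solves convex quadratics and Rosenbrock", {
  f <- function(x) sum(x^2)
  g <- function(x) 2 * x
  res <- bfgs_minimize(f, g, rep(1, 10), max_iter = 100)
  expect_true(res$converged)
  expect_lt(max(abs(res$x)), 1e-4)
  expect_lt(res$gradient_norm, 1e-6)

  fr <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  gr <- function(x) c(-2 * (1 - x[1]) - 400 * x[1] * (x[2] - x[1]^2),
                      200 * (x[2] - x[1]^2))
  res2 <- bfgs_minimize(fr, gr, c(-1.2, 1), max_iter = 500)
  expect_lt(max(abs(res2$x - c(1, 1))), 1e-3)
  # independent reference optimizer agrees on the minimizer
  ref <- stats::optim(c(-1.2, 1), fr, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  expect_lt(max(abs(res2$x - ref$par)), 1e-3)
})

test_that("a start already at tolerance returns unchanged with zero iterations", {
  res <- bfgs_minimize(function(x) sum(x^2), function(x) 2 * x, rep(0, 3))
  expect_identical(res$iterations, 0L)
  expect_identical(res$x, rep(0, 3))
  expect_true(res$converged)
})

test_that("the objective is monotonically non-increasing along BFGS iterates", {
  fr <- function(x) (1 - x[1])^2 + 100 * (x[2] - x[1]^2)^2
  gr <- function(x) c(-2 * (1 - x[1]) - 400 * x[1] * (x[2] - x[1]^2),
                      200 * (x[2] - x[1]^2))
  vals <- c()
  f_traced <- function(x) { v <- fr(x); vals <<- c(vals, v); v }
  res <- bfgs_minimize(f_traced, gr, c(-1.2, 1), max_iter = 200)
  # accepted objective values never increase (trials may exceed, so
  # compare the running minimum against the reported optimum)
  expect_lte(res$f, min(vals) + 1e-12)
})

# --- Multistart -----------------------------------------------------------

test_that("multistart recovers both wells of (x^2-1)^2 and dedupes repeats", {
  f <- function(x) (x^2 - 1)^2
  g <- function(x) 4 * x * (x^2 - 1)
  res <- multistart_minimize(f, g, -2, 2, n_starts = 50, seed = 17)
  xs <- sort(vapply(res$minima, function(m) m$x, numeric(1)))
  expect_length(xs, 2)
  expect_equal(xs, c(-1, 1), tolerance = 1e-3)
  expect_lte(res$best$f, min(vapply(res$minima, function(m) m$f, numeric(1))))
  # every reported minimum is a converged stationary point
  for (m in res$minima) expect_lt(abs(g(m$x)), 1e-6)
})

test_that("a convex quadratic yields exactly one reported minimum", {
  res <- multistart_minimize(function(x) sum((x - 3)^2), function(x) 2 * (x - 3),
                             c(-5, -5), c(5, 5), n_starts = 20, seed = 4)
  expect_length(res$minima, 1)
  expect_equal(res$best$x, c(3, 3), tolerance = 1e-4)
})

test_that("multistart is deterministic given its seed", {
  f <- function(x) (x^2 - 1)^2
  g <- function(x) 4 * x * (x^2 - 1)
  a <- multistart_minimize(f, g, -2, 2, n_starts = 10, seed = 5)
  b <- multistart_minimize(f, g, -2, 2, n_starts = 10, seed = 5)
  expect_identical(a, b)
})

# --- GA operators ----------------------------------------------------------

test_that("arithmetic crossover reproduces its closed-form special cases", {
  x <- c(1, 2, 3); y <- c(4, 5, 6)
  expect_identical(ga_crossover(x, y, a = rep(1, 3)), list(x, y))
  expect_identical(ga_crossover(x, y, a = rep(0, 3)), list(y, x))
  mid <- (x + y) / 2
  expect_identical(ga_crossover(x, y, a = rep(0.5, 3)), list(mid, mid))
  # clipping keeps offspring inside the box
  kids <- ga_crossover(c(9, 9), c(-9, -9), a = c(1.5, -0.5),
                       lower = rep(-10, 2), upper = rep(10, 2))
  expect_true(all(unlist(kids) >= -10 & unlist(kids) <= 10))
})

test_that("non-uniform mutation anneals to zero and respects bounds", {
  x <- c(0.5, -0.5)
  expect_identical(ga_mutate(x, 10, 100, -1, 1, pm = 0), x)
  # at iter = itermax the exponent vanishes: r^0 = 1 -> no movement
  expect_equal(ga_mutate(x, 100, 100, -1, 1, pm = 1,
                         mask = c(TRUE, TRUE), t_draw = c(FALSE, TRUE),
                         r_draw = c(0.3, 0.9)), x)
  # direction bits move toward the matching bound
  up <- ga_mutate(0, 0, 100, -1, 1, pm = 1, mask = TRUE,
                  t_draw = FALSE, r_draw = 0.25)
  expect_gt(up, 0)
  dn <- ga_mutate(0, 0, 100, -1, 1, pm = 1, mask = TRUE,
                  t_draw = TRUE, r_draw = 0.25)
  expect_lt(dn, 0)
  # exhaustive bound check
  withr::with_seed(2, {
    res <- replicate(10000, ga_mutate(runif(1, -3, 7), sample(0:50, 1), 50,
                                      lower = -3, upper = 7, pm = 1))
    expect_true(all(res >= -3 & res <= 7))
  })
})

test_that("trial points interpolate between the best point and a random member", {
  b <- c(1, 2); y <- c(3, 8)
  expect_identical(ga_trial_point(b, y, gamma = c(0, 0)), b)
  expect_identical(ga_trial_point(b, y, gamma = c(-0.5, -0.5)), (b + y) / 2)
  expect_identical(ga_trial_point(b, y, gamma = c(0.5, 0.5)), 1.5 * b - 0.5 * y)
})

test_that("tournament selection prefers fitter members monotonically", {
  fitness <- 1:10  # member 1 is best
  withr::with_seed(3, {
    picks <- replicate(10000, tournament_select(fitness, size = 4))
    freq <- tabulate(picks, 10)
    # strictly more selections for the best than the median and worst members
    expect_gt(freq[1], freq[5])
    expect_gt(freq[5], freq[10])
    # overall monotone trend over fitness-ordered population
    expect_lt(cor(1:10, freq), -0.9)
  })
  expect_identical(tournament_select(5, size = 3), 1L)
})

# --- GA end to end ---------------------------------------------------------

test_that("the GA minimizes the 2-D sphere with constant population and monotone best", {
  f <- function(x) sum(x^2)
  res <- ga_minimize(f, c(-10, -10), c(10, 10),
                     ga_config(N = 50, itermax = 200), seed = 31,
                     g = function(x) 2 * x)
  expect_lt(res$f, 1e-3)
  expect_true(all(res$history$pop_size == 50))
  expect_true(all(diff(res$history$best) <= 1e-12))
})

test_that("the GA is deterministic given (config, seed)", {
  f <- function(x) sum((x - 1)^2)
  a <- ga_minimize(f, c(-5, -5), c(5, 5), ga_config(N = 20, itermax = 30),
                   seed = 9)
  b <- ga_minimize(f, c(-5, -5), c(5, 5), ga_config(N = 20, itermax = 30),
                   seed = 9)
  expect_identical(a, b)
})

test_that("all three trainers master a separable 3-class toy problem", {
  tab <- separable_toy_table(n_per_class = 50)  # n = 150
  X <- scale(as.matrix(tab[, 1:2]))
  y <- tab$label
  prob <- slnn_problem(X, y, n_hidden = 5)
  train_acc <- function(w) mean(slnn_predict(w, X, prob$shape, prob$levels) == y)

  fit_b <- bfgs_minimize(prob$f, prob$g, withr::with_seed(1, runif(prob$d, -0.2, 0.2)),
                         max_iter = 300, armijo = armijo_params(s = 0.1))
  expect_gte(train_acc(fit_b$x), 0.95)

  fit_m <- multistart_minimize(prob$f, prob$g, rep(-10, prob$d), rep(10, prob$d),
                               n_starts = 5, seed = 2, max_iter = 150,
                               armijo = armijo_params(s = 0.1),
                               keep_unconverged = TRUE,
                               sample_lower = rep(-0.5, prob$d),
                               sample_upper = rep(0.5, prob$d))
  expect_gte(train_acc(fit_m$best$x), 0.95)

  fit_g <- ga_minimize(prob$f, rep(-2, prob$d), rep(2, prob$d),
                       ga_config(N = 40, itermax = 40, kls = 10), seed = 3,
                       g = prob$g)
  expect_gte(train_acc(fit_g$x), 0.95)
})
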