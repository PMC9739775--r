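# Desk-scale study presets: the shipped configuration for running the
# window-length experiment end to end on a single CPU in minutes.

#' Desk-scale optimizer budgets for the window-length study
#'
#' The full-study optimizer defaults (GA population 200 over 200
#' generations, 25 multistart launches) are sized for a cluster run.
#' This preset keeps every algorithmic component - Armijo-BFGS,
#' multistart-over-BFGS, the modified GA with periodic local search,
#' and K-NN with K = 2 - but scales the search budgets so a sweep over
#' a 10-recordings-per-class dataset finishes in minutes: GA with
#' N = 50 over 60 generations (local search every 20), 8 multistart
#' launches, and BFGS capped at 300 iterations.
#'
#' The weight boxes are also sized for trainability rather than taken
#' from the generic +/-10 default: uniform starting points over the
#' full +/-10 box put a 135-weight sigmoid network deep into
#' saturation, where gradients vanish and a desk-scale search budget
#' cannot recover. Multistart therefore draws its starting points from
#' the +/-0.5 sub-box (local searches still roam the full box), and
#' the GA evolves inside +/-2.
#'
#' @return named list of per-method configuration overrides suitable
#'   for the `method_config` argument of [run_window_sweep()] and
#'   [evaluate_classifier()].
#' @export
study_method_config <- function() {
  list(
    bfgs = list(max_iter = 300L),
    multistart = list(n_starts = 8L, max_iter = 150L, bound = 10,
                      init_bound = 0.5),
    ga = list(bound = 2,
              ga = ga_config(N = 50L, itermax = 60L, kls = 20L)),
    knn = list(k = 2L)
  )
}
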