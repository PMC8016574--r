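#' Genetic-algorithm configuration for (C, gamma) search
#'
#' Chromosomes are real-valued pairs `(log2 C, log2 gamma)`. Each
#' generation the elite complement of the generation gap (top 5% by
#' fitness at the defaults) is carried over unchanged, and the remainder
#' is bred by tournament selection, blend (BLX) crossover and Gaussian
#' mutation. Fitness is cross-validated accuracy unless a custom fitness
#' function is supplied.
#'
#' @param pop_size Population size (default 50).
#' @param max_gen Number of generations after initialization (default 50).
#' @param generation_gap Fraction of the population replaced each
#'   generation (default 0.95); the complement is the elite carried
#'   unchanged.
#' @param p_crossover Crossover probability per offspring pair (default 0.8).
#' @param p_mutation Per-gene Gaussian mutation probability (default 0.1).
#' @param C_range,gamma_range Search ranges in log2 units (defaults
#'   `c(-5, 15)` and `c(-15, 3)`, the community-standard grid bounds).
#' @param cv_folds Cross-validation folds for the fitness (default 5).
#' @param seed Integer seed; the whole run (fold assignment included) is
#'   reproducible from it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 50L, max_gen = 50L, generation_gap = 0.95,
                      p_crossover = 0.8, p_mutation = 0.1,
                      C_range = c(-5, 15), gamma_range = c(-15, 3),
                      cv_folds = 5L, seed = 1L) {
  if (pop_size < 2L) stop("`pop_size` must be >= 2", call. = FALSE)
  if (max_gen < 1L) stop("`max_gen` must be >= 1", call. = FALSE)
  if (generation_gap <= 0 || generation_gap > 1) {
    stop("`generation_gap` must lie in (0, 1]", call. = FALSE)
  }
  if (diff(C_range) <= 0 || diff(gamma_range) <= 0) {
    stop("search ranges must be non-empty intervals", call. = FALSE)
  }
  structure(
    list(pop_size = as.integer(pop_size), max_gen = as.integer(max_gen),
         generation_gap = generation_gap, p_crossover = p_crossover,
         p_mutation = p_mutation, C_range = as.numeric(C_range),
         gamma_range = as.numeric(gamma_range),
         cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
    class = "ga_config"
  )
}

#' Genetic-algorithm optimization of the RBF-SVM hyperparameters
#'
#' Searches `(log2 C, log2 gamma)` for the setting maximizing
#' [cv_fitness()] on `ds`. Elitism guarantees a non-decreasing
#' best-fitness history; the fold assignment is fixed once per run so
#' every chromosome is scored on identical folds.
#'
#' @param ds Labelled dataset tibble (ignored when `fitness` is supplied).
#' @param cfg A [ga_config()].
#' @param fitness Optional custom fitness `function(C, gamma)` returning a
#'   scalar to maximize; defaults to cross-validated accuracy on `ds`.
#' @return A `ga_result` with `best_params` ([svm_params()]),
#'   `best_fitness`, a per-generation `history` tibble (columns
#'   `generation`, `best`, `mean`) and the total number of fitness
#'   `evaluations`.
#' @examples
#' \donttest{
#' res <- ga_optimize(fitness = function(C, g) -(log2(C) - 2)^2 - (log2(g) + 3)^2,
#'                    cfg = ga_config(pop_size = 20, max_gen = 10, seed = 7))
#' res$best_params
#' }
#' @export
ga_optimize <- function(ds = NULL, cfg = ga_config(), fitness = NULL) {
  if (is.null(fitness)) {
    if (is.null(ds)) stop("supply `ds` or a `fitness` function", call. = FALSE)
    validate_dataset(ds)
    cv_seed <- cfg$seed + 10007L
    fitness <- function(C, gamma) {
      cv_fitness(ds, svm_params(C, gamma), folds = cfg$cv_folds, seed = cv_seed)
    }
  }
  lo <- c(cfg$C_range[1L], cfg$gamma_range[1L])
  hi <- c(cfg$C_range[2L], cfg$gamma_range[2L])
  eval_chrom <- function(ch) fitness(2^ch[1L], 2^ch[2L])
  n_elite <- max(1L, as.integer(round((1 - cfg$generation_gap) * cfg$pop_size)))
  evaluations <- 0L

  withr::with_seed(cfg$seed, {
    pop <- t(replicate(cfg$pop_size, stats::runif(2, lo, hi)))
    fit <- apply(pop, 1L, eval_chrom)
    evaluations <- evaluations + cfg$pop_size
    history <- tibble::tibble(generation = 0L, best = max(fit), mean = mean(fit))

    for (gen in seq_len(cfg$max_gen)) {
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(n_elite)], , drop = FALSE]
      elite_fit <- fit[ord[seq_len(n_elite)]]

      n_off <- cfg$pop_size - n_elite
      off <- matrix(0, n_off, 2L)
      i <- 1L
      while (i <= n_off) {
        p1 <- tournament_pick(fit)
        p2 <- tournament_pick(fit)
        c1 <- pop[p1, ]; c2 <- pop[p2, ]
        if (stats::runif(1) < cfg$p_crossover) {
          xo <- blend_crossover(c1, c2, lo, hi)
          c1 <- xo[[1L]]; c2 <- xo[[2L]]
        }
        off[i, ] <- gaussian_mutate(c1, cfg$p_mutation, lo, hi)
        i <- i + 1L
        if (i <= n_off) {
          off[i, ] <- gaussian_mutate(c2, cfg$p_mutation, lo, hi)
          i <- i + 1L
        }
      }
      off_fit <- apply(off, 1L, eval_chrom)
      evaluations <- evaluations + n_off
      pop <- rbind(elite, off)
      fit <- c(elite_fit, off_fit)
      history <- dplyr::bind_rows(history, tibble::tibble(
        generation = gen, best = max(fit), mean = mean(fit)
      ))
    }
  })

  best_idx <- which.max(fit)
  structure(
    list(best_params = svm_params(2^pop[best_idx, 1L], 2^pop[best_idx, 2L]),
         best_chromosome = pop[best_idx, ],
         best_fitness = fit[best_idx],
         history = history,
         evaluations = evaluations,
         config = cfg),
    class = "ga_result"
  )
}

tournament_pick <- function(fit, k = 3L) {
  cand <- sample.int(length(fit), min(k, length(fit)))
  cand[which.max(fit[cand])]
}

blend_crossover <- function(a, b, lo, hi, alpha = 0.5) {
  d <- abs(a - b)
  lower <- pmin(a, b) - alpha * d
  upper <- pmax(a, b) + alpha * d
  mk <- function() pmin(pmax(stats::runif(2, lower, upper), lo), hi)
  list(mk(), mk())
}

gaussian_mutate <- function(ch, p, lo, hi, sd_frac = 0.1) {
  for (g in seq_along(ch)) {
    if (stats::runif(1) < p) {
      ch[g] <- ch[g] + stats::rnorm(1, sd = sd_frac * (hi[g] - lo[g]))
    }
  }
  pmin(pmax(ch, lo), hi)
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result> best C = %.4f, gamma = %.4f, fitness = %.4f (%d evaluations)\n",
    x$best_params$C, x$best_params$gamma, x$best_fitness, x$evaluations
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ga_result <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    best_C = x$best_params$C,
    best_gamma = x$best_params$gamma,
    best_fitness = x$best_fitness,
    generations = max(x$history$generation),
    evaluations = x$evaluations
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.ga_result <- function(object, ...) {
  hist_long <- tidyr::pivot_longer(object$history, c("best", "mean"),
                                   names_to = "series", values_to = "fitness")
  ggplot2::ggplot(hist_long,
                  ggplot2::aes(x = .data$generation, y = .data$fitness,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "cross-validated fitness",
                  colour = NULL,
                  title = "GA convergence of (C, gamma)") +
    ggplot2::theme_minimal()
}
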