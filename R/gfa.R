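#' Genetic-algorithm feature selection (GFA)
#'
#' A generational GA over binary descriptor masks, wrapping any
#' [regressor_spec()] learner. Chromosome fitness is leave-20%-out q2 on
#' the training compounds (see [cv_r2()]); at (numerically) equal fitness
#' the smaller subset wins, a parsimony tie-break. Elites survive
#' unaltered, so the best-so-far fitness is monotone non-decreasing, and
#' every step is driven by one seeded RNG stream: identical settings give
#' bit-identical selections and traces.
#'
#' @param population_size chromosomes per generation (default 200).
#' @param max_generations generations to run (default 1000; scale down
#'   for interactive work — the search on desk-scale problems converges
#'   in tens of generations).
#' @param survivor_fraction fraction ranked into the mating pool (0.40).
#' @param tournament_size tournament selection size (2).
#' @param elitism_rate fraction copied unaltered to the next generation
#'   (0.10).
#' @param crossover_rate probability a mating pair recombines (uniform
#'   crossover, each bit from either parent with equal probability;
#'   0.60).
#' @param mutation_rate per-bit flip probability applied to offspring
#'   (0.01).
#' @param min_features,max_features subset size bounds enforced by
#'   seeded random repair (defaults 3 and 10).
#' @param seed integer RNG seed.
#' @return A `GASettings` list.
#' @export
ga_settings <- function(population_size = 200L, max_generations = 1000L,
                        survivor_fraction = 0.40, tournament_size = 2L,
                        elitism_rate = 0.10, crossover_rate = 0.60,
                        mutation_rate = 0.01, min_features = 3L,
                        max_features = 10L, seed = 1L) {
  stopifnot(population_size >= 2L,
            survivor_fraction > 0, survivor_fraction <= 1,
            elitism_rate >= 0, elitism_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            min_features >= 1L, max_features >= min_features)
  structure(list(population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 survivor_fraction = survivor_fraction,
                 tournament_size = as.integer(tournament_size),
                 elitism_rate = elitism_rate,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 min_features = as.integer(min_features),
                 max_features = as.integer(max_features),
                 seed = as.integer(seed)),
            class = "GASettings")
}

#' Select a descriptor subset by GFA
#'
#' @param matrix a `DescriptorMatrix` restricted to training compounds,
#'   or any numeric matrix plus `y`.
#' @param spec learner driving the fitness, a [regressor_spec()].
#' @param ga a [ga_settings()].
#' @param ids optional training compound ids (when `matrix` is a
#'   `DescriptorMatrix`, rows to use; default all rows).
#' @return List with `subset` (column names), `fitness`, `model` (fitted
#'   on the full training block) and `trace` (generation, best, mean).
#' @export
gfa_select <- function(matrix, spec = regressor_spec(), ga = ga_settings(),
                       ids = NULL) {
  if (inherits(matrix, "DescriptorMatrix")) {
    rows <- if (is.null(ids)) seq_along(matrix$ids) else match(ids, matrix$ids)
    X <- matrix$values[rows, , drop = FALSE]
    y <- matrix$activity[rows]
  } else {
    X <- as.matrix(matrix)
    y <- attr(matrix, "y")
    if (is.null(y)) stop("supply a DescriptorMatrix or a matrix with attr 'y'")
  }
  p <- ncol(X)
  if (ga$max_features > p)
    stop("max_features (", ga$max_features, ") exceeds descriptor count (",
         p, ")")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(ga$seed)

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(mask) {
    key <- paste(which(mask), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- tryCatch(
      cv_r2(X[, mask, drop = FALSE], y, spec, "L20"),
      error = function(e) -Inf)
    cache[[key]] <- val
    val
  }
  repair <- function(mask) {
    k <- sum(mask)
    if (k < ga$min_features) {
      off <- which(!mask)
      mask[off[sample.int(length(off), ga$min_features - k)]] <- TRUE
    } else if (k > ga$max_features) {
      on_ <- which(mask)
      mask[on_[sample.int(k, k - ga$max_features)]] <- FALSE
    }
    mask
  }
  new_mask <- function() {
    k <- sample(ga$min_features:ga$max_features, 1L)
    mask <- rep(FALSE, p)
    mask[sample.int(p, k)] <- TRUE
    mask
  }

  pop <- replicate(ga$population_size, new_mask(), simplify = FALSE)
  n_elite <- max(1L, floor(ga$elitism_rate * ga$population_size))
  n_surv <- max(2L, floor(ga$survivor_fraction * ga$population_size))
  trace <- data.frame(generation = integer(), best = numeric(),
                      mean = numeric())
  best_mask <- NULL; best_fit <- -Inf

  for (gen in seq_len(ga$max_generations)) {
    fits <- vapply(pop, fitness_of, numeric(1))
    sizes <- vapply(pop, sum, numeric(1))
    ord <- order(-fits, sizes)          # parsimony tie-break
    pop <- pop[ord]; fits <- fits[ord]; sizes <- sizes[ord]
    if (fits[1] > best_fit + 1e-9 ||
        (abs(fits[1] - best_fit) <= 1e-9 && !is.null(best_mask) &&
         sizes[1] < sum(best_mask))) {
      best_fit <- fits[1]; best_mask <- pop[[1]]
    }
    if (is.null(best_mask)) { best_fit <- fits[1]; best_mask <- pop[[1]] }
    trace <- rbind(trace, data.frame(generation = gen, best = best_fit,
                                     mean = mean(fits[is.finite(fits)])))
    if (gen == ga$max_generations) break
    survivors <- pop[seq_len(n_surv)]
    surv_fits <- fits[seq_len(n_surv)]
    pick <- function() {
      cand <- sample.int(n_surv, ga$tournament_size, replace = TRUE)
      cand[which.max(surv_fits[cand])]
    }
    nxt <- pop[seq_len(n_elite)]        # elites pass unaltered
    while (length(nxt) < ga$population_size) {
      p1 <- survivors[[pick()]]
      p2 <- survivors[[pick()]]
      child <- if (stats::runif(1) < ga$crossover_rate) {
        take1 <- stats::runif(p) < 0.5
        ifelse(take1, p1, p2)
      } else p1
      flips <- stats::runif(p) < ga$mutation_rate
      child <- xor(child, flips)
      nxt[[length(nxt) + 1L]] <- repair(child)
    }
    pop <- nxt
  }
  subset <- colnames(X)[best_mask]
  model <- fit_regressor(X[, best_mask, drop = FALSE], y, spec)
  list(subset = subset, fitness = best_fit, model = model, trace = trace)
}
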