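#' Genetic-programming configuration
#'
#' Defaults follow the published parameterisation of the spike-detection
#' search: 25 individuals, 100 generations, trees limited to 25 levels,
#' initial crossover/mutation probabilities 90%/10% with an adaptive
#' schedule, and the function set plus/minus/times/sin/cos/log over the
#' terminals X1..X8.
#'
#' The adaptive schedule: when a generation fails to improve the best
#' fitness, the mutation probability is raised by `adaptation_step`
#' (capped at `p_mutation_cap`) to push exploration; on improvement both
#' probabilities reset to their initial values. The two probabilities always
#' sum to 1.
#'
#' @param population_size number of individuals per generation (>= 2).
#' @param n_generations number of generations before termination.
#' @param max_tree_level depth cap enforced on every individual.
#' @param p_crossover_init,p_mutation_init initial operator probabilities
#'   (must sum to 1).
#' @param adaptation_step probability shifted to mutation per stagnant
#'   generation.
#' @param p_mutation_cap upper bound on the mutation probability.
#' @param terminal_subset feature indices available as terminals.
#' @param rng_seed optional integer; when non-NULL, [evolve_formula()] seeds
#'   R's RNG with it for bit-reproducible runs.
#' @return a `gp_config` list.
#' @export
gp_config <- function(population_size = 25L, n_generations = 100L,
                      max_tree_level = 25L, p_crossover_init = 0.90,
                      p_mutation_init = 0.10, adaptation_step = 0.05,
                      p_mutation_cap = 0.40, terminal_subset = 1:8,
                      rng_seed = NULL) {
  if (population_size < 2L) stop("population_size must be >= 2", call. = FALSE)
  if (abs(p_crossover_init + p_mutation_init - 1) > 1e-12)
    stop("crossover and mutation probabilities must sum to 1", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 max_tree_level = as.integer(max_tree_level),
                 p_crossover_init = p_crossover_init,
                 p_mutation_init = p_mutation_init,
                 adaptation_step = adaptation_step,
                 p_mutation_cap = p_mutation_cap,
                 terminal_subset = as.integer(terminal_subset),
                 rng_seed = rng_seed),
            class = "gp_config")
}

#' Subtree crossover
#'
#' Each offspring is one parent with a uniformly chosen subtree replaced by
#' a uniformly chosen subtree of the other parent (two offspring per pair).
#' Offspring deeper than `max_depth` are rejected and the swap resampled up
#' to `max_tries` times; if no admissible pair is found the parents pass
#' through unchanged, so the depth cap is never broken.
#'
#' @param a,b parent `gp_tree`s.
#' @param max_depth depth cap (default 25 levels).
#' @param max_tries resampling attempts before falling back to the parents.
#' @return list of two `gp_tree` offspring.
#' @export
crossover <- function(a, b, max_depth = 25L, max_tries = 10L) {
  for (t in seq_len(max_tries)) {
    ia <- sample.int(tree_size(a), 1L)
    ib <- sample.int(tree_size(b), 1L)
    sa <- get_subtree(a, ia)
    sb <- get_subtree(b, ib)
    c1 <- set_subtree(a, ia, sb)
    c2 <- set_subtree(b, ib, sa)
    if (tree_depth(c1) <= max_depth && tree_depth(c2) <= max_depth)
      return(list(c1, c2))
  }
  list(a, b)
}

#' Subtree mutation
#'
#' Replaces one uniformly chosen subtree by a freshly grown random tree
#' (max depth `subtree_depth`); the depth cap is enforced by the same
#' reject-and-resample rule as [crossover()].
#'
#' @param a parent `gp_tree`.
#' @param max_depth depth cap.
#' @param subtree_depth maximum depth of the inserted random subtree.
#' @param terminals feature indices for leaves of the new subtree.
#' @param max_tries resampling attempts before returning the parent.
#' @return a `gp_tree`.
#' @export
mutate <- function(a, max_depth = 25L, subtree_depth = 4L, terminals = 1:8,
                   max_tries = 10L) {
  for (t in seq_len(max_tries)) {
    i <- sample.int(tree_size(a), 1L)
    child <- set_subtree(a, i, random_tree(subtree_depth, "grow", terminals))
    if (tree_depth(child) <= max_depth) return(child)
  }
  a
}

#' Fitness context: balanced reference and validation groups
#'
#' The fitness of a candidate formula is the error rate of a scalar KNN
#' classifier: the formula is applied to the reference segments' features to
#' give reference points, every validation segment's scalar is classified
#' against them, and the misclassified fraction is returned. Both groups
#' must be class-balanced (equal spike / nonspike counts).
#'
#' @param reference,validation data frames with columns `X1..X8` and `label`
#'   (values `"spike"` / `"nonspike"`).
#' @param k neighbour count used inside the fitness KNN; clamped (with a
#'   warning) to the reference-group size.
#' @return a `fitness_context` list with elements `reference_x` (matrix),
#'   `reference_labels`, `validation_x`, `validation_labels`, `k`.
#' @export
fitness_context <- function(reference, validation, k = 100L) {
  ref <- split_features(reference, "reference")
  val <- split_features(validation, "validation")
  if (length(val$labels) == 0L) stop("empty validation set", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > length(ref$labels)) {
    warning("k = ", k, " exceeds reference size ", length(ref$labels),
            "; clamping", call. = FALSE)
    k <- length(ref$labels)
  }
  structure(list(reference_x = ref$x, reference_labels = ref$labels,
                 validation_x = val$x, validation_labels = val$labels,
                 k = k),
            class = "fitness_context")
}

split_features <- function(df, what) {
  cols <- paste0("X", 1:8)
  if (!all(cols %in% names(df)) || is.null(df$label))
    stop(what, " group needs columns X1..X8 and label", call. = FALSE)
  tab <- table(factor(df$label, levels = c("spike", "nonspike")))
  if (tab[["spike"]] != tab[["nonspike"]])
    stop(what, " group must have equal spike and nonspike counts (got ",
         tab[["spike"]], " vs ", tab[["nonspike"]], ")", call. = FALSE)
  if (tab[["spike"]] == 0L) stop(what, " group has no segments", call. = FALSE)
  list(x = as.matrix(df[, cols]), labels = as.character(df$label))
}

#' KNN classification error of a candidate formula
#'
#' @param tree a `gp_tree`.
#' @param ctx a [fitness_context()].
#' @return misclassified fraction in `[0, 1]`; lower is better.
#' @export
gp_fitness <- function(tree, ctx) {
  stopifnot(inherits(ctx, "fitness_context"))
  refs <- evaluate_formula(tree, ctx$reference_x)
  model <- knn_model(refs, ctx$reference_labels, k = ctx$k)
  pred <- knn_classify(model, evaluate_formula(tree, ctx$validation_x))
  mean(pred != ctx$validation_labels)
}

#' Evolve a discriminative scalar formula
#'
#' Elitist (mu + lambda) loop with lambda = mu: every generation the current
#' population breeds `population_size` offspring — a crossover pair with
#' probability `p_crossover`, a mutant otherwise, parents picked by size-2
#' tournaments — and the fittest `population_size` individuals among parents
#' and offspring survive. Ties in fitness are broken stably (parents, then
#' earlier offspring, first). The operator probabilities adapt as described
#' in [gp_config()]. Search minimises [gp_fitness()].
#'
#' @param ctx a [fitness_context()].
#' @param cfg a [gp_config()].
#' @param on_generation optional callback run after each generation's
#'   survivor selection, called as `on_generation(gen, population, fitness,
#'   p_crossover, p_mutation)`; useful for instrumentation and live traces.
#' @return a `gp_result` list: `best` (the fittest `gp_tree` found),
#'   `best_fitness`, `trace` (best fitness per generation, element 1 being
#'   the initial random population; length `n_generations + 1`),
#'   `p_crossover` / `p_mutation` (per-generation operator probabilities
#'   after adaptation), `n_evaluations`.
#' @export
evolve_formula <- function(ctx, cfg = gp_config(), on_generation = NULL) {
  stopifnot(inherits(ctx, "fitness_context"), inherits(cfg, "gp_config"))
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  mu <- cfg$population_size
  terms <- cfg$terminal_subset
  pop <- ramped_population(mu, terms)
  fit <- vapply(pop, gp_fitness, numeric(1), ctx = ctx)
  n_eval <- mu
  p_mut <- cfg$p_mutation_init
  p_cross <- cfg$p_crossover_init
  trace <- numeric(cfg$n_generations + 1L)
  trace[1L] <- min(fit)
  p_hist <- matrix(NA_real_, cfg$n_generations, 2L,
                   dimnames = list(NULL, c("p_crossover", "p_mutation")))
  tournament <- function() {
    i <- sample.int(mu, 2L, replace = TRUE)
    if (fit[i[1L]] <= fit[i[2L]]) i[1L] else i[2L]
  }
  for (gen in seq_len(cfg$n_generations)) {
    offspring <- vector("list", mu)
    n_off <- 0L
    while (n_off < mu) {
      if (stats::runif(1) < p_cross) {
        kids <- crossover(pop[[tournament()]], pop[[tournament()]],
                          max_depth = cfg$max_tree_level)
        for (kid in kids) {
          if (n_off >= mu) break
          n_off <- n_off + 1L
          offspring[[n_off]] <- kid
        }
      } else {
        n_off <- n_off + 1L
        offspring[[n_off]] <- mutate(pop[[tournament()]],
                                     max_depth = cfg$max_tree_level,
                                     terminals = terms)
      }
    }
    off_fit <- vapply(offspring, gp_fitness, numeric(1), ctx = ctx)
    n_eval <- n_eval + mu
    all_pop <- c(pop, offspring)
    all_fit <- c(fit, off_fit)
    keep <- order(all_fit)[seq_len(mu)]   # stable: parents win ties
    pop <- all_pop[keep]
    fit <- all_fit[keep]
    improved <- min(fit) < trace[gen]
    if (improved) {
      p_mut <- cfg$p_mutation_init
    } else {
      p_mut <- min(p_mut + cfg$adaptation_step, cfg$p_mutation_cap)
    }
    p_cross <- 1 - p_mut
    trace[gen + 1L] <- min(fit)
    p_hist[gen, ] <- c(p_cross, p_mut)
    if (!is.null(on_generation))
      on_generation(gen, pop, fit, p_cross, p_mut)
  }
  best_i <- which.min(fit)
  structure(list(best = pop[[best_i]], best_fitness = fit[best_i],
                 trace = trace, p_crossover = p_hist[, 1L],
                 p_mutation = p_hist[, 2L], n_evaluations = n_eval,
                 population = pop, population_fitness = fit),
            class = "gp_result")
}

#' @export
print.gp_result <- function(x, ...) {
  cat(sprintf("<gp_result> best fitness %.4f after %d evaluations\n  %s\n",
              x$best_fitness, x$n_evaluations, deparse_formula(x$best)))
  invisible(x)
}

#' Write a fitness trace as two-column TSV (generation, best_error)
#' @param result a `gp_result`.
#' @param path file path.
#' @export
write_trace <- function(result, path) {
  utils::write.table(
    data.frame(generation = seq_along(result$trace) - 1L,
               best_error = result$trace),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
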