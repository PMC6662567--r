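# Genetic-algorithm search over binning parameters, with the count of
# high-quality bins against simulated truth as the fitness.

#' Genetic-algorithm configuration
#'
#' Defaults: population 10, selection (elite) size 3, per-gene mutation rate
#' 0.05, crossover rate 0.01, minimum/maximum generations 3/10, binary
#' tournament selection, early stop after 3 generations without improvement
#' once the minimum is reached.
#'
#' @param population,selection_size,mutation_rate,crossover_rate,min_generations,max_generations,tournament,flat_generations,seed
#'   See above.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population = 10, selection_size = 3,
                      mutation_rate = 0.05, crossover_rate = 0.01,
                      min_generations = 3, max_generations = 10,
                      tournament = 2, flat_generations = 3, seed = 1) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            population >= selection_size, selection_size >= 1,
            min_generations >= 1, max_generations >= min_generations)
  structure(list(population = population, selection_size = selection_size,
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 min_generations = min_generations,
                 max_generations = max_generations, tournament = tournament,
                 flat_generations = flat_generations, seed = seed),
            class = "ga_config")
}

#' Default search space for the three accuracy parameters
#'
#' @return Named list of discrete grids for `max_edges`, `max_p`, `min_s`.
#' @export
default_search_space <- function() {
  list(max_edges = c(50, 100, 200, 400, 800),
       max_p = c(80, 85, 90, 95, 97),
       min_s = c(50, 60, 70, 80, 90))
}

#' Genetic-algorithm search over a discrete parameter space
#'
#' Individuals are index vectors into the per-parameter grids.  Each
#' generation: binary tournament selection of parents, one-point crossover
#' at `crossover_rate`, per-gene mutation at `mutation_rate`, and elitism of
#' the top `selection_size` individuals.  Evolution runs for at least
#' `min_generations` and at most `max_generations`, stopping early when the
#' best fitness has not improved for `flat_generations` consecutive
#' generations.  Deterministic given the seed; fitness values are memoised
#' so each parameter set is evaluated once.
#'
#' @param fitness Function taking a named list of parameter values and
#'   returning a numeric fitness (higher is better).
#' @param space Named list of discrete value grids.
#' @param cfg A [ga_config()].
#' @return List with `best` (list `params`, `fitness`), `evaluations` (data
#'   frame of all distinct parameter sets tried), `best_by_generation`, and
#'   `populations` (per-generation index matrices).
#' @export
ga_search <- function(fitness, space, cfg = ga_config()) {
  stopifnot(length(space) >= 1L, all(lengths(space) >= 1L))
  n_genes <- length(space)
  cache <- new.env(parent = emptyenv())
  evals <- list()
  decode <- function(ind) stats::setNames(
    lapply(seq_len(n_genes), function(g) space[[g]][[ind[[g]]]]), names(space))
  fit_of <- function(ind) {
    key <- paste(ind, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- fitness(decode(ind))
    cache[[key]] <- val
    evals[[length(evals) + 1L]] <<- c(decode(ind), list(fitness = val))
    val
  }
  with_seed(cfg$seed, {
    pop <- lapply(seq_len(cfg$population), function(i)
      vapply(lengths(space), function(m) sample.int(m, 1L), integer(1)))
    fits <- vapply(pop, fit_of, numeric(1))
    best_ever <- list(ind = pop[[which.max(fits)]], fitness = max(fits))
    best_by_gen <- numeric(0)
    populations <- list()
    flat <- 0L
    for (gen in seq_len(cfg$max_generations)) {
      o <- order(-fits)
      pop <- pop[o]; fits <- fits[o]
      populations[[gen]] <- do.call(rbind, pop)
      elite <- pop[seq_len(cfg$selection_size)]
      offspring <- list()
      while (length(offspring) < cfg$population - cfg$selection_size) {
        pick <- function() {
          c1 <- sample.int(length(pop), cfg$tournament)
          pop[[c1[which.max(fits[c1])]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- p1
        if (runif(1) < cfg$crossover_rate && n_genes > 1L) {
          cut <- sample.int(n_genes - 1L, 1L)
          child <- c(p1[seq_len(cut)], p2[(cut + 1L):n_genes])
        }
        mut <- runif(n_genes) < cfg$mutation_rate
        if (any(mut))
          child[mut] <- vapply(which(mut), function(g)
            sample.int(length(space[[g]]), 1L), integer(1))
        offspring[[length(offspring) + 1L]] <- child
      }
      pop <- c(elite, offspring)
      fits <- vapply(pop, fit_of, numeric(1))
      gen_best <- max(fits)
      if (gen_best > best_ever$fitness) {
        best_ever <- list(ind = pop[[which.max(fits)]], fitness = gen_best)
        flat <- 0L
      } else {
        flat <- flat + 1L
      }
      best_by_gen <- c(best_by_gen, best_ever$fitness)
      if (gen >= cfg$min_generations && flat >= cfg$flat_generations) break
    }
    ev <- do.call(rbind, lapply(evals, function(e)
      as.data.frame(e, stringsAsFactors = FALSE)))
    list(best = list(params = decode(best_ever$ind),
                     fitness = best_ever$fitness),
         evaluations = ev, best_by_generation = best_by_gen,
         populations = populations)
  })
}

#' High-quality-bin fitness against simulated truth
#'
#' Runs the full binner with the given accuracy parameters on a generated
#' community and counts bins whose majority-genome precision is at least
#' 0.95 (contamination <= 5%) and whose majority genome is at least 90%
#' complete within that bin.
#'
#' @param params Named list with any of `max_edges`, `max_p`, `min_s` (other
#'   binning parameters keep their defaults).
#' @param community Output of [generate_community()].
#' @param base Base [binning_params()] to override.
#' @return Integer count of high-quality bins (0 when the binner fails).
#' @export
truth_fitness <- function(params, community, base = binning_params()) {
  bp <- base
  for (nm in intersect(names(params), names(bp))) bp[[nm]] <- params[[nm]]
  res <- tryCatch(
    run_binning(community$contigs, community$coverage, out_prefix = NULL,
                params = bp, quiet = TRUE),
    error = function(e) {
      message("binner failed for parameter set (fitness 0): ",
              conditionMessage(e))
      NULL
    })
  if (is.null(res) || length(res$bins$bins) == 0L) return(0L)
  truth <- stats::setNames(community$truth$genome_id,
                           community$truth$contig_id)
  lens <- stats::setNames(as.numeric(community$truth$contig_bp),
                          community$truth$contig_id)
  rep <- evaluate_bins(res$bins, community$truth)
  genome_bp <- vapply(rep$per_genome$genome, function(g)
    sum(lens[names(truth)[truth == g]]), numeric(1))
  hq <- 0L
  for (i in seq_len(nrow(rep$per_bin))) {
    b <- rep$per_bin[i, ]
    if (b$precision < 0.95) next
    maj <- b$majority_genome
    maj_bp_in_bin <- b$bp * b$precision
    if (maj_bp_in_bin / genome_bp[[maj]] >= 0.9) hq <- hq + 1L
  }
  hq
}
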