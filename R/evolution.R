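#' Pareto dominance of two fitness vectors
#'
#' `x` dominates `y` iff `x` is at least as large in every component and
#' strictly larger in at least one. The relation is irreflexive,
#' antisymmetric and transitive; vectors with both larger and smaller
#' components are incomparable.
#'
#' @param x,y Numeric vectors of equal length (larger = better).
#' @return Logical scalar.
#' @export
#' @examples
#' dominates(c(3, 1, 2), c(3, 1, 1))  # TRUE
#' dominates(c(4, 0, 2), c(3, 1, 2))  # FALSE: incomparable
dominates <- function(x, y) {
    if (length(x) != length(y))
        stop("fitness vectors differ in arity (", length(x), " vs ",
             length(y), ")")
    all(x >= y) && any(x > y)
}

# full pairwise dominance matrix: D[i, j] is TRUE iff row i dominates row j
.dominanceMatrix <- function(fit) {
    d <- ncol(fit)
    allGe <- anyGt <- NULL
    for (k in seq_len(d)) {
        ge <- outer(fit[, k], fit[, k], ">=")
        gt <- outer(fit[, k], fit[, k], ">")
        allGe <- if (is.null(allGe)) ge else allGe & ge
        anyGt <- if (is.null(anyGt)) gt else anyGt | gt
    }
    allGe & anyGt
}

#' Pareto-rank a set of fitness vectors by iterative frontier peeling
#'
#' The nondominated vectors form frontier 1; they are removed, the
#' nondominated set of the remainder forms frontier 2, and so on until
#' every vector carries a rank count.
#'
#' @param fitness Numeric matrix (rows = vectors, columns = objectives,
#'   larger = better) or a list of equal-length numeric vectors.
#' @return A [ParetoRanking-class].
#' @export
#' @examples
#' r <- paretoRank(rbind(c(3, 1, 2), c(3, 1, 1), c(4, 0, 2)))
#' paretoRanks(r)  # 1 2 1
paretoRank <- function(fitness) {
    if (is.list(fitness)) fitness <- do.call(rbind, fitness)
    if (!is.matrix(fitness)) fitness <- matrix(fitness, nrow = length(fitness))
    if (nrow(fitness) == 0L) stop("cannot rank an empty set")
    if (!all(is.finite(fitness))) stop("fitness values must be finite")
    n <- nrow(fitness)
    # duplicates share the rank of their representative (identical vectors
    # never dominate each other), so peel unique rows only
    key <- do.call(paste, c(asplit(fitness, 2L), sep = "\r"))
    repIdx <- match(key, key)
    uniq <- which(repIdx == seq_len(n))
    dom <- .dominanceMatrix(fitness[uniq, , drop = FALSE])
    uranks <- integer(length(uniq))
    remaining <- seq_along(uniq)
    k <- 0L
    while (length(remaining)) {
        k <- k + 1L
        sub <- dom[remaining, remaining, drop = FALSE]
        nd <- remaining[colSums(sub) == 0L]
        uranks[nd] <- k
        remaining <- setdiff(remaining, nd)
    }
    ranks <- uranks[match(repIdx, uniq)]
    new("ParetoRanking", ranks = ranks,
        frontiers = unname(split(seq_len(n), ranks)))
}

#' GA configuration
#'
#' @param populationSize Individuals per generation (default 600).
#' @param generations Number of generations to run.
#' @param mutationRate Independent substitution probability per free
#'   position of each offspring (default 0.01).
#' @param offspringPerGeneration Offspring produced per generation
#'   (default: `populationSize`, giving a 2N elitist pool).
#' @param founderMutationRate Per-free-position mutation probability used
#'   to scatter the founder population around the seed (default 0.05).
#' @param rngSeed Integer seed driving all randomness of the run.
#' @param selection `"rank"` (sampling weight 1/rank) or `"tournament"`
#'   (binary tournament on rank).
#' @return Named list of class `GAConfig`.
#' @export
gaConfig <- function(populationSize = 600L, generations = 100L,
                     mutationRate = 0.01,
                     offspringPerGeneration = populationSize,
                     founderMutationRate = 0.05, rngSeed = 1L,
                     selection = c("rank", "tournament")) {
    stopifnot(populationSize >= 2L, generations >= 0L,
              mutationRate >= 0, mutationRate <= 1,
              offspringPerGeneration >= 1L,
              founderMutationRate >= 0, founderMutationRate <= 1)
    structure(list(populationSize = as.integer(populationSize),
                   generations = as.integer(generations),
                   mutationRate = mutationRate,
                   offspringPerGeneration = as.integer(offspringPerGeneration),
                   founderMutationRate = founderMutationRate,
                   rngSeed = as.integer(rngSeed),
                   selection = match.arg(selection)),
              class = "GAConfig")
}

#' Number of sequences evaluated by a run
#'
#' The evaluated-sequence accounting: population size times generations.
#'
#' @param populationSize Individuals per generation, or a `GAConfig`.
#' @param generations Number of generations (ignored when a config is
#'   given).
#' @return Numeric scalar.
#' @export
#' @examples
#' countEvaluated(600, 2000)  # 1.2e6
countEvaluated <- function(populationSize, generations = NULL) {
    if (inherits(populationSize, "GAConfig")) {
        generations <- populationSize$generations
        populationSize <- populationSize$populationSize
    }
    as.numeric(populationSize) * as.numeric(generations)
}

#' Select two distinct parents, biased towards low Pareto rank
#'
#' Under the `"rank"` scheme individuals are sampled without replacement
#' with weight 1/rank, so selection probability is strictly decreasing in
#' rank; `"tournament"` picks each parent as the lower-ranked of two
#' uniform draws (ties uniform).
#'
#' @param pop A [Population-class] (only its size is used).
#' @param ranking A [ParetoRanking-class] for the population.
#' @param scheme `"rank"` or `"tournament"`.
#' @return Integer vector of two distinct indices into the population.
#' @export
selectParents <- function(pop, ranking, scheme = c("rank", "tournament")) {
    stopifnot(is(pop, "Population"), is(ranking, "ParetoRanking"))
    scheme <- match.arg(scheme)
    n <- length(popSequences(pop))
    if (n < 2L) stop("need at least two individuals to select parents")
    ranks <- paretoRanks(ranking)
    if (scheme == "rank")
        return(sample.int(n, 2L, prob = 1 / ranks))
    pick <- function(exclude = 0L) {
        cand <- sample(setdiff(seq_len(n), exclude), 2L)
        if (ranks[cand[1]] < ranks[cand[2]]) cand[1]
        else if (ranks[cand[2]] < ranks[cand[1]]) cand[2]
        else cand[sample.int(2L, 1L)]
    }
    a <- pick()
    c(a, pick(exclude = a))
}

#' One-point crossover of two equal-length sequences
#'
#' The child takes positions 1..k from `a` and k+1..L from `b`, with the
#' cut point k uniform on 1..L-1 unless supplied. Because both parents
#' satisfy the fixed-position constraint, so does the child.
#'
#' @param a,b Parent sequences (equal length).
#' @param k Optional cut point in 1..L-1.
#' @return Child sequence.
#' @export
crossover1pt <- function(a, b, k = NULL) {
    L <- nchar(a)
    if (nchar(b) != L) stop("parent lengths differ (", L, " vs ", nchar(b), ")")
    if (L < 2L) stop("sequences too short for crossover")
    if (is.null(k)) k <- sample.int(L - 1L, 1L)
    stopifnot(k >= 1L, k < L)
    paste0(substr(a, 1L, k), substr(b, k + 1L, L))
}

#' Constrained mutation of a candidate sequence
#'
#' Every free (non-conserved) position is independently substituted with
#' probability `rate` by a uniformly chosen *different* residue; conserved
#' positions never change.
#'
#' @param seq Candidate sequence satisfying the template.
#' @param template A [DesignTemplate-class].
#' @param rate Per-free-position substitution probability.
#' @return Mutated sequence.
#' @export
mutateSequence <- function(seq, template, rate = 0.01) {
    stopifnot(is(template, "DesignTemplate"), rate >= 0, rate <= 1)
    if (rate == 0) return(seq)
    res <- strsplit(seq, "", fixed = TRUE)[[1]]
    free <- setdiff(seq_along(res), fixedPositions(template))
    if (!length(free)) return(seq)
    hit <- free[stats::runif(length(free)) < rate]
    if (length(hit)) {
        aa <- aminoAcids()
        for (i in hit) {
            alt <- aa[aa != res[i]]
            res[i] <- alt[sample.int(19L, 1L)]
        }
    }
    paste(res, collapse = "")
}

# elitist truncation order: rank, then best first objective, then stable
.truncationOrder <- function(ranks, fit) {
    order(ranks, -fit[, 1L], seq_along(ranks))
}

#' Run the multiobjective genetic algorithm
#'
#' Per generation: parents are selected with probability decreasing in
#' Pareto rank, recombined by one-point crossover, mutated at free
#' positions, and evaluated; parents and offspring are pooled, re-ranked,
#' and the pool is truncated elitistically (by rank, ties broken on the
#' first objective, then stably) back to the fixed population size.
#' The founder population consists of copies of the seed mutated at free
#' positions with `founderMutationRate`.
#'
#' All randomness flows from `cfg$rngSeed`; identical configurations give
#' bitwise-identical runs.
#'
#' @param template A [DesignTemplate-class].
#' @param cfg A [gaConfig()].
#' @param fitnessFun Function `character vector -> numeric matrix` mapping
#'   sequences to fitness rows (larger = better). Defaults to the
#'   three-objective evaluator via [evaluateFitnessBatch()] with `...`
#'   passed through.
#' @param ... Passed to [evaluateFitnessBatch()] when `fitnessFun` is
#'   `NULL` (predictor, alignment params, tables, window).
#' @param verbose Print a progress line every 10 generations.
#' @param keepFrontiers Also return the rank-1 fitness matrix of every
#'   generation (for frontier-regression diagnostics).
#' @return List with elements `population` (final [Population-class],
#'   ranked), `ranking` (its [ParetoRanking-class]) and `history`
#'   (data.frame: generation, frontierSize, best per objective,
#'   evaluations so far); with `keepFrontiers = TRUE` also `frontiers`,
#'   a list of per-generation rank-1 fitness matrices.
#' @export
evolve <- function(template, cfg, fitnessFun = NULL, ..., verbose = FALSE,
                   keepFrontiers = FALSE) {
    stopifnot(is(template, "DesignTemplate"), inherits(cfg, "GAConfig"))
    if (is.null(fitnessFun))
        fitnessFun <- function(seqs)
            evaluateFitnessBatch(seqs, template, ...)
    set.seed(cfg$rngSeed)
    n <- cfg$populationSize

    seqs <- vapply(seq_len(n), function(i)
        mutateSequence(seedSequence(template), template,
                       cfg$founderMutationRate), character(1))
    fit <- fitnessFun(seqs)
    if (!is.matrix(fit) || nrow(fit) != n)
        stop("fitness closure must return one row per sequence")
    ranking <- paretoRank(fit)

    history <- vector("list", cfg$generations + 1L)
    frontierFits <- if (keepFrontiers) vector("list", cfg$generations + 1L)
    record <- function(g) {
        best <- apply(fit, 2L, max)
        names(best) <- paste0("best_", colnames(fit))
        c(list(generation = g,
               frontierSize = length(paretoFrontiers(ranking)[[1]])),
          as.list(best),
          list(evaluations = countEvaluated(n, g + 1L)))
    }
    history[[1L]] <- record(0L)
    if (keepFrontiers)
        frontierFits[[1L]] <- fit[paretoFrontiers(ranking)[[1]], ,
                                  drop = FALSE]

    for (g in seq_len(cfg$generations)) {
        pop <- Population(seqs, fit, paretoRanks(ranking), g - 1L)
        offspring <- vapply(seq_len(cfg$offspringPerGeneration),
            function(i) {
                p <- selectParents(pop, ranking, cfg$selection)
                mutateSequence(crossover1pt(seqs[p[1]], seqs[p[2]]),
                               template, cfg$mutationRate)
            }, character(1))
        offFit <- tryCatch(fitnessFun(offspring), error = function(e)
            stop("fitness evaluation failed at generation ", g, ": ",
                 conditionMessage(e), call. = FALSE))
        poolSeqs <- c(seqs, offspring)
        poolFit <- rbind(fit, offFit)
        poolRanks <- paretoRanks(paretoRank(poolFit))
        keep <- .truncationOrder(poolRanks, poolFit)[seq_len(n)]
        seqs <- poolSeqs[keep]
        fit <- poolFit[keep, , drop = FALSE]
        ranking <- paretoRank(fit)
        history[[g + 1L]] <- record(g)
        if (keepFrontiers)
            frontierFits[[g + 1L]] <- fit[paretoFrontiers(ranking)[[1]], ,
                                          drop = FALSE]
        if (verbose && g %% 10L == 0L)
            message("generation ", g, ": frontier ",
                    length(paretoFrontiers(ranking)[[1]]))
    }

    out <- list(population = Population(seqs, fit, paretoRanks(ranking),
                                        cfg$generations),
                ranking = ranking,
                history = do.call(rbind, lapply(history, as.data.frame)))
    if (keepFrontiers) out$frontiers <- frontierFits
    out
}
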