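test_that("dominance follows the strict-partial-order definition", {
    expect_true(dominates(c(3, 1, 2), c(3, 1, 1)))
    expect_false(dominates(c(4, 0, 2), c(3, 1, 2)))
    expect_false(dominates(c(3, 1, 2), c(4, 0, 2)))
    expect_false(dominates(c(4, 0, 2), c(3, 1, 1)))
    expect_false(dominates(c(3, 1, 2), c(3, 1, 2)))  # irreflexive
    expect_error(dominates(c(1, 2), c(1, 2, 3)), "arity")
})

test_that("dominance is irreflexive, antisymmetric and transitive on random vectors", {
    set.seed(5)
    for (i in 1:200) {
        x <- sample(0:3, 3, TRUE); y <- sample(0:3, 3, TRUE)
        z <- sample(0:3, 3, TRUE)
        expect_false(dominates(x, x))
        if (dominates(x, y)) expect_false(dominates(y, x))
        if (dominates(x, y) && dominates(y, z))
            expect_true(dominates(x, z))
    }
})

test_that("frontier peeling reproduces the worked three-vector example", {
    fit <- rbind(c(3, 1, 2), c(3, 1, 1), c(4, 0, 2))
    r <- paretoRank(fit)
    expect_equal(paretoRanks(r), c(1L, 2L, 1L))
    expect_equal(paretoFrontiers(r), list(c(1L, 3L), 2L))
    single <- paretoRank(matrix(c(1, 2, 3), 1))
    expect_equal(paretoRanks(single), 1L)
    expect_error(paretoRank(matrix(numeric(0), 0, 3)), "empty")
})

test_that("ranking equals the brute-force oracle on random sets", {
    set.seed(21)
    for (i in 1:30) {
        n <- sample(2:50, 1)
        fit <- matrix(rnorm(n * 3), n)
        expect_equal(paretoRanks(paretoRank(fit)), bruteParetoRanks(fit))
    }
    # with heavy ties/duplicates from a small lattice
    for (i in 1:30) {
        n <- sample(2:30, 1)
        fit <- matrix(sample(0:2, n * 3, TRUE), n)
        expect_equal(paretoRanks(paretoRank(fit)), bruteParetoRanks(fit))
    }
})

test_that("parent selection is uniform when all ranks are equal", {
    pop <- Population(rep("AAAA", 10))
    ranking <- new("ParetoRanking", ranks = rep(1L, 10),
                   frontiers = list(1:10))
    set.seed(1)
    draws <- replicate(2e4, selectParents(pop, ranking))
    expect_true(all(draws[1, ] != draws[2, ]))  # always two distinct parents
    counts <- tabulate(draws, 10)
    expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("1/rank weighting selects rank-1 parents about twice as often", {
    pop <- Population(rep("AAAA", 100))
    ranks <- rep(c(1L, 2L), each = 50)
    ranking <- new("ParetoRanking", ranks = ranks,
                   frontiers = list(1:50, 51:100))
    set.seed(2)
    draws <- replicate(2e4, selectParents(pop, ranking))
    ratio <- sum(ranks[draws] == 1L) / sum(ranks[draws] == 2L)
    expect_gt(ratio, 1.85)
    expect_lt(ratio, 2.15)
})

test_that("selection is deterministic under a fixed seed", {
    pop <- Population(rep("AAAA", 20))
    ranking <- paretoRank(matrix(rnorm(60), 20))
    set.seed(33); a <- replicate(50, selectParents(pop, ranking))
    set.seed(33); b <- replicate(50, selectParents(pop, ranking))
    expect_identical(a, b)
})

test_that("one-point crossover splices prefix and suffix", {
    expect_equal(crossover1pt("AAAA", "CCCC", k = 2), "AACC")
    expect_equal(crossover1pt("MKVL", "MKVL", k = 3), "MKVL")
    a <- "ACDEFG"; b <- "HIKLMN"
    for (k in 1:5)
        expect_equal(crossover1pt(a, b, k),
                     paste0(substr(a, 1, k), substr(b, k + 1, 6)))
    expect_error(crossover1pt("AAA", "AAAA"), "lengths differ")
})

test_that("mutation respects the conserved mask and the rate semantics", {
    tpl <- designTemplate("ACDEFGHIKLMNPQRSTVWY", fixed = c(1, 10, 20))
    seed <- seedSequence(tpl)
    expect_identical(mutateSequence(seed, tpl, 0), seed)
    set.seed(4)
    m1 <- mutateSequence(seed, tpl, 1)
    a <- strsplit(m1, "")[[1]]; s <- strsplit(seed, "")[[1]]
    free <- setdiff(1:20, c(1, 10, 20))
    expect_true(all(a[free] != s[free]))        # every free position differs
    expect_equal(a[c(1, 10, 20)], s[c(1, 10, 20)])
    # binomial expectation at a moderate rate
    set.seed(8)
    nmut <- replicate(2000, {
        m <- strsplit(mutateSequence(seed, tpl, 0.1), "")[[1]]
        sum(m != s)
    })
    expect_equal(mean(nmut), 0.1 * 17, tolerance = 0.1)
})

test_that("evaluated-sequence accounting multiplies population by generations", {
    expect_equal(countEvaluated(8, 15), 120)
    expect_equal(countEvaluated(1, 1), 1)
    expect_equal(countEvaluated(gaConfig(populationSize = 10,
                                         generations = 7)), 70)
})

test_that("zero generations returns the evaluated founders unchanged", {
    tpl <- simulateTemplate(seqLength = 20, nFixed = 4, rngSeed = 2)
    cfg <- gaConfig(populationSize = 10, generations = 0, rngSeed = 9)
    res <- evolve(tpl, cfg)
    expect_length(popSequences(res$population), 10)
    expect_equal(res$population@generation, 0L)
    expect_equal(nrow(res$history), 1L)
    # founders are deterministic reruns of the same seed
    res2 <- evolve(tpl, cfg)
    expect_identical(popSequences(res$population),
                     popSequences(res2$population))
})

test_that("constant fitness puts the whole population on the first frontier", {
    tpl <- simulateTemplate(seqLength = 15, nFixed = 3, rngSeed = 3)
    cfg <- gaConfig(populationSize = 12, generations = 3, rngSeed = 1)
    res <- evolve(tpl, cfg,
                  fitnessFun = function(seqs)
                      matrix(1, length(seqs), 2,
                             dimnames = list(NULL, c("a", "b"))))
    expect_true(all(res$history$frontierSize == 12))
})

test_that("the GA climbs a single-objective toy fitness to its optimum", {
    tpl <- designTemplate(strrep("C", 20), fixed = c(1, 2, 3, 4))
    countA <- function(seqs) {
        free <- setdiff(1:20, fixedPositions(tpl))
        matrix(vapply(seqs, function(s)
            sum(strsplit(s, "")[[1]][free] == "A"), numeric(1)),
            dimnames = list(NULL, "nA"))
    }
    cfg <- gaConfig(populationSize = 50, generations = 100,
                    mutationRate = 0.05, rngSeed = 42)
    res <- evolve(tpl, cfg, fitnessFun = countA)
    expect_true(all(diff(res$history$best_nA) >= 0))  # elitist: never regresses
    expect_equal(max(res$history$best_nA), 16)        # free-position maximum
})

test_that("every individual in every generation satisfies the constraints", {
    tpl <- simulateTemplate(seqLength = 25, nFixed = 8, rngSeed = 6)
    seen <- character(0)
    wrapped <- function(seqs) {
        seen <<- c(seen, seqs)
        evaluateFitnessBatch(seqs, tpl)
    }
    cfg <- gaConfig(populationSize = 20, generations = 10, rngSeed = 5)
    res <- evolve(tpl, cfg, fitnessFun = wrapped)
    expect_gt(length(seen), 20 * 10)
    expect_true(all(vapply(seen, validateSequence, logical(1),
                           template = tpl)))
})

test_that("identical seeds give bitwise-identical runs", {
    tpl <- simulateTemplate(seqLength = 20, nFixed = 5, rngSeed = 8)
    cfg <- gaConfig(populationSize = 15, generations = 8, rngSeed = 123)
    r1 <- evolve(tpl, cfg)
    r2 <- evolve(tpl, cfg)
    expect_identical(popSequences(r1$population), popSequences(r2$population))
    expect_identical(r1$history, r2$history)
    expect_identical(popFitness(r1$population), popFitness(r2$population))
})
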