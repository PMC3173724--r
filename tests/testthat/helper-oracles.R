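# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the alignment oracle enumerates matched-column
# sets instead of running dynamic programming, and the Pareto oracle peels
# with scalar pairwise comparisons instead of vectorized dominance.

# Exhaustive local alignment with linear gap penalties: every local
# alignment is a strictly increasing set of matched column pairs
# (i_1..i_k) ~ (j_1..j_k); internal skipped characters each cost `gap`,
# characters outside the aligned region are free. The empty alignment
# scores 0.
bruteLocalAlign <- function(a, b, match = 2, mismatch = -1, gap = -2) {
    A <- strsplit(a, "", fixed = TRUE)[[1]]
    B <- strsplit(b, "", fixed = TRUE)[[1]]
    m <- length(A); n <- length(B)
    best <- 0
    for (k in seq_len(min(m, n))) {
        ia <- utils::combn(m, k, simplify = FALSE)
        ib <- utils::combn(n, k, simplify = FALSE)
        for (i in ia) {
            gi <- sum(diff(i) - 1L)
            for (j in ib) {
                s <- sum(ifelse(A[i] == B[j], match, mismatch)) +
                    gap * (gi + sum(diff(j) - 1L))
                if (s > best) best <- s
            }
        }
    }
    best
}

# O(n^2 d) frontier peeling with scalar comparisons
bruteParetoRanks <- function(fit) {
    n <- nrow(fit)
    ranks <- rep(NA_integer_, n)
    r <- 0L
    remaining <- seq_len(n)
    while (length(remaining)) {
        r <- r + 1L
        nd <- Filter(function(i) {
            for (j in remaining)
                if (j != i && all(fit[j, ] >= fit[i, ]) &&
                    any(fit[j, ] > fit[i, ])) return(FALSE)
            TRUE
        }, remaining)
        ranks[nd] <- r
        remaining <- setdiff(remaining, nd)
    }
    ranks
}

randomSeq <- function(n) paste(sample(aminoAcids(), n, TRUE), collapse = "")

randomSS <- function(n) paste(sample(c("H", "E", "C"), n, TRUE), collapse = "")

# dense trapezoid quadrature of the natural interpolating spline
quadratureIntegral <- function(profile, grid = 2e5L) {
    f <- stats::splinefun(seq_along(profile), profile, method = "natural")
    x <- seq(1, length(profile), length.out = grid)
    y <- f(x)
    sum((y[-1] + y[-grid]) / 2 * diff(x))
}
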