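#' @importFrom Biostrings pairwiseAlignment BString BStringSet
NULL

# truncated-window running mean: value at i is the mean of v over the
# window of width `window` centred at i, shrunk at the termini so that
# the profile keeps exactly length(v) points
.windowMean <- function(v, window) {
    n <- length(v)
    h <- (window - 1L) %/% 2L
    cs <- c(0, cumsum(v))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# ---------------------------------------------------------------------------
# Secondary-structure predictors (contract: function(seq) -> state string)

#' Built-in windowed-propensity secondary-structure predictor
#'
#' A deterministic three-state baseline: for each position the helix,
#' sheet and coil propensities (classic conformational propensity
#' constants, see [propensityTable()]) are averaged over a truncated
#' window, and the state with the highest mean wins. Ties break in the
#' fixed order H, then E, then C, so predictions are fully deterministic.
#'
#' This baseline stands behind the pluggable predictor contract used by
#' the fitness function; any `function(seq) -> state string` over
#' \{H,E,C\} can be substituted (e.g. [externalPredictor()] wrapping a
#' neural-network tool).
#'
#' @param window Odd window width (default 5).
#' @param propensities 20 x 3 matrix with columns `H`, `E`, `C`.
#' @return A predictor function.
#' @export
#' @examples
#' p <- propensityPredictor()
#' p(strrep("A", 20))  # all-helix for poly-alanine
propensityPredictor <- function(window = 5L, propensities = propensityTable()) {
    stopifnot(window >= 1L, window %% 2L == 1L)
    force(propensities)
    function(seq) {
        res <- strsplit(seq, "", fixed = TRUE)[[1]]
        w <- min(window, length(res))
        if (w %% 2L == 0L) w <- w - 1L
        means <- vapply(c("H", "E", "C"),
                        function(s) .windowMean(propensities[res, s], w),
                        numeric(length(res)))
        if (length(res) == 1L) means <- matrix(means, nrow = 1L)
        paste(c("H", "E", "C")[max.col(means, ties.method = "first")],
              collapse = "")
    }
}

#' Constant-state stub predictor
#'
#' Predicts the same state at every position; intended for tests and for
#' isolating the profile objectives from the structure objective.
#'
#' @param state One of `"H"`, `"E"`, `"C"`.
#' @return A predictor function.
#' @export
constantPredictor <- function(state = "C") {
    stopifnot(state %in% ssStates())
    function(seq) strrep(state, nchar(seq))
}

#' External-command secondary-structure predictor
#'
#' Wraps any external program that reads a single-record FASTA on stdin
#' and writes the three-state string to stdout.
#'
#' @param command Shell command to run.
#' @return A predictor function.
#' @export
externalPredictor <- function(command) {
    force(command)
    function(seq) {
        out <- tryCatch(
            system(command, input = c(">query", seq), intern = TRUE),
            error = function(e) stop("external predictor failed: ",
                                     conditionMessage(e), call. = FALSE))
        paste(trimws(out), collapse = "")
    }
}

#' Resolve a predictor spec string into a predictor function
#'
#' Accepts `"propensity"`, `"constant:<X>"` or `"external:<command>"`,
#' matching the `ss_predictor` config key.
#'
#' @param spec Character scalar.
#' @return A predictor function.
#' @export
resolvePredictor <- function(spec) {
    if (is.function(spec)) return(spec)
    stopifnot(is.character(spec), length(spec) == 1L)
    if (spec == "propensity") return(propensityPredictor())
    if (startsWith(spec, "constant:"))
        return(constantPredictor(sub("^constant:", "", spec)))
    if (startsWith(spec, "external:"))
        return(externalPredictor(sub("^external:", "", spec)))
    stop("unknown predictor spec: '", spec, "'")
}

#' Predict secondary structure for a sequence
#'
#' Applies a predictor under the contract checks: the input must be a
#' non-empty canonical sequence and the output must be a \{H,E,C\}
#' string of the same length. Predictor failures are rethrown as
#' prediction errors carrying the predictor's diagnostic.
#'
#' @param seq Amino-acid sequence.
#' @param predictor Predictor function (default: the built-in
#'   windowed-propensity baseline).
#' @return State string over \{H,E,C\}, one state per residue.
#' @export
predictSS <- function(seq, predictor = propensityPredictor()) {
    msg <- .checkSeq(seq)
    if (!is.null(msg)) stop(msg)
    ss <- tryCatch(predictor(seq), error = function(e)
        stop("secondary-structure prediction failed: ",
             conditionMessage(e), call. = FALSE))
    msg <- .checkSS(ss, "predicted states")
    if (!is.null(msg)) stop(msg)
    if (nchar(ss) != nchar(seq))
        stop("predictor returned ", nchar(ss), " states for ",
             nchar(seq), " residues")
    ss
}

# ---------------------------------------------------------------------------
# Secondary-structure alignment score

#' Alignment parameters for the three-state structure alignment
#'
#' Linear gap model: match reward, mismatch penalty and per-position gap
#' penalty for the Smith-Waterman local alignment of \{H,E,C\} strings.
#'
#' @param match Positive match reward (default 2).
#' @param mismatch Non-positive mismatch score (default -1).
#' @param gap Non-positive per-gap-position score (default -2).
#' @return Named list of class `AlignmentParams`.
#' @export
alignmentParams <- function(match = 2, mismatch = -1, gap = -2) {
    stopifnot(is.numeric(match), match > 0,
              is.numeric(mismatch), mismatch <= 0,
              is.numeric(gap), gap <= 0)
    structure(list(match = match, mismatch = mismatch, gap = gap),
              class = "AlignmentParams")
}

.ssSubMatrix <- function(params) {
    m <- matrix(params$mismatch, 3L, 3L,
                dimnames = list(ssStates(), ssStates()))
    diag(m) <- params$match
    m
}

#' Smith-Waterman score of two secondary-structure strings (batch)
#'
#' Optimal local-alignment scores of each query state string against one
#' target, over the three-letter alphabet with linear gap penalties.
#' The score is non-negative (the empty local alignment scores 0).
#'
#' @param queries Character vector of \{H,E,C\} strings.
#' @param target Single \{H,E,C\} string.
#' @param params [alignmentParams()].
#' @return Numeric vector of scores.
#' @export
ssAlignmentScores <- function(queries, target, params = alignmentParams()) {
    stopifnot(length(queries) >= 1L)
    for (q in unique(c(queries, target))) {
        msg <- .checkSS(q)
        if (!is.null(msg)) stop(msg)
        if (nchar(q) == 0L) stop("alignment inputs must be non-empty")
    }
    s <- pairwiseAlignment(BStringSet(queries), BString(target),
                           substitutionMatrix = .ssSubMatrix(params),
                           gapOpening = 0, gapExtension = -params$gap,
                           type = "local", scoreOnly = TRUE)
    pmax(s, 0)
}

#' Smith-Waterman score of two secondary-structure strings
#'
#' @param queryStates,targetStates \{H,E,C\} strings (order is
#'   irrelevant: the score is symmetric).
#' @param params [alignmentParams()].
#' @return Non-negative numeric scalar.
#' @export
#' @examples
#' ssAlignmentScore("HHCEE", "CHHEE")           # 6 with the defaults
#' ssAlignmentScore("HHHH", "EEEE")             # 0: nothing aligns
ssAlignmentScore <- function(queryStates, targetStates,
                             params = alignmentParams()) {
    ssAlignmentScores(queryStates, targetStates, params)[1]
}

# ---------------------------------------------------------------------------
# Windowed property profiles and spline integrals

#' Sliding-window property profile of a sequence
#'
#' Value at position i is the mean property value over the window of odd
#' width `window` centred at i; at the termini the window is truncated,
#' so the profile has exactly one value per residue.
#'
#' @param seq Amino-acid sequence.
#' @param table A [PropertyTable-class].
#' @param window Odd window width not exceeding the sequence length
#'   (default 7, the standard hydropathy-plot window).
#' @return Numeric vector, one value per residue (scale units).
#' @export
windowedProfile <- function(seq, table, window = 7L) {
    msg <- .checkSeq(seq)
    if (!is.null(msg)) stop(msg)
    stopifnot(is(table, "PropertyTable"))
    n <- nchar(seq)
    if (window %% 2L == 0L || window < 1L)
        stop("window must be a positive odd integer")
    if (window > n)
        stop("window (", window, ") exceeds sequence length (", n, ")")
    v <- table@values[strsplit(seq, "", fixed = TRUE)[[1]]]
    .windowMean(unname(v), window)
}

#' Definite integral of the natural-spline interpolant of a profile
#'
#' Fits a natural cubic spline through the points (i, value_i),
#' i = 1..n, and integrates it exactly over the profile support [1, n]
#' (two-point Gauss-Legendre per knot interval, exact for cubics).
#'
#' @param profile Numeric vector of profile values (length >= 2).
#' @return Numeric scalar (scale units x residues).
#' @export
#' @examples
#' profileIntegral(rep(2, 10))    # constant: 2 * 9
#' profileIntegral(seq(0, 1, length.out = 5))  # linear ramp: 2
profileIntegral <- function(profile) {
    n <- length(profile)
    if (n < 2L) stop("profile must have at least 2 points")
    if (!all(is.finite(profile))) stop("profile values must be finite")
    f <- stats::splinefun(seq_len(n), profile, method = "natural")
    mid <- seq_len(n - 1L) + 0.5
    h <- 0.5 / sqrt(3)
    sum(0.5 * (f(mid - h) + f(mid + h)))
}

#' Profile-integral difference between a query and the template target
#'
#' The absolute difference between the spline integral of the query's
#' windowed property profile and the target integral stored in the
#' template; zero when the query reproduces the profile-defining target
#' sequence.
#'
#' @param querySeq Query amino-acid sequence.
#' @param template A [DesignTemplate-class].
#' @param table Property table; must correspond to `objective`.
#' @param window Odd window width (default 7).
#' @param objective Which stored target integral to compare against.
#' @return Non-negative numeric scalar.
#' @export
integralDifferenceScore <- function(querySeq, template,
                                    table = hydrophobicityTable(),
                                    window = 7L,
                                    objective = c("hydrophobicity",
                                                  "molecularWeight")) {
    stopifnot(is(template, "DesignTemplate"))
    objective <- match.arg(objective)
    target <- targetIntegrals(template)[[objective]]
    abs(profileIntegral(windowedProfile(querySeq, table, window)) - target)
}

# ---------------------------------------------------------------------------
# Combined fitness

#' Evaluate the three-objective fitness vector of one candidate
#'
#' Components, all oriented so that larger is better for Pareto
#' dominance:
#' \enumerate{
#'   \item local-alignment score of the candidate's predicted secondary
#'     structure against the template target structure;
#'   \item minus the hydropathy profile-integral difference;
#'   \item minus the molecular-weight profile-integral difference.
#' }
#'
#' @param seq Candidate sequence; must pass [validateSequence()].
#' @param template A [DesignTemplate-class].
#' @param predictor Secondary-structure predictor.
#' @param params [alignmentParams()].
#' @param hydroTable,mwTable Property tables.
#' @param window Odd window width (default 7).
#' @return Named numeric vector `c(ss, hydro, mw)`.
#' @export
evaluateFitness <- function(seq, template,
                            predictor = propensityPredictor(),
                            params = alignmentParams(),
                            hydroTable = hydrophobicityTable(),
                            mwTable = molecularWeightTable(),
                            window = 7L) {
    evaluateFitnessBatch(seq, template, predictor, params, hydroTable,
                         mwTable, window)[1L, ]
}

#' Evaluate fitness for many candidates at once
#'
#' Batch version of [evaluateFitness()]; alignment scores are computed in
#' one vectorized pass, which is what makes full-size generations cheap.
#'
#' @param seqs Character vector of candidate sequences.
#' @inheritParams evaluateFitness
#' @return Numeric matrix `length(seqs)` x 3, columns `ss`, `hydro`, `mw`.
#' @export
evaluateFitnessBatch <- function(seqs, template,
                                 predictor = propensityPredictor(),
                                 params = alignmentParams(),
                                 hydroTable = hydrophobicityTable(),
                                 mwTable = molecularWeightTable(),
                                 window = 7L) {
    stopifnot(is(template, "DesignTemplate"), length(seqs) >= 1L)
    ok <- vapply(seqs, validateSequence, logical(1), template = template)
    if (!all(ok))
        stop(sum(!ok), " candidate(s) violate the template constraints")
    ss <- vapply(seqs, function(s) predictSS(s, predictor), character(1))
    scores <- ssAlignmentScores(ss, targetSS(template), params)
    ti <- targetIntegrals(template)
    hd <- vapply(seqs, function(s)
        abs(profileIntegral(windowedProfile(s, hydroTable, window)) -
            ti[["hydrophobicity"]]), numeric(1))
    md <- vapply(seqs, function(s)
        abs(profileIntegral(windowedProfile(s, mwTable, window)) -
            ti[["molecularWeight"]]), numeric(1))
    cbind(ss = scores, hydro = -hd, mw = -md)
}
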