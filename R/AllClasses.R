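#' @import methods
NULL

#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter residue codes, alphabetically ordered.
#' Non-canonical codes (B, J, O, U, X, Z) are rejected throughout the
#' package: the scoring tables carry no values for them.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Secondary-structure alphabet
#'
#' Three-state alphabet: H (alpha-helix), E (beta-sheet), C (loop/coil).
#'
#' @return Character vector of length 3.
#' @export
ssStates <- function() c("H", "E", "C")

.checkSeq <- function(seq, what = "sequence") {
    if (!is.character(seq) || length(seq) != 1L || is.na(seq))
        return(sprintf("%s must be a single character string", what))
    if (nchar(seq) == 0L)
        return(sprintf("%s is empty", what))
    bad <- setdiff(strsplit(seq, "", fixed = TRUE)[[1]], aminoAcids())
    if (length(bad))
        return(sprintf("%s contains non-canonical residue(s): %s",
                       what, paste(unique(bad), collapse = ", ")))
    NULL
}

.checkSS <- function(ss, what = "secondary-structure string") {
    if (!is.character(ss) || length(ss) != 1L || is.na(ss))
        return(sprintf("%s must be a single character string", what))
    bad <- setdiff(strsplit(ss, "", fixed = TRUE)[[1]], ssStates())
    if (length(bad))
        return(sprintf("%s contains states outside {H,E,C}: %s",
                       what, paste(unique(bad), collapse = ", ")))
    NULL
}

# ---------------------------------------------------------------------------
# PropertyTable

#' PropertyTable: one numeric value per canonical residue
#'
#' A named amino-acid property scale, e.g. Kyte-Doolittle hydropathy
#' (dimensionless) or average residue mass (Da). Exactly one finite value
#' per canonical residue is required.
#'
#' @slot name Single character label for the scale.
#' @slot values Named numeric vector of length 20 keyed by one-letter codes.
#'
#' @seealso [hydrophobicityTable()], [molecularWeightTable()],
#'   [readPropertyTable()]
#' @export
setClass("PropertyTable",
    representation(name = "character", values = "numeric"),
    validity = function(object) {
        msg <- character()
        if (length(object@name) != 1L)
            msg <- c(msg, "'name' must be a single string")
        v <- object@values
        if (length(v) != 20L || !setequal(names(v), aminoAcids()) ||
            anyDuplicated(names(v)))
            msg <- c(msg, "'values' must carry exactly the 20 canonical residues")
        if (!all(is.finite(v)))
            msg <- c(msg, "all property values must be finite")
        if (length(msg)) msg else TRUE
    })

#' Construct a PropertyTable
#'
#' @param name Label for the scale.
#' @param values Named numeric vector over the 20 canonical one-letter codes.
#' @return A [PropertyTable-class] object.
#' @export
PropertyTable <- function(name, values) {
    new("PropertyTable", name = name,
        values = values[order(names(values))])
}

#' @describeIn PropertyTable-class value lookup for a residue vector
#' @param x A `PropertyTable`.
#' @param residues Character vector of one-letter codes.
#' @export
propertyValues <- function(x, residues = NULL) {
    stopifnot(is(x, "PropertyTable"))
    if (is.null(residues)) x@values else unname(x@values[residues])
}

setMethod("show", "PropertyTable", function(object) {
    cat("PropertyTable:", object@name, "\n")
    print(round(object@values, 4))
})

# ---------------------------------------------------------------------------
# DesignTemplate

#' DesignTemplate: the constrained design problem
#'
#' Holds the fusion seed sequence, the set of conserved (never-mutated)
#' positions, and the target profiles the three objectives compare against:
#' a secondary-structure string over {H,E,C} and the hydropathy and
#' molecular-weight spline integrals of the seed.
#'
#' All residue positions are 1-based, matching standard residue numbering.
#'
#' @slot seed Seed amino-acid sequence (single string).
#' @slot fixedPositions Sorted integer vector of conserved 1-based positions.
#' @slot targetSS Target secondary-structure string, same length as seed.
#' @slot targetHydroIntegral Target hydropathy profile integral
#'   (scale units x residues).
#' @slot targetMWIntegral Target molecular-weight profile integral
#'   (Da x residues).
#'
#' @seealso [buildFusionTemplate()], [validateSequence()], [evaluateFitness()]
#' @export
setClass("DesignTemplate",
    representation(seed = "character",
                   fixedPositions = "integer",
                   targetSS = "character",
                   targetHydroIntegral = "numeric",
                   targetMWIntegral = "numeric"),
    validity = function(object) {
        msg <- .checkSeq(object@seed, "seed")
        n <- nchar(object@seed)
        fp <- object@fixedPositions
        if (length(fp) && (any(fp < 1L) || any(fp > n)))
            msg <- c(msg, sprintf("fixed positions must lie in [1, %d]", n))
        if (anyDuplicated(fp))
            msg <- c(msg, "fixed positions must be unique")
        msg <- c(msg, .checkSS(object@targetSS, "targetSS"))
        if (is.null(.checkSS(object@targetSS)) &&
            nchar(object@targetSS) != n)
            msg <- c(msg, "targetSS length must equal seed length")
        for (s in c("targetHydroIntegral", "targetMWIntegral")) {
            v <- slot(object, s)
            if (length(v) != 1L || !is.finite(v))
                msg <- c(msg, sprintf("'%s' must be a single finite number", s))
        }
        if (length(msg)) msg else TRUE
    })

#' @describeIn DesignTemplate-class seed sequence accessor
#' @param x A `DesignTemplate`.
#' @export
seedSequence <- function(x) { stopifnot(is(x, "DesignTemplate")); x@seed }

#' @describeIn DesignTemplate-class conserved 1-based positions accessor
#' @export
fixedPositions <- function(x) { stopifnot(is(x, "DesignTemplate")); x@fixedPositions }

#' @describeIn DesignTemplate-class target secondary-structure accessor
#' @export
targetSS <- function(x) { stopifnot(is(x, "DesignTemplate")); x@targetSS }

#' @describeIn DesignTemplate-class target profile integrals, named vector
#' @export
targetIntegrals <- function(x) {
    stopifnot(is(x, "DesignTemplate"))
    c(hydrophobicity = x@targetHydroIntegral,
      molecularWeight = x@targetMWIntegral)
}

setMethod("show", "DesignTemplate", function(object) {
    n <- nchar(object@seed)
    cat("DesignTemplate of length", n, "\n")
    cat("  seed:", if (n <= 60) object@seed else
        paste0(substr(object@seed, 1, 57), "..."), "\n")
    cat("  fixed positions (", length(object@fixedPositions), "): ",
        paste(object@fixedPositions, collapse = ","), "\n", sep = "")
    cat("  target integrals: hydropathy ",
        signif(object@targetHydroIntegral, 6), ", molecular weight ",
        signif(object@targetMWIntegral, 6), "\n", sep = "")
})

# ---------------------------------------------------------------------------
# Population / ParetoRanking

#' Population: a fixed-size generation of candidate sequences
#'
#' Sequences are stored as a character vector; the fitness matrix has one
#' row per individual and one column per objective (all oriented so larger
#' is better), and `ranks` holds Pareto rank counts (1 = nondominated).
#' Fitness and ranks may be empty (length/nrow 0) before evaluation.
#'
#' @slot sequences Character vector of candidate sequences.
#' @slot fitness Numeric matrix, `length(sequences)` x n objectives, or 0-row.
#' @slot ranks Integer vector of Pareto ranks, or length 0.
#' @slot generation Non-negative generation counter.
#' @export
setClass("Population",
    representation(sequences = "character", fitness = "matrix",
                   ranks = "integer", generation = "integer"),
    prototype(fitness = matrix(numeric(0), 0, 0), ranks = integer(0),
              generation = 0L),
    validity = function(object) {
        msg <- character()
        n <- length(object@sequences)
        if (n == 0L) msg <- c(msg, "population is empty")
        if (nrow(object@fitness) != 0L && nrow(object@fitness) != n)
            msg <- c(msg, "fitness must have one row per individual")
        if (nrow(object@fitness) && !all(is.finite(object@fitness)))
            msg <- c(msg, "fitness values must be finite")
        if (length(object@ranks) != 0L && length(object@ranks) != n)
            msg <- c(msg, "ranks must have one entry per individual")
        if (length(object@ranks) && any(object@ranks < 1L))
            msg <- c(msg, "ranks must be positive")
        if (length(object@generation) != 1L || object@generation < 0L)
            msg <- c(msg, "generation must be a single non-negative integer")
        if (length(msg)) msg else TRUE
    })

#' Construct a Population
#' @param sequences Character vector of sequences.
#' @param fitness Optional fitness matrix (rows = individuals).
#' @param ranks Optional integer Pareto ranks.
#' @param generation Generation counter (default 0).
#' @return A [Population-class] object.
#' @export
Population <- function(sequences, fitness = NULL, ranks = NULL,
                       generation = 0L) {
    new("Population", sequences = sequences,
        fitness = if (is.null(fitness)) matrix(numeric(0), 0, 0) else fitness,
        ranks = if (is.null(ranks)) integer(0) else as.integer(ranks),
        generation = as.integer(generation))
}

#' @describeIn Population-class sequences accessor
#' @param x A `Population`.
#' @export
popSequences <- function(x) { stopifnot(is(x, "Population")); x@sequences }

#' @describeIn Population-class fitness matrix accessor
#' @export
popFitness <- function(x) { stopifnot(is(x, "Population")); x@fitness }

#' @describeIn Population-class Pareto rank accessor
#' @export
popRanks <- function(x) { stopifnot(is(x, "Population")); x@ranks }

setMethod("show", "Population", function(object) {
    cat("Population of", length(object@sequences), "individuals, generation",
        object@generation, "\n")
    if (length(object@ranks))
        cat("  Pareto frontier size:", sum(object@ranks == 1L), "\n")
})

#' ParetoRanking: frontier decomposition of a set of fitness vectors
#'
#' `ranks[i]` is the Pareto rank count of vector i (1 = first frontier,
#' i.e. nondominated); `frontiers` lists the index sets of successive
#' frontiers, which partition the input.
#'
#' @slot ranks Integer vector of positive ranks.
#' @slot frontiers List of integer index vectors, one per frontier.
#' @seealso [paretoRank()], [dominates()]
#' @export
setClass("ParetoRanking",
    representation(ranks = "integer", frontiers = "list"),
    validity = function(object) {
        msg <- character()
        n <- length(object@ranks)
        if (n == 0L) msg <- c(msg, "empty ranking")
        if (any(object@ranks < 1L)) msg <- c(msg, "ranks must be positive")
        idx <- sort(unlist(object@frontiers, use.names = FALSE))
        if (!identical(idx, seq_len(n)))
            msg <- c(msg, "frontiers must partition the index set")
        for (k in seq_along(object@frontiers))
            if (!all(object@ranks[object@frontiers[[k]]] == k))
                msg <- c(msg, "frontier membership inconsistent with ranks")
        if (length(msg)) msg else TRUE
    })

#' @describeIn ParetoRanking-class rank vector accessor
#' @param x A `ParetoRanking`.
#' @export
paretoRanks <- function(x) { stopifnot(is(x, "ParetoRanking")); x@ranks }

#' @describeIn ParetoRanking-class list of frontier index sets
#' @export
paretoFrontiers <- function(x) { stopifnot(is(x, "ParetoRanking")); x@frontiers }

setMethod("show", "ParetoRanking", function(object) {
    cat("ParetoRanking:", length(object@ranks), "vectors in",
        length(object@frontiers), "frontier(s); first frontier size",
        length(object@frontiers[[1]]), "\n")
})

# ---------------------------------------------------------------------------
# CaStructure / CaTrajectory

#' CaStructure: per-residue C-alpha coordinates
#'
#' @slot residueIds Strictly increasing integer residue numbers (1-based
#'   in the numbering of the source structure).
#' @slot coords Numeric matrix, one (x, y, z) row per residue, in Angstrom.
#' @seealso [readCaPdb()], [kabschSuperpose()], [regionRmsd()]
#' @export
setClass("CaStructure",
    representation(residueIds = "integer", coords = "matrix"),
    validity = function(object) {
        msg <- character()
        n <- length(object@residueIds)
        if (n == 0L) msg <- c(msg, "no residues")
        if (n > 1L && any(diff(object@residueIds) <= 0L))
            msg <- c(msg, "residueIds must be strictly increasing")
        if (!is.numeric(object@coords) || nrow(object@coords) != n ||
            ncol(object@coords) != 3L)
            msg <- c(msg, "coords must be an n x 3 numeric matrix")
        else if (!all(is.finite(object@coords)))
            msg <- c(msg, "coordinates must be finite")
        if (length(msg)) msg else TRUE
    })

#' Construct a CaStructure
#' @param residueIds Integer residue numbers (strictly increasing).
#' @param coords n x 3 coordinate matrix (Angstrom).
#' @return A [CaStructure-class] object.
#' @export
CaStructure <- function(residueIds, coords) {
    coords <- as.matrix(coords)
    dimnames(coords) <- list(NULL, c("x", "y", "z"))
    new("CaStructure", residueIds = as.integer(residueIds), coords = coords)
}

#' @describeIn CaStructure-class residue id accessor
#' @param x A `CaStructure` or `CaTrajectory`.
#' @export
residueIds <- function(x) x@residueIds

#' @describeIn CaStructure-class coordinate matrix accessor
#' @export
caCoords <- function(x) { stopifnot(is(x, "CaStructure")); x@coords }

setMethod("show", "CaStructure", function(object) {
    cat("CaStructure:", length(object@residueIds), "residues (",
        object@residueIds[1], "-", tail(object@residueIds, 1), ")\n")
})

#' CaTrajectory: multi-frame C-alpha coordinates over a shared residue set
#'
#' @slot residueIds Strictly increasing integer residue numbers shared by
#'   all frames.
#' @slot coords Numeric array n residues x 3 x n frames (Angstrom).
#' @slot times Strictly increasing frame times (ps).
#' @seealso [readCaPdb()], [rmsf()], [superposeTrajectory()]
#' @export
setClass("CaTrajectory",
    representation(residueIds = "integer", coords = "array",
                   times = "numeric"),
    validity = function(object) {
        msg <- character()
        n <- length(object@residueIds)
        d <- dim(object@coords)
        if (n > 1L && any(diff(object@residueIds) <= 0L))
            msg <- c(msg, "residueIds must be strictly increasing")
        if (length(d) != 3L || d[1] != n || d[2] != 3L)
            msg <- c(msg, "coords must be an n x 3 x frames array")
        else {
            if (!all(is.finite(object@coords)))
                msg <- c(msg, "coordinates must be finite")
            if (length(object@times) != d[3])
                msg <- c(msg, "one time per frame required")
        }
        if (length(object@times) > 1L && any(diff(object@times) <= 0))
            msg <- c(msg, "times must be strictly increasing")
        if (length(msg)) msg else TRUE
    })

#' Construct a CaTrajectory
#' @param residueIds Shared integer residue numbers.
#' @param frames List of n x 3 coordinate matrices, one per frame.
#' @param times Frame times in ps (default 1, 2, ...).
#' @return A [CaTrajectory-class] object.
#' @export
CaTrajectory <- function(residueIds, frames, times = seq_along(frames)) {
    arr <- array(unlist(lapply(frames, as.matrix)),
                 dim = c(length(residueIds), 3L, length(frames)),
                 dimnames = list(NULL, c("x", "y", "z"), NULL))
    new("CaTrajectory", residueIds = as.integer(residueIds), coords = arr,
        times = as.numeric(times))
}

#' @describeIn CaTrajectory-class number of frames
#' @param x A `CaTrajectory`.
#' @export
nFrames <- function(x) { stopifnot(is(x, "CaTrajectory")); dim(x@coords)[3] }

#' @describeIn CaTrajectory-class extract one frame as a CaStructure
#' @param i Frame index.
#' @export
trajFrame <- function(x, i) {
    stopifnot(is(x, "CaTrajectory"), i >= 1L, i <= nFrames(x))
    CaStructure(x@residueIds, x@coords[, , i, drop = TRUE])
}

#' @describeIn CaTrajectory-class frame times accessor (ps)
#' @export
frameTimes <- function(x) { stopifnot(is(x, "CaTrajectory")); x@times }

setMethod("show", "CaTrajectory", function(object) {
    cat("CaTrajectory:", dim(object@coords)[3], "frames,",
        length(object@residueIds), "residues\n")
})

# ---------------------------------------------------------------------------
# ReactionPairSet

#' ReactionPairSet: polar atom pairs defining the association criterion
#'
#' Cross-molecule polar atom pairs identified in a bound reference complex
#' at less than `defineCutoff` Angstrom. In a diffusional frame the
#' molecules count as associated when at least `minPairs` of these pairs
#' are closer than `fireCutoff` Angstrom.
#'
#' @slot pairs Integer matrix with columns `protein` and `dna` holding atom
#'   serial numbers; zero rows allowed.
#' @slot defineCutoff Distance (A) below which a pair is defined (default 4.5).
#' @slot fireCutoff Distance (A) below which a defined pair counts as in
#'   contact during the association test (default 5.5).
#' @slot minPairs Minimum number of in-contact pairs for association
#'   (default 3).
#' @seealso [defineReactionPairs()], [associationTest()]
#' @export
setClass("ReactionPairSet",
    representation(pairs = "matrix", defineCutoff = "numeric",
                   fireCutoff = "numeric", minPairs = "integer"),
    validity = function(object) {
        msg <- character()
        p <- object@pairs
        if (ncol(p) != 2L)
            msg <- c(msg, "pairs must have two columns (protein, dna serials)")
        if (object@defineCutoff >= object@fireCutoff)
            msg <- c(msg, "defineCutoff must be smaller than fireCutoff")
        if (object@minPairs < 1L)
            msg <- c(msg, "minPairs must be at least 1")
        if (length(msg)) msg else TRUE
    })

#' Construct a ReactionPairSet
#' @param pairs Two-column matrix of (protein serial, dna serial); may be
#'   empty.
#' @param defineCutoff,fireCutoff,minPairs Criterion parameters; see
#'   [ReactionPairSet-class].
#' @return A [ReactionPairSet-class] object.
#' @export
ReactionPairSet <- function(pairs, defineCutoff = 4.5, fireCutoff = 5.5,
                            minPairs = 3L) {
    pairs <- matrix(as.integer(pairs), ncol = 2L,
                    dimnames = list(NULL, c("protein", "dna")))
    new("ReactionPairSet", pairs = pairs, defineCutoff = defineCutoff,
        fireCutoff = fireCutoff, minPairs = as.integer(minPairs))
}

#' @describeIn ReactionPairSet-class pair matrix accessor
#' @param x A `ReactionPairSet`.
#' @export
reactionPairs <- function(x) { stopifnot(is(x, "ReactionPairSet")); x@pairs }

#' @describeIn ReactionPairSet-class number of defined pairs
#' @export
nPairs <- function(x) { stopifnot(is(x, "ReactionPairSet")); nrow(x@pairs) }

setMethod("show", "ReactionPairSet", function(object) {
    cat("ReactionPairSet:", nrow(object@pairs), "pairs (defined < ",
        object@defineCutoff, " A; fires when >= ", object@minPairs,
        " pairs < ", object@fireCutoff, " A)\n", sep = "")
})
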