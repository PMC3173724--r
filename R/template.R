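#' Parse a 1-based position list of the form "5,9-11,13"
#'
#' Comma-separated positions and inclusive ranges, as used for conserved
#' binding positions on the command line and in config files.
#'
#' @param spec Character scalar, e.g. `"5,9-11,13,14,28,31"`. Empty string
#'   yields an empty set.
#' @return Sorted unique integer vector.
#' @export
#' @examples
#' parsePositions("5,9-11,13")   # 5 9 10 11 13
parsePositions <- function(spec) {
    stopifnot(is.character(spec), length(spec) == 1L)
    spec <- gsub("[[:space:]]", "", spec)
    if (!nzchar(spec)) return(integer(0))
    parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
    out <- lapply(parts, function(p) {
        if (grepl("^[0-9]+$", p)) return(as.integer(p))
        m <- regmatches(p, regexec("^([0-9]+)-([0-9]+)$", p))[[1]]
        if (length(m) != 3L) stop("cannot parse position token: '", p, "'")
        a <- as.integer(m[2]); b <- as.integer(m[3])
        if (a > b) stop("descending range: '", p, "'")
        a:b
    })
    sort(unique(unlist(out)))
}

#' Format a position set back into "5,9-11,13" notation
#' @param positions Integer vector of 1-based positions.
#' @return Character scalar.
#' @export
formatPositions <- function(positions) {
    positions <- sort(unique(as.integer(positions)))
    if (!length(positions)) return("")
    runs <- split(positions, cumsum(c(1L, diff(positions) != 1L)))
    paste(vapply(runs, function(r)
        if (length(r) == 1L) as.character(r)
        else paste0(r[1], "-", r[length(r)]), ""), collapse = ",")
}

.checkRange <- function(range, n, system) {
    if (length(range) != 2L || any(!is.finite(range)))
        stop("range in ", system, " coordinates must be two numbers")
    range <- as.integer(range)
    if (range[1] < 1L || range[2] > n || range[1] > range[2])
        stop("range ", range[1], "-", range[2], " out of bounds in ",
             system, " coordinates (valid: 1-", n, ")")
    range
}

#' Build a constrained fusion design template
#'
#' Constructs the seed of a graft design: the kept scaffold segment is
#' concatenated with a segment excised from a donor protein (e.g. helix 3
#' of the Z domain, scaffold residues 42-57, replaced by the DNA-binding
#' helix of MyoD, donor residues 110-125). Conserved positions given in
#' scaffold and donor numbering are remapped onto 1-based fusion
#' coordinates and become the never-mutated set. The target
#' secondary-structure string and the target hydropathy/molecular-weight
#' integrals are computed from the seed itself.
#'
#' @param scaffoldSeq Scaffold amino-acid sequence (single string).
#' @param scaffoldKeep Closed 1-based range of scaffold residues to keep,
#'   e.g. `c(1, 41)`.
#' @param graftSeq Donor amino-acid sequence in the donor's own numbering.
#' @param graftRange Closed 1-based range of donor residues to graft.
#' @param conservedScaffold Conserved positions in scaffold numbering
#'   (must lie inside `scaffoldKeep`).
#' @param conservedGraft Conserved positions in donor numbering (must lie
#'   inside `graftRange`).
#' @param predictor Secondary-structure predictor used for the target
#'   string; see [propensityPredictor()].
#' @param hydroTable,mwTable Property tables for the two profile
#'   objectives.
#' @param window Sliding-window width for the profiles (odd; default 7).
#' @return A [DesignTemplate-class].
#' @export
#' @examples
#' tpl <- buildFusionTemplate("AAAAAAAAAA", c(1, 6), "CCDDEE", c(3, 6),
#'                            conservedScaffold = 2, conservedGraft = 4)
#' seedSequence(tpl)   # "AAAAAADDEE"
#' fixedPositions(tpl) # 2 8
buildFusionTemplate <- function(scaffoldSeq, scaffoldKeep, graftSeq,
                                graftRange, conservedScaffold = integer(0),
                                conservedGraft = integer(0),
                                predictor = propensityPredictor(),
                                hydroTable = hydrophobicityTable(),
                                mwTable = molecularWeightTable(),
                                window = 7L) {
    for (s in list(c(scaffoldSeq, "scaffold"), c(graftSeq, "graft"))) {
        msg <- .checkSeq(s[1], s[2])
        if (!is.null(msg)) stop(msg)
    }
    scaffoldKeep <- .checkRange(scaffoldKeep, nchar(scaffoldSeq), "scaffold")
    graftRange <- .checkRange(graftRange, nchar(graftSeq), "donor")
    conservedScaffold <- sort(unique(as.integer(conservedScaffold)))
    conservedGraft <- sort(unique(as.integer(conservedGraft)))
    if (length(conservedScaffold) &&
        (min(conservedScaffold) < scaffoldKeep[1] ||
         max(conservedScaffold) > scaffoldKeep[2]))
        stop("conserved position outside the kept range in scaffold coordinates")
    if (length(conservedGraft) &&
        (min(conservedGraft) < graftRange[1] ||
         max(conservedGraft) > graftRange[2]))
        stop("conserved position outside the grafted range in donor coordinates")

    prefix <- substr(scaffoldSeq, scaffoldKeep[1], scaffoldKeep[2])
    graft <- substr(graftSeq, graftRange[1], graftRange[2])
    seed <- paste0(prefix, graft)
    nKeep <- nchar(prefix)
    fixed <- sort(c(conservedScaffold - scaffoldKeep[1] + 1L,
                    nKeep + (conservedGraft - graftRange[1] + 1L)))

    ss <- predictSS(seed, predictor)
    new("DesignTemplate", seed = seed, fixedPositions = as.integer(fixed),
        targetSS = ss,
        targetHydroIntegral =
            profileIntegral(windowedProfile(seed, hydroTable, window)),
        targetMWIntegral =
            profileIntegral(windowedProfile(seed, mwTable, window)))
}

#' Build a DesignTemplate directly from a seed sequence
#'
#' For designs where the fusion seed is already in hand (e.g. read from
#' FASTA) and only the conserved-position mask is needed.
#'
#' @param seed Seed amino-acid sequence.
#' @param fixed Conserved 1-based positions (integer vector or a
#'   "5,9-11" style string).
#' @param targetSeq Sequence defining the target profiles (secondary
#'   structure and integrals). Defaults to the seed itself, which makes
#'   the seed the known optimum of all three objectives — convenient for
#'   synthetic benchmarks; real designs typically pass the wild-type
#'   scaffold here.
#' @inheritParams buildFusionTemplate
#' @return A [DesignTemplate-class].
#' @export
designTemplate <- function(seed, fixed = integer(0), targetSeq = NULL,
                           predictor = propensityPredictor(),
                           hydroTable = hydrophobicityTable(),
                           mwTable = molecularWeightTable(),
                           window = 7L) {
    if (is.character(fixed)) fixed <- parsePositions(fixed)
    if (is.null(targetSeq)) targetSeq <- seed
    ss <- predictSS(targetSeq, predictor)
    if (nchar(targetSeq) != nchar(seed))
        stop("targetSeq length must equal seed length")
    new("DesignTemplate", seed = seed,
        fixedPositions = sort(unique(as.integer(fixed))), targetSS = ss,
        targetHydroIntegral =
            profileIntegral(windowedProfile(targetSeq, hydroTable, window)),
        targetMWIntegral =
            profileIntegral(windowedProfile(targetSeq, mwTable, window)))
}

#' Check a candidate sequence against a template's constraints
#'
#' Pure predicate: `TRUE` iff the candidate has the template's length and
#' agrees with the seed at every conserved position.
#'
#' @param seq Candidate amino-acid sequence.
#' @param template A [DesignTemplate-class].
#' @return Logical scalar.
#' @export
validateSequence <- function(seq, template) {
    stopifnot(is(template, "DesignTemplate"))
    if (!is.character(seq) || length(seq) != 1L || is.na(seq)) return(FALSE)
    if (nchar(seq) != nchar(template@seed)) return(FALSE)
    fp <- template@fixedPositions
    if (!length(fp)) return(TRUE)
    a <- strsplit(seq, "", fixed = TRUE)[[1]]
    b <- strsplit(template@seed, "", fixed = TRUE)[[1]]
    all(a[fp] == b[fp])
}
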