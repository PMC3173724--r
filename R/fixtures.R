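#' Simulate a random constrained design template
#'
#' Generates a random canonical seed sequence with a random conserved
#' mask, and derives the target secondary structure and profile
#' integrals from the seed with the built-in machinery — a synthetic
#' stand-in for a real fusion design problem, defaulting to the study
#' geometry (56 residues, 16 conserved binding positions).
#'
#' @param seqLength Seed length (default 56).
#' @param nFixed Number of conserved positions (default 16).
#' @param rngSeed Integer seed; templates are bit-reproducible from it.
#' @inheritParams buildFusionTemplate
#' @return A [DesignTemplate-class].
#' @export
simulateTemplate <- function(seqLength = 56L, nFixed = 16L, rngSeed = 1L,
                             predictor = propensityPredictor(),
                             hydroTable = hydrophobicityTable(),
                             mwTable = molecularWeightTable(),
                             window = 7L) {
    if (nFixed > seqLength)
        stop("nFixed (", nFixed, ") exceeds seqLength (", seqLength, ")")
    set.seed(rngSeed)
    seed <- paste(sample(aminoAcids(), seqLength, replace = TRUE),
                  collapse = "")
    fixed <- sort(sample.int(seqLength, nFixed))
    designTemplate(seed, fixed, predictor = predictor,
                   hydroTable = hydroTable, mwTable = mwTable,
                   window = window)
}

# ideal alpha-helical CA trace: 2.3 A radius, 1.5 A rise, 100 deg/residue
.helixTrace <- function(n) {
    th <- (seq_len(n) - 1L) * 100 * pi / 180
    cbind(x = 2.3 * cos(th), y = 2.3 * sin(th), z = 1.5 * (seq_len(n) - 1L))
}

#' Apply a rigid transform to a coordinate matrix
#' @param coords n x 3 matrix.
#' @param rotation 3 x 3 proper rotation matrix.
#' @param translation Length-3 vector.
#' @return Transformed n x 3 matrix.
#' @export
rigidTransform <- function(coords, rotation, translation) {
    t(rotation %*% t(coords)) +
        matrix(translation, nrow(coords), 3L, byrow = TRUE)
}

#' A reproducible random proper rotation + translation
#' @param rngSeed Integer seed.
#' @param maxShift Maximum component of the random translation (A).
#' @return List with `rotation` (det +1) and `translation`.
#' @export
randomTransform <- function(rngSeed = 1L, maxShift = 10) {
    set.seed(rngSeed)
    m <- matrix(stats::rnorm(9L), 3L)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1L] <- -q[, 1L]
    list(rotation = q,
         translation = stats::runif(3L, -maxShift, maxShift))
}

#' Simulate a helix-like C-alpha trajectory with planted fluctuations
#'
#' Frames are an ideal alpha-helical CA trace plus independent isotropic
#' Gaussian jitter whose per-axis standard deviation is
#' `amplitude / sqrt(3)`, so the expected 3-D RMSF of residue i equals
#' `rmsfAmplitudes[i]` exactly. Optionally every frame is pre-transformed
#' by a planted rigid transform (for superposition-recovery tests).
#'
#' @param nResidues Number of residues.
#' @param nFrames Number of frames (>= 2).
#' @param rmsfAmplitudes Per-residue RMSF amplitude in Angstrom (recycled;
#'   default 0 = static trajectory).
#' @param transform Optional list(rotation, translation) applied to all
#'   frames, e.g. from [randomTransform()].
#' @param rngSeed Integer seed; bit-reproducible.
#' @return A [CaTrajectory-class] with residue ids 1..nResidues.
#' @export
simulateTrajectory <- function(nResidues = 15L, nFrames = 100L,
                               rmsfAmplitudes = 0, transform = NULL,
                               rngSeed = 1L) {
    stopifnot(nResidues >= 1L, nFrames >= 1L, all(rmsfAmplitudes >= 0))
    set.seed(rngSeed)
    base <- .helixTrace(nResidues)
    sd <- rep_len(rmsfAmplitudes, nResidues) / sqrt(3)
    frames <- lapply(seq_len(nFrames), function(f) {
        co <- base + matrix(stats::rnorm(3L * nResidues, sd = sd),
                            nResidues, 3L)
        if (!is.null(transform))
            co <- rigidTransform(co, transform$rotation,
                                 transform$translation)
        co
    })
    CaTrajectory(seq_len(nResidues), frames)
}

#' Simulate protein-DNA frames with a planted number of associating frames
#'
#' Builds a bound reference complex whose polar cross-molecule contacts
#' sit at 3.0 A (defining `nPairs` reaction pairs below the 4.5 A
#' cutoff), then emits diffusional frames: associating frames keep the
#' bound geometry (all pairs below the firing cutoff), non-associating
#' frames displace the DNA far away. Which frames associate is drawn
#' reproducibly from `rngSeed`, with exactly `nFiring` of them firing.
#'
#' @param nFrames Number of frames.
#' @param nFiring Number of frames planted to associate
#'   (`0 <= nFiring <= nFrames`).
#' @param nPairs Number of reaction pairs in the bound complex
#'   (default 4; must be >= `minPairs` for any frame to fire).
#' @param minPairs Association threshold stored in the pair set
#'   (default 3).
#' @param rngSeed Integer seed.
#' @return List with `complex` (the bound atom table), `frames` (list of
#'   atom tables), `pairs` (the [ReactionPairSet-class]) and `firing`
#'   (logical per frame).
#' @export
simulateComplexFrames <- function(nFrames = 100L, nFiring = 10L,
                                  nPairs = 4L, minPairs = 3L,
                                  rngSeed = 1L) {
    stopifnot(nFrames >= 1L, nFiring >= 0L, nFiring <= nFrames,
              nPairs >= 1L)
    if (nFiring > 0L && nPairs < minPairs)
        stop("cannot plant firing frames: nPairs < minPairs")
    set.seed(rngSeed)
    # protein polar atoms along x at 5 A spacing (so only facing atoms
    # fall under the 4.5 A cutoff); matching DNA atoms 3 A away in y;
    # one apolar carbon on each side for realism
    k <- seq_len(nPairs)
    complex <- atomRecords(
        serial = c(k, nPairs + 1L, nPairs + 1L + k, 2L * nPairs + 2L),
        atomName = c(rep("N", nPairs), "CA", rep("OP1", nPairs), "C1'"),
        element = c(rep("N", nPairs), "C", rep("O", nPairs), "C"),
        residueId = c(k, 1L, k, 1L),
        moleculeTag = c(rep("protein", nPairs + 1L), rep("dna", nPairs + 1L)),
        x = c(5 * k, 0, 5 * k, 0),
        y = c(rep(0, nPairs + 1L), rep(3, nPairs), 3),
        z = rep(0, 2L * nPairs + 2L))
    pairs <- defineReactionPairs(complex, minPairs = minPairs)
    firing <- logical(nFrames)
    firing[sample.int(nFrames, nFiring)] <- TRUE
    dnaRows <- complex$moleculeTag == "dna"
    frames <- lapply(seq_len(nFrames), function(f) {
        fr <- complex
        if (!firing[f]) fr$z[dnaRows] <- fr$z[dnaRows] + 100
        fr
    })
    list(complex = complex, frames = frames, pairs = pairs, firing = firing)
}
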