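#' Read C-alpha coordinates from a PDB file
#'
#' Parses CA atoms of one chain from a fixed-column PDB file via
#' \pkg{bio3d}. Files with `MODEL`/`ENDMDL` records yield a
#' [CaTrajectory-class] (frame times default to the frame index in ps);
#' single-model files yield a [CaStructure-class].
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default: the first chain in the file.
#' @return A `CaStructure` or `CaTrajectory`.
#' @export
readCaPdb <- function(path, chain = NULL) {
    if (!file.exists(path)) stop("PDB file not found: ", path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    atoms <- pdb$atom
    ca <- atoms$elety == "CA"
    if (is.null(chain)) chain <- atoms$chain[ca][1]
    sel <- which(ca & atoms$chain == chain)
    if (!length(sel))
        stop("no CA atoms found in ", path,
             if (!is.na(chain)) paste0(" for chain ", chain))
    resid <- atoms$resno[sel]
    xyzIdx <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    nModels <- nrow(xyz)
    frames <- lapply(seq_len(nModels), function(m)
        matrix(xyz[m, xyzIdx], ncol = 3L, byrow = TRUE))
    if (any(!is.finite(unlist(frames))))
        stop("malformed coordinates in ", path)
    if (nModels == 1L) CaStructure(resid, frames[[1]])
    else CaTrajectory(resid, frames)
}

#' Write a CaStructure or CaTrajectory as a fixed-column PDB file
#'
#' CA-only records, chain A; trajectories are written with one
#' `MODEL`/`ENDMDL` block per frame. Coordinates are recorded at PDB
#' precision (3 decimals).
#'
#' @param x A [CaStructure-class] or [CaTrajectory-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCaPdb <- function(x, path) {
    atomLines <- function(coords, resid) {
        sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                seq_along(resid), resid,
                coords[, 1], coords[, 2], coords[, 3])
    }
    if (is(x, "CaStructure")) {
        lines <- c(atomLines(caCoords(x), residueIds(x)), "END")
    } else if (is(x, "CaTrajectory")) {
        lines <- unlist(lapply(seq_len(nFrames(x)), function(i)
            c(sprintf("MODEL %8d", i),
              atomLines(caCoords(trajFrame(x, i)), residueIds(x)),
              "ENDMDL")))
        lines <- c(lines, "END")
    } else stop("x must be a CaStructure or CaTrajectory")
    writeLines(lines, path)
    invisible(path)
}

.regionIdx <- function(x, residues) {
    idx <- match(residues, residueIds(x))
    if (anyNA(idx))
        stop("residues absent from structure: ",
             paste(residues[is.na(idx)], collapse = ","))
    idx
}

#' Optimal rigid superposition (Kabsch) onto a reference
#'
#' Finds the proper rotation R (det +1) and translation t minimizing the
#' RMSD between `R x + t` of the mobile structure and the reference over
#' the fit residues (e.g. helices 1 and 2, residues 6-17 and 22-33, when
#' assessing a helix-3 graft), then applies the transform to *all* mobile
#' residues. Near-degenerate (collinear) fit sets raise a conditioning
#' warning.
#'
#' @param mobile,reference [CaStructure-class] objects.
#' @param fitResidues Residue ids (present in both) used for the fit;
#'   at least 3.
#' @return List with `rotation` (3 x 3), `translation` (length 3),
#'   `transformed` (the transformed mobile `CaStructure`) and `fitRmsd`
#'   (Angstrom).
#' @export
kabschSuperpose <- function(mobile, reference, fitResidues) {
    stopifnot(is(mobile, "CaStructure"), is(reference, "CaStructure"))
    fitResidues <- sort(unique(as.integer(fitResidues)))
    if (length(fitResidues) < 3L)
        stop("need at least 3 fit residues for superposition")
    P <- caCoords(mobile)[.regionIdx(mobile, fitResidues), , drop = FALSE]
    Q <- caCoords(reference)[.regionIdx(reference, fitResidues), , drop = FALSE]
    cp <- colMeans(P); cq <- colMeans(Q)
    Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
    H <- crossprod(Pc, Qc)
    sv <- svd(H)
    if (sv$d[2] < 1e-8 * max(sv$d[1], .Machine$double.eps))
        warning("fit set is nearly collinear; superposition is ill-conditioned")
    d <- sign(det(sv$v %*% t(sv$u)))
    D <- diag(c(1, 1, d))
    R <- sv$v %*% D %*% t(sv$u)
    trans <- as.numeric(cq - R %*% cp)
    allT <- t(R %*% t(caCoords(mobile))) +
        matrix(trans, nrow(caCoords(mobile)), 3L, byrow = TRUE)
    transformed <- CaStructure(residueIds(mobile), allT)
    fitT <- caCoords(transformed)[.regionIdx(transformed, fitResidues), ,
                                  drop = FALSE]
    list(rotation = R, translation = trans, transformed = transformed,
         fitRmsd = sqrt(mean(rowSums((fitT - Q)^2))))
}

#' C-alpha RMSD over a residue region
#'
#' Root-mean-square deviation of paired CA positions over the given
#' residues (e.g. the grafted helix, residues 39-53, after superposing on
#' helices 1 and 2). No superposition is performed here.
#'
#' @param a,b [CaStructure-class] objects containing the region.
#' @param region Residue ids to compare.
#' @return Non-negative RMSD in Angstrom; symmetric in `a`, `b`.
#' @export
regionRmsd <- function(a, b, region) {
    stopifnot(is(a, "CaStructure"), is(b, "CaStructure"))
    region <- sort(unique(as.integer(region)))
    if (!length(region)) stop("empty region")
    A <- caCoords(a)[.regionIdx(a, region), , drop = FALSE]
    B <- caCoords(b)[.regionIdx(b, region), , drop = FALSE]
    sqrt(mean(rowSums((A - B)^2)))
}

#' Superpose every trajectory frame onto a reference
#'
#' Convenience wrapper applying [kabschSuperpose()] frame-wise, as done
#' before RMSF or RMSD-vs-time analysis.
#'
#' @param traj A [CaTrajectory-class].
#' @param reference Reference [CaStructure-class] (default: first frame).
#' @param fitResidues Residue ids used for each fit.
#' @return A superposed [CaTrajectory-class].
#' @export
superposeTrajectory <- function(traj, reference = NULL, fitResidues) {
    stopifnot(is(traj, "CaTrajectory"))
    if (is.null(reference)) reference <- trajFrame(traj, 1L)
    frames <- lapply(seq_len(nFrames(traj)), function(i)
        caCoords(kabschSuperpose(trajFrame(traj, i), reference,
                                 fitResidues)$transformed))
    CaTrajectory(residueIds(traj), frames, frameTimes(traj))
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each residue about its mean position across frames. Frames are
#' assumed already superposed (see [superposeTrajectory()]).
#'
#' @param traj A [CaTrajectory-class] with at least 2 frames.
#' @param region Residue ids to report (default: all).
#' @return Named numeric vector (Angstrom), names = residue ids.
#' @export
rmsf <- function(traj, region = NULL) {
    stopifnot(is(traj, "CaTrajectory"))
    if (nFrames(traj) < 2L) stop("RMSF requires at least 2 frames")
    if (is.null(region)) region <- residueIds(traj)
    idx <- .regionIdx(traj, sort(unique(as.integer(region))))
    xyz <- traj@coords[idx, , , drop = FALSE]
    meanPos <- apply(xyz, c(1L, 2L), mean)
    dev2 <- sweep(xyz, c(1L, 2L), meanPos)^2
    out <- sqrt(apply(dev2, 1L, sum) / dim(xyz)[3])
    stats::setNames(out, residueIds(traj)[idx])
}

#' Smooth a time series with a cubic smoothing spline
#'
#' Used to smooth RMSD-vs-time curves. A cubic smoothing spline is fit to
#' (time, value); because the roughness penalty acts on curvature only,
#' noiseless linear (or constant) series are reproduced exactly at any
#' smoothing level.
#'
#' @param times Strictly increasing times (>= 4 points).
#' @param values Values at `times`.
#' @param spar Optional smoothing parameter passed to
#'   [stats::smooth.spline()]; default: generalized cross-validation.
#' @return List with `smoothed` (values on the input grid), `curve`
#'   (function of time) and `fit` (the `smooth.spline` object).
#' @export
smoothCurve <- function(times, values, spar = NULL) {
    if (length(times) < 4L) stop("need at least 4 points to smooth")
    if (length(times) != length(values)) stop("times/values length mismatch")
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
    fit <- if (is.null(spar))
        stats::smooth.spline(times, values, cv = FALSE)
    else stats::smooth.spline(times, values, spar = spar)
    list(smoothed = stats::predict(fit, times)$y,
         curve = function(t) stats::predict(fit, t)$y,
         fit = fit)
}
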