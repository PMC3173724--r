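#' Build a validated atom table for a protein-DNA complex frame
#'
#' Frames are plain data.frames with one row per atom: serial, atom name,
#' element, residue id, molecule tag (`"protein"` or `"dna"`), Cartesian
#' coordinates in Angstrom, and a polar flag. By default an atom is polar
#' iff its element is N or O (the standard polar-contact convention); a
#' custom polar-atom rule can be supplied.
#'
#' @param serial Integer atom serial numbers (unique).
#' @param atomName Atom name strings.
#' @param element Element symbols.
#' @param residueId Integer residue numbers.
#' @param moleculeTag `"protein"` or `"dna"` per atom.
#' @param x,y,z Coordinates (Angstrom).
#' @param polar Optional logical; default `element %in% c("N", "O")`.
#' @return data.frame of atom records.
#' @export
atomRecords <- function(serial, atomName, element, residueId, moleculeTag,
                        x, y, z, polar = NULL) {
    n <- length(serial)
    stopifnot(!anyDuplicated(serial),
              all(moleculeTag %in% c("protein", "dna")),
              all(is.finite(c(x, y, z))))
    if (is.null(polar)) polar <- element %in% c("N", "O")
    data.frame(serial = as.integer(serial), atomName = atomName,
               element = element, residueId = as.integer(residueId),
               moleculeTag = moleculeTag, x = x, y = y, z = z,
               polar = polar)
}

.pairDistances <- function(frame, pairs) {
    i <- match(pairs[, 1L], frame$serial)
    j <- match(pairs[, 2L], frame$serial)
    if (anyNA(i) || anyNA(j)) {
        missing <- c(pairs[is.na(i), 1L], pairs[is.na(j), 2L])
        stop("atom serial(s) absent from frame: ",
             paste(unique(missing), collapse = ","))
    }
    sqrt((frame$x[i] - frame$x[j])^2 + (frame$y[i] - frame$y[j])^2 +
         (frame$z[i] - frame$z[j])^2)
}

#' Define reaction pairs from a bound reference complex
#'
#' Identifies every cross-molecule polar-polar atom pair at a distance
#' strictly below `cutoff` Angstrom (default 4.5) in the bound complex.
#' These pairs constitute the association criterion used by
#' [associationTest()].
#'
#' @param complex Atom table from [atomRecords()] containing both
#'   molecule tags.
#' @param cutoff Defining distance cutoff (A), strict inequality.
#' @param fireCutoff,minPairs Stored criterion parameters for the
#'   resulting [ReactionPairSet-class] (defaults 5.5 A / 3 pairs).
#' @return A [ReactionPairSet-class]; empty (with a warning) when one
#'   side has no polar atoms.
#' @export
defineReactionPairs <- function(complex, cutoff = 4.5, fireCutoff = 5.5,
                                minPairs = 3L) {
    stopifnot(all(c("protein", "dna") %in% complex$moleculeTag))
    prot <- complex[complex$moleculeTag == "protein" & complex$polar, ]
    dna <- complex[complex$moleculeTag == "dna" & complex$polar, ]
    if (nrow(prot) == 0L || nrow(dna) == 0L) {
        warning("no polar atoms on one side; empty reaction-pair set")
        return(ReactionPairSet(matrix(integer(0), 0L, 2L),
                               cutoff, fireCutoff, minPairs))
    }
    d2 <- outer(prot$x, dna$x, "-")^2 + outer(prot$y, dna$y, "-")^2 +
        outer(prot$z, dna$z, "-")^2
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    pairs <- cbind(prot$serial[hit[, 1L]], dna$serial[hit[, 2L]])
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    ReactionPairSet(pairs, cutoff, fireCutoff, minPairs)
}

#' Frame-wise association test
#'
#' A frame counts as associated when at least `minPairs` of the defined
#' reaction pairs are at a distance strictly below the firing cutoff
#' (defaults: 3 pairs below 5.5 A).
#'
#' @param frame Atom table containing every atom referenced by `pairs`.
#' @param pairs A [ReactionPairSet-class].
#' @return Logical scalar.
#' @export
associationTest <- function(frame, pairs) {
    stopifnot(is(pairs, "ReactionPairSet"))
    if (nPairs(pairs) == 0L) return(FALSE)
    d <- .pairDistances(frame, reactionPairs(pairs))
    sum(d < pairs@fireCutoff) >= pairs@minPairs
}

#' Fraction of frames/trajectories that associate
#'
#' @param frames List of atom tables.
#' @param pairs A [ReactionPairSet-class].
#' @return Numeric in [0, 1].
#' @export
associationFraction <- function(frames, pairs) {
    stopifnot(length(frames) >= 1L)
    mean(vapply(frames, associationTest, logical(1), pairs = pairs))
}

#' Relative association rate constants
#'
#' Normalizes measured k_on values by a reference complex (e.g. the
#' wild-type protein-DNA complex), reporting `rel_kon = k_on /
#' k_on(reference)` rounded half-even to 3 decimals; the reference row is
#' 1.000 and a zero k_on gives 0.000.
#'
#' @param rates data.frame with columns `label` and `k_on` (1/(M s)), and
#'   optionally `net_charge`.
#' @param referenceLabel Label of the reference row (default `"WT"`).
#' @return data.frame with columns `label`, `k_on`, `net_charge` (if
#'   present) and `rel_kon`.
#' @export
#' @examples
#' relativeKon(data.frame(label = c("WT", "Seed"),
#'                        k_on = c(4.66e8, 1.17e8)))
relativeKon <- function(rates, referenceLabel = "WT") {
    stopifnot(is.data.frame(rates), all(c("label", "k_on") %in% names(rates)))
    ref <- rates$k_on[match(referenceLabel, rates$label)]
    if (is.na(ref)) stop("reference label '", referenceLabel, "' not found")
    if (ref <= 0) stop("reference k_on must be positive")
    rates$rel_kon <- round(rates$k_on / ref, 3L)
    rates
}

#' Read a rate table from tab-separated text
#'
#' Columns: label, k_on, net_charge; `#` lines are comments. The default
#' path ships published Brownian-dynamics association rates for the
#' designed fusion models against target DNA.
#'
#' @param path File path; default: the bundled rate table.
#' @return data.frame.
#' @export
readRateTable <- function(path = NULL) {
    if (is.null(path)) path <- .extdata("brownian_kon_rates.tsv")
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
}

#' Read a protein-DNA complex (or frames) from PDB
#'
#' Atoms from the listed protein and DNA chains are tagged accordingly;
#' multi-model files yield one atom table per model.
#'
#' @param path PDB file path.
#' @param proteinChains,dnaChains Chain identifiers for each molecule.
#' @return A single atom table, or a list of them for multi-model files.
#' @export
readComplexPdb <- function(path, proteinChains = "A", dnaChains = "B") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    atoms <- pdb$atom
    sel <- which(atoms$chain %in% c(proteinChains, dnaChains))
    if (!length(sel)) stop("no atoms on the requested chains in ", path)
    tag <- ifelse(atoms$chain[sel] %in% proteinChains, "protein", "dna")
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    xyzIdx <- as.vector(rbind(3 * sel - 2, 3 * sel - 1, 3 * sel))
    elem <- atoms$elesy[sel]
    if (any(is.na(elem) | elem == ""))
        elem <- substr(trimws(atoms$elety[sel]), 1L, 1L)
    mk <- function(m) {
        co <- matrix(xyz[m, xyzIdx], ncol = 3L, byrow = TRUE)
        atomRecords(atoms$eleno[sel], trimws(atoms$elety[sel]), elem,
                    atoms$resno[sel], tag, co[, 1], co[, 2], co[, 3])
    }
    if (nrow(xyz) == 1L) mk(1L) else lapply(seq_len(nrow(xyz)), mk)
}
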