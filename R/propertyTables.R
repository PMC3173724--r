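#' Read an amino-acid property table from two-column text
#'
#' The on-disk format is whitespace-delimited text with one residue per
#' line: one-letter code, value. Lines starting with `#` are comments.
#'
#' @param path Path to the table file.
#' @param name Scale label; defaults to the file name without extension.
#' @return A [PropertyTable-class].
#' @export
readPropertyTable <- function(path, name = NULL) {
    if (!file.exists(path)) stop("property table not found: ", path)
    tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                             col.names = c("residue", "value"),
                             colClasses = c("character", "numeric"))
    if (is.null(name))
        name <- sub("\\.[^.]*$", "", basename(path))
    PropertyTable(name, stats::setNames(tab$value, tab$residue))
}

#' Write a PropertyTable to two-column text
#'
#' @param table A [PropertyTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePropertyTable <- function(table, path) {
    stopifnot(is(table, "PropertyTable"))
    v <- table@values
    writeLines(c(sprintf("# %s", table@name),
                 sprintf("%s\t%g", names(v), v)), path)
    invisible(path)
}

.extdata <- function(file) {
    system.file("extdata", file, package = "fusionGA", mustWork = TRUE)
}

#' Default hydropathy scale (Kyte-Doolittle)
#'
#' Per-residue hydropathy values on the Kyte-Doolittle scale, the standard
#' companion of the window-7 sliding-window hydropathy profile.
#'
#' @return A [PropertyTable-class] (dimensionless scale units).
#' @export
#' @examples
#' propertyValues(hydrophobicityTable(), c("I", "R"))  # 4.5, -4.5
hydrophobicityTable <- function() {
    readPropertyTable(.extdata("kyte_doolittle.tsv"), "Kyte-Doolittle hydropathy")
}

#' Default molecular-weight scale (average residue masses)
#'
#' Average (isotope-abundance weighted) residue masses in Da, i.e. the
#' amino-acid masses minus one water.
#'
#' @return A [PropertyTable-class] (Da).
#' @export
molecularWeightTable <- function() {
    readPropertyTable(.extdata("residue_mass_average.tsv"),
                      "average residue mass")
}

#' Secondary-structure propensity constants
#'
#' Classic per-residue conformational propensities for helix, sheet and
#' turn/coil states, used by the built-in windowed-propensity predictor.
#'
#' @return Numeric matrix 20 x 3 with columns `H`, `E`, `C`, rows named by
#'   one-letter code.
#' @seealso [propensityPredictor()]
#' @export
propensityTable <- function() {
    tab <- utils::read.table(.extdata("ss_propensities.tsv"), header = TRUE,
                             comment.char = "#", row.names = 1L)
    m <- as.matrix(tab[aminoAcids(), c("H", "E", "C")])
    if (any(!is.finite(m)))
        stop("propensity table incomplete")
    m
}
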