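#' Read amino-acid sequences from FASTA
#'
#' Wrapped lines are allowed; lowercase residues are uppercased with a
#' warning; non-canonical residues raise a format error naming the
#' offending record.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences (names = headers).
#' @export
readFastaSeqs <- function(path) {
    if (!file.exists(path)) stop("FASTA file not found: ", path)
    set <- tryCatch(Biostrings::readBStringSet(path), error = function(e)
        stop("cannot parse FASTA ", path, ": ", conditionMessage(e),
             call. = FALSE))
    if (length(set) == 0L) stop("empty FASTA file: ", path)
    seqs <- as.character(set)
    if (any(grepl("[a-z]", seqs))) {
        warning("lowercase residues uppercased")
        seqs <- toupper(seqs)
    }
    for (i in seq_along(seqs)) {
        msg <- .checkSeq(seqs[i], sprintf("record '%s'", names(seqs)[i]))
        if (!is.null(msg)) stop(msg)
    }
    seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
writeFastaSeqs <- function(seqs, path, width = 60L) {
    if (is.null(names(seqs)))
        names(seqs) <- paste0("seq", seq_along(seqs))
    set <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(set, path, width = width)
    invisible(path)
}

#' Assemble a run configuration
#'
#' A flat named list holding every GA, fitness and output parameter of a
#' design run; round-trips losslessly through YAML.
#'
#' @param seedFasta Path to the seed FASTA (first record is used).
#' @param fixed Conserved positions as a "5,9-11,13" style string.
#' @param populationSize,generations,mutationRate,offspringPerGeneration,founderMutationRate,rngSeed,selection
#'   See [gaConfig()].
#' @param window Profile window width.
#' @param ssPredictor Predictor spec for [resolvePredictor()].
#' @param match,mismatch,gap Alignment parameters.
#' @param hydroTable,mwTable Optional property-table file paths (defaults:
#'   the bundled scales).
#' @param outDir Output directory for [runDesignPipeline()].
#' @return Named list of class `RunConfig`.
#' @export
runConfig <- function(seedFasta, fixed = "", populationSize = 600L,
                      generations = 100L, mutationRate = 0.01,
                      offspringPerGeneration = populationSize,
                      founderMutationRate = 0.05, rngSeed = 1L,
                      selection = "rank", window = 7L,
                      ssPredictor = "propensity", match = 2,
                      mismatch = -1, gap = -2, hydroTable = NULL,
                      mwTable = NULL, outDir = "design_run") {
    structure(list(seedFasta = seedFasta, fixed = fixed,
                   populationSize = as.integer(populationSize),
                   generations = as.integer(generations),
                   mutationRate = mutationRate,
                   offspringPerGeneration = as.integer(offspringPerGeneration),
                   founderMutationRate = founderMutationRate,
                   rngSeed = as.integer(rngSeed), selection = selection,
                   window = as.integer(window), ssPredictor = ssPredictor,
                   match = match, mismatch = mismatch, gap = gap,
                   hydroTable = hydroTable, mwTable = mwTable,
                   outDir = outDir),
              class = "RunConfig")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A [runConfig()] list.
#' @param path YAML file path.
#' @return `writeRunConfig`: `path`, invisibly. `readRunConfig`: the
#'   `RunConfig` list.
#' @export
writeRunConfig <- function(cfg, path) {
    yaml::write_yaml(unclass(cfg), path)
    invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    raw <- yaml::read_yaml(path)
    do.call(runConfig, raw)
}

#' Write a data.frame as tab-separated text with one commented header
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a table written by [writeTsv()]
#' @param path File path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
    header <- sub("^# ", "", readLines(path, n = 1L))
    df <- utils::read.table(path, sep = "\t", comment.char = "#",
                            stringsAsFactors = FALSE)
    names(df) <- strsplit(header, "\t", fixed = TRUE)[[1]]
    df
}
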