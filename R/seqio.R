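## FASTA and metadata I/O, panel assembly, Newick output.

.normalizeSeq <- function(x) chartr("U", "T", toupper(gsub("[ \t\r]", "", x)))

## pre-scan a FASTA file so format errors can name the offending line;
## parsing proper is delegated to Biostrings afterwards
.validateFastaLines <- function(lines, path) {
    inSeq <- FALSE
    sawEntry <- FALSE
    for (i in seq_along(lines)) {
        ln <- lines[[i]]
        if (grepl("^>", ln)) {
            id <- sub("^>\\s*(\\S*).*$", "\\1", ln)
            if (!nzchar(id))
                stop(sprintf("%s: malformed FASTA header at line %d (empty id)",
                             path, i))
            sawEntry <- TRUE
            inSeq <- TRUE
        } else if (nzchar(gsub("[ \t\r]", "", ln))) {
            if (!inSeq)
                stop(sprintf("%s: sequence data before any header at line %d",
                             path, i))
            norm <- .normalizeSeq(ln)
            if (grepl("[^ACGTN-]", norm))
                stop(sprintf("%s: illegal character in sequence at line %d",
                             path, i))
        }
    }
    invisible(sawEntry)
}

#' Read a DNA FASTA file into a normalized DNAStringSet
#'
#' Sequences are uppercased, U is mapped to T and whitespace stripped; the
#' resulting alphabet is restricted to \code{A C G T N -}.  Entry order is
#' file order and ids must be unique within the file.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet] (empty for an empty file).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path) {
    if (!file.exists(path))
        stop(sprintf("FASTA file not found: %s", path))
    lines <- readLines(path, warn = FALSE)
    if (!.validateFastaLines(lines, path))
        return(DNAStringSet())
    ss <- readBStringSet(path, format = "fasta")  # normalize before DNA coercion
    ids <- sub("\\s.*$", "", names(ss))
    if (anyDuplicated(ids))
        stop(sprintf("%s: duplicate sequence id(s): %s", path,
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    seqs <- .normalizeSeq(as.character(ss))
    if (any(!nzchar(seqs)))
        stop(sprintf("%s: empty sequence for id %s", path,
                     paste(ids[!nzchar(seqs)], collapse = ", ")))
    out <- DNAStringSet(seqs)
    names(out) <- ids
    out
}

#' Write a DNAStringSet to FASTA
#'
#' @param seqs named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path) {
    writeXStringSet(seqs, path, format = "fasta", width = 70L)
    invisible(path)
}

.STRAIN_TABLE_COLS <- c("strain_id", "species", "locus", "fasta_path", "seq_id")

#' Read the strain metadata table
#'
#' Tab-delimited, UTF-8, with header \code{strain_id species locus
#' fasta_path seq_id}; lines starting with \code{#} are ignored.  Species
#' labels are trimmed and duplicate (strain, locus) rows rejected.
#'
#' @param path path to the TSV file.
#' @return data.frame with the five columns above, row order preserved.
#' @export
readStrainTable <- function(path) {
    if (!file.exists(path))
        stop(sprintf("metadata table not found: %s", path))
    tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      colClasses = "character", stringsAsFactors = FALSE,
                      quote = "", fileEncoding = "UTF-8")
    missing <- setdiff(.STRAIN_TABLE_COLS, names(tab))
    if (length(missing))
        stop(sprintf("metadata table missing column(s): %s",
                     paste(missing, collapse = ", ")))
    extra <- setdiff(names(tab), .STRAIN_TABLE_COLS)
    if (length(extra))
        stop(sprintf("metadata table has unexpected column(s): %s",
                     paste(extra, collapse = ", ")))
    tab <- tab[, .STRAIN_TABLE_COLS]
    tab$species <- trimws(tab$species)
    if (any(!nzchar(tab$species)))
        stop("metadata table contains empty species labels")
    key <- paste(tab$strain_id, tab$locus, sep = "\r")
    if (anyDuplicated(key)) {
        dup <- tab[duplicated(key), c("strain_id", "locus"), drop = FALSE]
        stop(sprintf("duplicate (strain, locus) row(s): %s",
                     paste(paste(dup$strain_id, dup$locus, sep = "/"),
                           collapse = ", ")))
    }
    tab
}

#' Assemble a StrainPanel from a metadata table and FASTA entries
#'
#' @param table data.frame as returned by [readStrainTable()].
#' @param entries optional named list of \code{DNAStringSet}s keyed by
#'   \code{fasta_path}; when \code{NULL}, each distinct \code{fasta_path}
#'   is read with [readFasta()] (relative paths resolved against
#'   \code{baseDir}).
#' @param referenceStrain optional strain id to mark as the panel reference.
#' @param baseDir directory against which relative \code{fasta_path}s are
#'   resolved; defaults to the working directory.
#' @return a [StrainPanel-class]; strain and locus order is first appearance
#'   in the table.
#' @export
buildPanel <- function(table, entries = NULL, referenceStrain = NA_character_,
                       baseDir = ".") {
    if (!all(.STRAIN_TABLE_COLS %in% names(table)))
        stop("table must have the five strain-table columns")
    if (is.null(entries)) {
        paths <- unique(table$fasta_path)
        entries <- lapply(paths, function(p) {
            fp <- if (file.exists(p)) p else file.path(baseDir, p)
            readFasta(fp)
        })
        names(entries) <- paths
    }
    strains <- table[!duplicated(table$strain_id),
                     c("strain_id", "species"), drop = FALSE]
    rownames(strains) <- NULL
    loci <- unique(table$locus)
    sequences <- list()
    for (loc in loci) {
        rows <- table[table$locus == loc, , drop = FALSE]
        seqs <- character(nrow(rows))
        for (i in seq_len(nrow(rows))) {
            ent <- entries[[rows$fasta_path[i]]]
            if (is.null(ent))
                stop(sprintf("no FASTA entries for path '%s' (strain %s, locus %s)",
                             rows$fasta_path[i], rows$strain_id[i], loc))
            j <- match(rows$seq_id[i], names(ent))
            if (is.na(j))
                stop(sprintf("seq_id '%s' not found in '%s' (strain %s, locus %s)",
                             rows$seq_id[i], rows$fasta_path[i],
                             rows$strain_id[i], loc))
            seqs[i] <- as.character(ent[[j]])
        }
        ss <- DNAStringSet(seqs)
        names(ss) <- rows$strain_id
        sequences[[loc]] <- ss
    }
    new("StrainPanel", strains = strains, loci = loci, sequences = sequences,
        referenceStrain = as.character(referenceStrain))
}

#' Write a phylogenetic tree as Newick
#'
#' @param tree an [ape::phylo] tree with unique leaf labels.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
    if (!inherits(tree, "phylo"))
        stop("tree must be an ape 'phylo' object")
    if (anyDuplicated(tree$tip.label))
        stop(sprintf("duplicate leaf label(s): %s",
                     paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                           collapse = ", ")))
    ape::write.tree(tree, file = path)
    invisible(path)
}
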