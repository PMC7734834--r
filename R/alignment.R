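#' Single-locus nucleotide alignment
#'
#' Container for one aligned locus: unique taxon labels and one equal-length
#' uppercase sequence string per taxon over the alphabet A, C, G, T, the
#' IUPAC ambiguity codes, `-`, `N` and `?`.
#'
#' @param sequences Named character vector of aligned sequences (names are
#'   taxon labels) or a character matrix (rows = taxa, one character per
#'   cell).
#' @param locus_id Locus identifier.
#' @return An object of class `gene_alignment` with fields `locus_id`,
#'   `taxa`, `seqs` (named character vector) and `length`.
#' @export
gene_alignment <- function(sequences, locus_id = "locus") {
  if (is.matrix(sequences))
    sequences <- apply(sequences, 1, paste0, collapse = "")
  taxa <- names(sequences)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    stop("all sequences must be named with taxon labels")
  dup <- taxa[duplicated(taxa)]
  if (length(dup))
    stop("duplicate taxon label(s): ", paste(unique(dup), collapse = ", "))
  sequences <- toupper(sequences)
  len <- unique(nchar(sequences))
  if (length(sequences) == 0) len <- 0L
  if (length(len) > 1) {
    ref <- nchar(sequences[1])
    bad <- taxa[nchar(sequences) != ref]
    stop("unequal sequence lengths; offending taxa: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(locus_id = as.character(locus_id), taxa = taxa,
         seqs = sequences, length = as.integer(len)),
    class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment> ", x$locus_id, ": ", length(x$taxa), " taxa x ",
      x$length, " columns\n", sep = "")
  invisible(x)
}

n_taxa <- function(aln) length(aln$taxa)

# taxa x columns character matrix view
aln_matrix <- function(aln) {
  if (inherits(aln, "supermatrix") || inherits(aln, "gene_alignment")) {
    if (length(aln$taxa) == 0) return(matrix(character(), 0, 0))
    m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
    if (aln$length == 0) m <- matrix(character(), length(aln$taxa), 0)
    rownames(m) <- aln$taxa
    return(m)
  }
  stop("not an alignment object")
}

matrix_to_alignment <- function(m, locus_id) {
  seqs <- if (ncol(m) == 0) stats::setNames(rep("", nrow(m)), rownames(m))
          else apply(m, 1, paste0, collapse = "")
  gene_alignment(seqs, locus_id)
}

#' Read a FASTA alignment
#'
#' Reads a (possibly multi-line) FASTA file into a [gene_alignment()].
#' Sequences are uppercase-normalised; duplicate headers and unequal row
#' lengths are rejected with the offending taxon named.
#'
#' @param path Path to a FASTA file.
#' @param locus_id Locus identifier; defaults to the file name without
#'   extension.
#' @return A [gene_alignment()].
#' @export
read_fasta <- function(path, locus_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(locus_id))
    locus_id <- sub("\\.[^.]*$", "", basename(path))
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0)
    return(gene_alignment(stats::setNames(character(0), character(0)), locus_id))
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  seqs <- stats::setNames(toupper(vapply(recs, function(r) as.character(r)[1], "")),
                          names(recs))
  gene_alignment(seqs, locus_id)
}

#' Write a FASTA alignment
#'
#' One record per taxon in stored order, sequence on a single line:
#' byte-deterministic for a fixed input.
#'
#' @param aln A [gene_alignment()].
#' @param path Output path.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "gene_alignment") || inherits(aln, "supermatrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(aln$taxa))
    writeLines(as.vector(rbind(paste0(">", aln$taxa), unname(aln$seqs))),
               con, sep = "\n")
  invisible(path)
}
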