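# Amino-acid alignments as plain character matrices (rows = taxa), the unit
# over which all per-gene diagnostics are computed. Gaps are '-', unknowns
# 'X'; both are treated identically everywhere (composition, distances,
# likelihood partials).

aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

missing_symbols <- function() c("-", "X", "?")

#' Construct a multiple sequence alignment object
#'
#' @param mat character matrix (taxa x columns) over the 20 amino acids plus
#'   gap `-` and unknown `X`; rownames are the taxon labels.
#' @param gene_id label for the gene/locus.
#' @return an object of class `msa` (a character matrix with a `gene_id`
#'   attribute).
#' @export
msa <- function(mat, gene_id = "gene") {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop_invalid("alignment rows must carry unique taxon labels")
  if (nrow(mat) < 1L || ncol(mat) < 1L)
    stop_invalid("alignment needs at least one taxon and one column")
  bad <- !(mat %in% c(aa_alphabet(), missing_symbols()))
  if (any(bad))
    stop_invalid("alignment contains symbols outside the amino-acid alphabet: ",
                 paste(unique(mat[bad]), collapse = " "))
  structure(mat, gene_id = gene_id, class = c("msa", class(mat)))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> gene '%s': %d taxa x %d columns\n",
              attr(x, "gene_id"), nrow(x), ncol(x)))
  invisible(x)
}

gene_id <- function(x) attr(x, "gene_id") %||% "gene"

#' Read a per-gene FASTA alignment
#'
#' @param path FASTA file; all sequences must be equally long.
#' @param gene_id gene label; defaults to the file name without extension.
#' @return an [msa] object.
#' @export
read_fasta_msa <- function(path, gene_id = NULL) {
  x <- ape::read.FASTA(path, type = "AA")
  m <- toupper(as.character(as.matrix(x)))
  m[!(m %in% c(aa_alphabet(), missing_symbols()))] <- "X"
  m[m == "?"] <- "X"
  msa(m, gene_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an alignment as FASTA
#'
#' Gaps are written as `-`; taxa masked out entirely (all-gap rows) are
#' omitted from the file, matching supermatrix occupancy accounting.
#'
#' @param x an [msa].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta_msa <- function(x, path) {
  keep <- apply(x, 1, function(r) any(!(r %in% missing_symbols())))
  m <- x[keep, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste0(">", rownames(m)[i]), con)
    writeLines(paste(m[i, ], collapse = ""), con)
  }
  invisible(path)
}

# taxa with at least one usable (non-gap, non-X) site
usable_taxa <- function(x) {
  rownames(x)[apply(x, 1, function(r) any(!(r %in% missing_symbols())))]
}
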