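#' Reverse-complement nucleotide strings
#'
#' Vectorised reverse complement over the DNA alphabet ACGTN
#' (case-insensitive input, uppercase output).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGNA"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# Validate a nucleotide string against the ACGTN alphabet; error names the
# first offending position.
check_alphabet <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("%s contains non-ACGTN character '%s' at position %d",
                 what, substr(seq[i], bad[i], bad[i]), bad[i]), call. = FALSE)
  }
  invisible(TRUE)
}

# Normalise a genome to a named uppercase character vector.
# Accepts a named character vector, a list, or a Biostrings::DNAStringSet.
as_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    g <- as.character(genome)
  } else if (is.list(genome)) {
    g <- vapply(genome, as.character, character(1))
  } else {
    g <- as.character(genome)
    names(g) <- names(genome)
  }
  if (is.null(names(g)) || anyNA(names(g)) || any(names(g) == "")) {
    stop("genome sequences must be named by chromosome", call. = FALSE)
  }
  toupper(g)
}

#' Read a genome FASTA into a named sequence vector
#'
#' @param path path to a (possibly multi-record) FASTA file.
#' @return named uppercase character vector, one element per chromosome.
#'   FASTA descriptions are truncated at the first whitespace.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  g
}

# Write a named character vector of sequences as FASTA.
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}
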