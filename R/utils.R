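`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a private RNG state
#'
#' Runs \code{code} with the global RNG seeded to \code{seed} and
#' restores the caller's RNG state afterwards, so that package
#' functions never perturb (and are never perturbed by) the session's
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Coerce scaffold input to a named character vector
#' @param x named character vector, DNAStringSet, or path to a FASTA file.
#' @return named character vector of upper-case sequences.
#' @keywords internal
as_seq_vector <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      !grepl("^[ACGTNacgtn]+$", x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(toupper(out))
  }
  if (!is.character(x) || is.null(names(x)))
    stop("scaffolds must be a named character vector, DNAStringSet or FASTA path")
  toupper(x)
}

#' Write sequences as wrapped FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 60L)
  invisible(path)
}

#' Write reads as Phred+33 FASTQ with uniform quality
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a named character vector
#' @param path FASTQ file (optionally gzipped).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  as_seq_vector(Biostrings::readDNAStringSet(path, format = "fastq"))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
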