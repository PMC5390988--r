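# Shared codon-level helpers.  The genetic code itself comes from
# Biostrings::GENETIC_CODE; everything here is lookup plumbing.

.diverscan_env <- new.env(parent = emptyenv())

.codon_table <- function() {
  if (is.null(.diverscan_env$codon_table)) {
    .diverscan_env$codon_table <- Biostrings::GENETIC_CODE
  }
  .diverscan_env$codon_table
}

.stop_codons <- function() {
  ct <- .codon_table()
  names(ct)[ct == "*"]
}

.sense_codons <- function() {
  ct <- .codon_table()
  names(ct)[ct != "*"]
}

#' @keywords internal
.split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

.aa_of <- function(codons) {
  ct <- .codon_table()
  aa <- unname(ct[codons])
  aa[is.na(aa)] <- "X"  # codons containing N or other ambiguity
  aa
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

.validate_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}", what),
         call. = FALSE)
  }
  invisible(TRUE)
}
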