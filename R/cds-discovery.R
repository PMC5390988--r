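#' Read a transcript FASTA into a transcript table
#'
#' Transcripts are represented throughout the package as a plain data frame
#' with columns \code{id}, \code{species} and \code{sequence} (uppercase DNA
#' over \code{A,C,G,T,N}).  Identifiers follow the Trinity convention
#' \code{c<contig>_g<gene>_i<isoform>}; the \code{c<contig>_g<gene>} prefix is
#' the unigene.
#'
#' @param path path to a FASTA file.
#' @param species species label attached to every record.
#' @return data frame with columns \code{id}, \code{species}, \code{sequence}.
#' @export
read_transcripts <- function(path, species = NA_character_) {
  ss <- Biostrings::readDNAStringSet(path)
  data.frame(id = names(ss),
             species = species,
             sequence = toupper(as.character(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a transcript table as FASTA (70-column wrapped)
#'
#' @param transcripts transcript data frame (see [read_transcripts()]).
#' @param path output path.
#' @export
write_transcripts <- function(transcripts, path) {
  ss <- Biostrings::DNAStringSet(transcripts$sequence)
  names(ss) <- transcripts$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Parse Trinity-style transcript identifiers
#'
#' @param ids character vector of identifiers \code{c<contig>_g<gene>_i<iso>}.
#' @return data frame with columns \code{id}, \code{unigene}, \code{isoform}.
#' @export
parse_trinity_id <- function(ids) {
  m <- regmatches(ids, regexec("^(c[0-9]+_g[0-9]+)_i([0-9]+)$", ids))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) {
    stop(sprintf("unparseable Trinity-style id: %s",
                 paste(ids[bad], collapse = ", ")), call. = FALSE)
  }
  data.frame(id = ids,
             unigene = vapply(m, `[`, character(1), 2L),
             isoform = as.integer(vapply(m, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}

#' Keep only the longest isoform of each unigene
#'
#' Reduces a transcript table to one representative transcript per unigene:
#' the longest isoform, with ties broken by the lexicographically smallest
#' identifier.
#'
#' @param transcripts transcript data frame.
#' @return transcript data frame with one row per unigene.
#' @export
select_longest_isoform <- function(transcripts) {
  info <- parse_trinity_id(transcripts$id)
  len <- nchar(transcripts$sequence)
  ord <- order(info$unigene, -len, transcripts$id)
  keep <- ord[!duplicated(info$unigene[ord])]
  out <- transcripts[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find open reading frames in a transcript
#'
#' Scans all six frames (both strands) for maximal stop-to-stop ORFs and
#' reports those whose protein is at least \code{min_aa} residues long.
#' Within a stop-bounded segment the call is trimmed to the first ATG
#' (\code{complete} if a terminal stop follows, \code{3'-partial} if the
#' segment runs off the transcript end); a segment with no upstream stop and
#' no ATG is reported from the frame start as \code{5'-partial} (with stop)
#' or \code{internal} (without).
#'
#' Coordinates are 0-based half-open on the reported strand, i.e. on the
#' reverse complement for \code{strand == "-"}; the terminal stop codon, when
#' present, is included in \code{[start, end)}.
#'
#' @param sequence DNA string over \code{A,C,G,T,N}.
#' @param id transcript identifier carried into the result.
#' @param min_aa minimum protein length in residues (default 100, i.e. ORFs
#'   of at least 100 amino acids are kept).
#' @return data frame with columns \code{transcript_id}, \code{strand},
#'   \code{frame}, \code{start}, \code{end}, \code{protein},
#'   \code{completeness}, sorted by protein length, longest first.
#' @export
find_orfs <- function(sequence, id = "transcript", min_aa = 100L) {
  stopifnot(min_aa >= 1L)
  sequence <- toupper(sequence)
  .validate_dna(sequence, sprintf("transcript %s", id))
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") sequence else .revcomp(sequence)
    L <- nchar(s)
    for (frame in 0:2) {
      n_codons <- (L - frame) %/% 3L
      if (n_codons < 1L) next
      codons <- .split_codons(substr(s, frame + 1L, frame + 3L * n_codons))
      aa <- .aa_of(codons)
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)            # codon index of segment start
      seg_stop <- c(stops, n_codons + 1L)       # codon index of bounding stop
      for (k in seq_along(seg_start)) {
        i0 <- seg_start[k]
        i1 <- seg_stop[k]                        # stop codon or one past end
        if (i1 - i0 < 1L) next
        has_stop <- i1 <= n_codons
        atg <- which(codons[seq.int(i0, i1 - 1L)] == "ATG")
        if (length(atg) > 0L) {
          a0 <- i0 + atg[1L] - 1L
          prot <- paste(aa[seq.int(a0, i1 - 1L)], collapse = "")
          completeness <- if (has_stop) "complete" else "3'-partial"
          c_end <- if (has_stop) i1 else i1 - 1L
          res[[length(res) + 1L]] <- data.frame(
            transcript_id = id, strand = strand, frame = frame,
            start = frame + (a0 - 1L) * 3L,
            end = frame + c_end * 3L,
            protein = prot,
            completeness = completeness,
            stringsAsFactors = FALSE)
        } else if (i0 == 1L) {
          # runs in from the transcript edge: plausible 5'-truncated CDS
          prot <- paste(aa[seq.int(i0, i1 - 1L)], collapse = "")
          completeness <- if (has_stop) "5'-partial" else "internal"
          c_end <- if (has_stop) i1 else i1 - 1L
          res[[length(res) + 1L]] <- data.frame(
            transcript_id = id, strand = strand, frame = frame,
            start = frame + (i0 - 1L) * 3L,
            end = frame + c_end * 3L,
            protein = prot,
            completeness = completeness,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(transcript_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0), end = integer(0),
                      protein = character(0), completeness = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[nchar(out$protein) >= min_aa, , drop = FALSE]
  out <- out[order(-nchar(out$protein), out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict coding regions for a whole transcript table
#'
#' Applies [find_orfs()] to every transcript and returns the pooled CDS
#' table; \code{cds_id} is \code{<transcript_id>.p<rank>} with rank 1 the
#' longest ORF of that transcript.
#'
#' @param transcripts transcript data frame.
#' @param min_aa minimum protein length (residues).
#' @param longest_only keep only the single longest ORF per transcript.
#' @return CDS data frame.
#' @export
predict_cds <- function(transcripts, min_aa = 100L, longest_only = FALSE) {
  per <- lapply(seq_len(nrow(transcripts)), function(i) {
    orfs <- find_orfs(transcripts$sequence[i], transcripts$id[i], min_aa)
    if (nrow(orfs) == 0L) return(orfs)
    if (longest_only) orfs <- orfs[1L, , drop = FALSE]
    orfs$cds_id <- sprintf("%s.p%d", orfs$transcript_id, seq_len(nrow(orfs)))
    orfs
  })
  per <- per[vapply(per, nrow, integer(1)) > 0L]
  if (length(per) == 0L) {
    return(data.frame(transcript_id = character(0), strand = character(0),
                      frame = integer(0), start = integer(0), end = integer(0),
                      protein = character(0), completeness = character(0),
                      cds_id = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Extract the nucleotide sequence of a CDS record
#'
#' @param sequence the transcript's forward-strand sequence.
#' @param cds one row of a CDS table from [find_orfs()].
#' @param drop_stop drop the terminal stop codon if present.
#' @return DNA string of the coding sequence, on the coding strand.
#' @export
cds_sequence <- function(sequence, cds, drop_stop = TRUE) {
  s <- if (cds$strand == "+") toupper(sequence) else .revcomp(toupper(sequence))
  nt <- substr(s, cds$start + 1L, cds$end)
  if (drop_stop && nchar(nt) >= 3L) {
    last <- substr(nt, nchar(nt) - 2L, nchar(nt))
    if (.aa_of(last) == "*") nt <- substr(nt, 1L, nchar(nt) - 3L)
  }
  nt
}

#' Translate a coding sequence with the standard genetic code
#'
#' A terminal stop codon is dropped; an internal stop is an error.  Codons
#' containing \code{N} translate to \code{X}.
#'
#' @param nt DNA string whose length is a multiple of 3.
#' @return protein string.
#' @export
translate_cds <- function(nt) {
  nt <- toupper(nt)
  .validate_dna(nt, "CDS")
  aa <- .aa_of(.split_codons(nt))
  n <- length(aa)
  if (n > 0L && aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) stop("internal stop codon in CDS", call. = FALSE)
  paste(aa, collapse = "")
}
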