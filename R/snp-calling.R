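#' Caller thresholds
#'
#' Bundles the filters applied during SNP calling: minimum retained coverage
#' per species, minimum base (Phred) quality, minimum mapping quality where a
#' per-read mapping quality is visible (read-start markers), the minimum
#' number of reads supporting the alternate allele and the minimum alternate
#' allele frequency.  Coverage 42 and the two quality-30 cutoffs are the
#' stringent transcriptome screen this pipeline is built around; the
#' alternate-read and frequency floors mirror common variant-caller
#' defaults.
#'
#' @param min_coverage minimum retained read depth per species (default 42).
#' @param min_base_quality minimum Phred base quality (default 30); calls
#'   below it are dropped before anything else is evaluated.
#' @param min_mapping_quality minimum mapping quality (default 30), applied
#'   to calls whose read-start marker exposes a per-read mapping quality;
#'   other calls carry no mapping quality in the text pileup and pass
#'   through.
#' @param min_alt_reads minimum reads carrying the alternate allele
#'   (default 2).
#' @param min_alt_frequency minimum alternate allele frequency, measured
#'   against retained depth (default 0.20).
#' @return a list of class \code{caller_thresholds}.
#' @export
caller_thresholds <- function(min_coverage = 42L, min_base_quality = 30L,
                              min_mapping_quality = 30L, min_alt_reads = 2L,
                              min_alt_frequency = 0.20) {
  stopifnot(min_coverage >= 0, min_base_quality >= 0,
            min_mapping_quality >= 0, min_alt_reads >= 0,
            min_alt_frequency >= 0, min_alt_frequency <= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_alt_frequency = min_alt_frequency),
            class = "caller_thresholds")
}

# Character codes used by the scalar base-string parser.
.PILEUP_BASES <- c("A", "C", "G", "T", "N")

# Full scalar decode of one pileup base string; handles every marker the
# format defines.  Returns per-call base/strand/mapq and a logical marking
# real base calls (FALSE for * # > < placeholders, which still consume a
# quality character).
.parse_base_string <- function(bases, ref, line_no = NA_integer_) {
  v <- utf8ToInt(bases)
  n <- length(v)
  base <- character(n); strand <- character(n)
  mapq <- integer(n); is_call <- logical(n)
  m <- 0L
  i <- 1L
  pending_mq <- NA_integer_
  while (i <= n) {
    ch <- v[i]
    if (ch == 46L || ch == 44L) {                       # . ,
      m <- m + 1L
      base[m] <- ref
      strand[m] <- if (ch == 46L) "+" else "-"
      mapq[m] <- pending_mq; pending_mq <- NA_integer_
      is_call[m] <- TRUE
      i <- i + 1L
    } else if (ch == 94L) {                             # ^ + mapq char
      if (i + 1L > n) {
        stop(sprintf("line %s: dangling read-start marker", line_no),
             call. = FALSE)
      }
      pending_mq <- v[i + 1L] - 33L
      i <- i + 2L
    } else if (ch == 36L) {                             # $
      i <- i + 1L
    } else if (ch == 43L || ch == 45L) {                # +n / -n indel
      j <- i + 1L
      while (j <= n && v[j] >= 48L && v[j] <= 57L) j <- j + 1L
      if (j == i + 1L) {
        stop(sprintf("line %s: malformed indel marker", line_no),
             call. = FALSE)
      }
      len <- as.integer(intToUtf8(v[seq.int(i + 1L, j - 1L)]))
      i <- j + len
    } else if (ch == 42L || ch == 35L || ch == 62L || ch == 60L) { # * # > <
      m <- m + 1L
      base[m] <- NA_character_; strand[m] <- NA_character_
      mapq[m] <- pending_mq; pending_mq <- NA_integer_
      is_call[m] <- FALSE
      i <- i + 1L
    } else {
      up <- if (ch >= 97L) ch - 32L else ch
      bch <- intToUtf8(up)
      if (!(bch %in% .PILEUP_BASES)) {
        stop(sprintf("line %s: unexpected character '%s' in pileup bases",
                     line_no, intToUtf8(ch)), call. = FALSE)
      }
      m <- m + 1L
      base[m] <- bch
      strand[m] <- if (ch < 97L) "+" else "-"
      mapq[m] <- pending_mq; pending_mq <- NA_integer_
      is_call[m] <- TRUE
      i <- i + 1L
    }
  }
  list(base = base[seq_len(m)], strand = strand[seq_len(m)],
       mapq = mapq[seq_len(m)], is_call = is_call[seq_len(m)])
}

#' Parse a samtools 6-column text pileup
#'
#' Handles read-start markers \verb{^X} (consuming the following
#' mapping-quality character and attaching the decoded quality to the
#' read's call), read-end \code{$}, \code{.}/\code{,} reference matches with
#' strand, case-coded mismatches, \code{*}/\code{#} deletion placeholders
#' and \code{>}/\code{<} reference skips (consumed, not reported as calls)
#' and \verb{+n}/\verb{-n} indel suffixes (consumed and ignored).  Base and
#' mapping qualities are decoded as Phred+33.
#'
#' @param path path to a pileup file.
#' @param text optional character vector of pileup lines, used instead of
#'   \code{path}.
#' @return a list of pileup columns; each element carries
#'   \code{transcript_id}, \code{pos}, \code{ref}, \code{depth} (retained
#'   base calls) and the per-call vectors \code{base}, \code{qual},
#'   \code{strand}, \code{mapq} (NA where the column does not expose it).
#' @export
parse_pileup <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[nzchar(lines)]
  nl <- length(lines)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 6L)) {
    bad <- which(nfield != 6L)[1]
    stop(sprintf("line %d: expected 6 tab-separated columns, got %d",
                 bad, nfield[bad]), call. = FALSE)
  }
  tid <- vapply(parts, `[[`, character(1), 1L)
  pos <- as.integer(vapply(parts, `[[`, character(1), 2L))
  ref <- toupper(vapply(parts, `[[`, character(1), 3L))
  bstr <- vapply(parts, `[[`, character(1), 5L)
  qstr <- vapply(parts, `[[`, character(1), 6L)
  simple <- grepl("^[.,ACGTacgt]+$", bstr)
  out <- vector("list", nl)
  up <- c("A", "C", "G", "T")
  lo <- c("a", "c", "g", "t")
  for (ln in seq_len(nl)) {
    quals <- utf8ToInt(qstr[ln]) - 33L
    if (simple[ln]) {
      ch <- strsplit(bstr[ln], "", fixed = TRUE)[[1]]
      if (length(quals) != length(ch)) {
        stop(sprintf(
          "line %d: quality string length %d does not match %d calls",
          ln, length(quals), length(ch)), call. = FALSE)
      }
      isref <- ch == "." | ch == ","
      fwd <- ch == "." | ch %in% up
      base <- ifelse(isref, ref[ln], toupper(ch))
      out[[ln]] <- list(transcript_id = tid[ln], pos = pos[ln], ref = ref[ln],
                        depth = length(ch), base = base,
                        qual = quals,
                        strand = ifelse(fwd, "+", "-"),
                        mapq = rep(NA_integer_, length(ch)))
    } else {
      p <- .parse_base_string(bstr[ln], ref[ln], ln)
      if (length(quals) != length(p$base)) {
        stop(sprintf(
          "line %d: quality string length %d does not match %d parsed calls",
          ln, length(quals), length(p$base)), call. = FALSE)
      }
      keep <- p$is_call & !is.na(p$base) & p$base != "N"
      out[[ln]] <- list(transcript_id = tid[ln], pos = pos[ln], ref = ref[ln],
                        depth = sum(keep), base = p$base[keep],
                        qual = quals[keep], strand = p$strand[keep],
                        mapq = p$mapq[keep])
    }
  }
  out
}

# Retained A/C/G/T counts for one parsed column under the thresholds.
.column_counts <- function(column, thresholds) {
  keep <- column$qual >= thresholds$min_base_quality &
    (is.na(column$mapq) | column$mapq >= thresholds$min_mapping_quality)
  b <- column$base[keep]
  c(A = sum(b == "A"), C = sum(b == "C"), G = sum(b == "G"),
    T = sum(b == "T"))
}

#' Summarize a pileup into per-site retained base counts
#'
#' Applies the base-quality (and, where exposed, mapping-quality) filters
#' and tabulates the retained calls per nucleotide.  This is the
#' per-species input to [joint_sites()]; sites below \code{min_coverage}
#' are kept here with their counts so that the joint step can enforce
#' coverage in both species.
#'
#' @param pileup result of [parse_pileup()], or a path to a pileup file.
#' @param thresholds a [caller_thresholds()] object.
#' @return data frame with columns \code{transcript_id}, \code{pos},
#'   \code{ref}, \code{depth} (retained), \code{A}, \code{C}, \code{G},
#'   \code{T}.
#' @export
pileup_site_counts <- function(pileup, thresholds = caller_thresholds()) {
  if (is.character(pileup)) pileup <- parse_pileup(pileup)
  cnt <- t(vapply(pileup, .column_counts,
                  c(A = 0L, C = 0L, G = 0L, T = 0L),
                  thresholds = thresholds))
  data.frame(
    transcript_id = vapply(pileup, `[[`, character(1), "transcript_id"),
    pos = vapply(pileup, `[[`, integer(1), "pos"),
    ref = vapply(pileup, `[[`, character(1), "ref"),
    depth = as.integer(rowSums(cnt)),
    A = as.integer(cnt[, "A"]), C = as.integer(cnt[, "C"]),
    G = as.integer(cnt[, "G"]), T = as.integer(cnt[, "T"]),
    stringsAsFactors = FALSE, row.names = NULL)
}

# Vectorized variant decision over a count matrix (n x 4, columns ACGT).
# Returns npass (number of qualifying alternate alleles), and for rows with
# exactly one, its column index.
.variant_scan <- function(cnt, ref_idx, thresholds) {
  depth <- rowSums(cnt)
  pass <- cnt >= thresholds$min_alt_reads &
    cnt / pmax(depth, 1L) >= thresholds$min_alt_frequency
  pass[cbind(seq_len(nrow(cnt)), ref_idx)] <- FALSE
  npass <- rowSums(pass)
  alt_idx <- max.col(pass, ties.method = "first")
  alt_idx[npass != 1L] <- NA_integer_
  list(npass = npass, alt_idx = alt_idx, depth = depth)
}

#' Call a variant at one pileup column
#'
#' Drops calls below the base-quality threshold, requires retained depth of
#' at least \code{min_coverage}, takes the qualifying non-reference base as
#' the alternate allele and emits a call only when it is supported by at
#' least \code{min_alt_reads} reads at frequency at least
#' \code{min_alt_frequency}.  A site with more than one qualifying
#' alternate allele is multiallelic and excluded (no call).
#'
#' @param column one element of [parse_pileup()] output.
#' @param thresholds a [caller_thresholds()] object.
#' @return a one-row data frame (\code{transcript_id}, \code{pos},
#'   \code{ref}, \code{alt}, \code{ref_count}, \code{alt_count},
#'   \code{frequency}) or \code{NULL} when no call is made.
#' @export
call_site <- function(column, thresholds = caller_thresholds()) {
  cnt <- matrix(.column_counts(column, thresholds), nrow = 1,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  if (sum(cnt) < thresholds$min_coverage) return(NULL)
  ref_idx <- match(column$ref, c("A", "C", "G", "T"))
  vs <- .variant_scan(cnt, ref_idx, thresholds)
  if (is.na(vs$alt_idx[1])) return(NULL)
  alt <- c("A", "C", "G", "T")[vs$alt_idx[1]]
  rc <- cnt[1, column$ref]; ac <- cnt[1, alt]
  data.frame(transcript_id = column$transcript_id, pos = column$pos,
             ref = column$ref, alt = alt,
             ref_count = unname(rc), alt_count = unname(ac),
             frequency = unname(ac / (rc + ac)),
             stringsAsFactors = FALSE)
}

#' Joint interspecific sites from two per-species count tables
#'
#' A joint site is reported where at least one species has a variant call
#' and both species retain depth of at least \code{min_coverage}.  The
#' alternate allele is defined globally (the same nucleotide in both
#' species); a species with no reads of that allele gets frequency 0.
#' Sites where the two species call different alternate alleles, or where
#' either species is multiallelic, are excluded: the differentiation index
#' presumes one shared biallelic axis.
#'
#' Frequencies are exact ratios of integer read counts, so fixed sites come
#' out at exactly 0 and 1.
#'
#' @param counts_a,counts_b per-species [pileup_site_counts()] tables
#'   against the same reference transcriptome.
#' @param thresholds a [caller_thresholds()] object.
#' @return data frame with one row per joint site: \code{transcript_id},
#'   \code{pos}, \code{ref}, \code{alt}, per-species ref/alt counts and
#'   retained depths, and frequencies \code{freq_a}, \code{freq_b} of the
#'   shared alternate allele.
#' @export
joint_sites <- function(counts_a, counts_b,
                        thresholds = caller_thresholds()) {
  nt <- c("A", "C", "G", "T")
  key_a <- paste(counts_a$transcript_id, counts_a$pos)
  key_b <- paste(counts_b$transcript_id, counts_b$pos)
  common <- intersect(key_a, key_b)
  ia <- match(common, key_a)
  ib <- match(common, key_b)
  empty <- data.frame(transcript_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      ref_count_a = integer(0), alt_count_a = integer(0),
                      ref_count_b = integer(0), alt_count_b = integer(0),
                      depth_a = integer(0), depth_b = integer(0),
                      freq_a = numeric(0), freq_b = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(common) == 0L) return(empty)
  ref <- counts_a$ref[ia]
  mism <- ref != counts_b$ref[ib]
  if (any(mism)) {
    stop(sprintf("reference base mismatch between pileups at %s",
                 common[which(mism)[1]]), call. = FALSE)
  }
  A <- as.matrix(counts_a[ia, nt]); storage.mode(A) <- "integer"
  B <- as.matrix(counts_b[ib, nt]); storage.mode(B) <- "integer"
  ref_idx <- match(ref, nt)
  va <- .variant_scan(A, ref_idx, thresholds)
  vb <- .variant_scan(B, ref_idx, thresholds)
  cov_ok <- va$depth >= thresholds$min_coverage &
    vb$depth >= thresholds$min_coverage
  multi <- va$npass > 1L | vb$npass > 1L
  has_a <- !is.na(va$alt_idx); has_b <- !is.na(vb$alt_idx)
  discordant <- has_a & has_b & va$alt_idx != vb$alt_idx
  keep <- cov_ok & !multi & (has_a | has_b) & !discordant
  if (!any(keep)) return(empty)
  alt_idx <- ifelse(has_a, va$alt_idx, vb$alt_idx)[keep]
  i <- which(keep)
  rca <- A[cbind(i, ref_idx[keep])]; aca <- A[cbind(i, alt_idx)]
  rcb <- B[cbind(i, ref_idx[keep])]; acb <- B[cbind(i, alt_idx)]
  out <- data.frame(
    transcript_id = counts_a$transcript_id[ia][keep],
    pos = counts_a$pos[ia][keep],
    ref = ref[keep], alt = nt[alt_idx],
    ref_count_a = rca, alt_count_a = aca,
    ref_count_b = rcb, alt_count_b = acb,
    depth_a = as.integer(va$depth[keep]),
    depth_b = as.integer(vb$depth[keep]),
    stringsAsFactors = FALSE)
  den_a <- out$ref_count_a + out$alt_count_a
  den_b <- out$ref_count_b + out$alt_count_b
  out$freq_a <- ifelse(den_a > 0, out$alt_count_a / den_a, 0)
  out$freq_b <- ifelse(den_b > 0, out$alt_count_b / den_b, 0)
  ord <- order(out$transcript_id, out$pos)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
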