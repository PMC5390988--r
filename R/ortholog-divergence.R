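#' Scoring scheme for protein similarity search and alignment
#'
#' Parameters of the local-alignment ortholog search and the global
#' pairwise alignment: substitution matrix, affine gap penalties (positive
#' numbers, subtracted from the score) and the reciprocal-best-hit
#' acceptance threshold as an approximate E-value.  E-values use
#' Karlin-Altschul statistics \eqn{E = K m n e^{-\lambda S}} with the
#' conventional gapped BLOSUM62 (open 11 / extend 1) parameters
#' \eqn{\lambda = 0.267}, \eqn{K = 0.041}; the best-hit decision itself is
#' score-rank based, so the approximation only moves the absolute cutoff.
#'
#' @param matrix substitution matrix name (default \code{"BLOSUM62"}).
#' @param gap_open,gap_extend affine gap penalties (defaults 11 and 1).
#' @param evalue_max maximum approximate E-value for an accepted hit
#'   (default \code{1e-12}).
#' @param lambda,K Karlin-Altschul parameters for the chosen scoring system.
#' @return a list of class \code{scoring_scheme}.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           evalue_max = 1e-12, lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= 0, gap_extend >= 0, evalue_max > 0,
            lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, evalue_max = evalue_max,
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

.AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYBZXUJO*"

.validate_protein <- function(p, what = "protein") {
  ok <- grepl(sprintf("^[%s]*$", .AA_ALPHABET), p)
  if (!all(ok)) {
    stop(sprintf("%s contains non-amino-acid characters", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Approximate Karlin-Altschul E-value for a local alignment raw score.
.evalue <- function(score, m, n, scheme) {
  scheme$K * m * n * exp(-scheme$lambda * score)
}

# k-mer index: term -> integer indices of sequences containing it.
.kmer_index <- function(seqs, k) {
  env <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) next
    kmers <- unique(substring(s, 1:(n - k + 1L), k:n))
    for (km in kmers) env[[km]] <- c(env[[km]], i)
  }
  env
}

#' Reciprocal best hits between two proteomes
#'
#' All-versus-all local (Smith-Waterman) alignment, with a shared k-mer
#' prefilter to skip pairs with no exact word match (the same heuristic
#' seeded search strategy BLAST-style tools use).  A pair (a, b) is kept
#' when b is a's unique best-scoring hit and a is b's, and the approximate
#' E-value of their alignment is at most \code{scheme$evalue_max}.  A tie
#' for the best score eliminates the query from pairing.
#'
#' @param proteome_a,proteome_b named character vectors of protein
#'   sequences.
#' @param scheme a [scoring_scheme()].
#' @param kmer word length of the prefilter (default 4).
#' @return data frame with columns \code{id_a}, \code{id_b}, \code{score},
#'   \code{evalue}.
#' @export
reciprocal_best_hits <- function(proteome_a, proteome_b,
                                 scheme = scoring_scheme(), kmer = 4L) {
  if (length(proteome_a) == 0L || length(proteome_b) == 0L) {
    stop("empty proteome", call. = FALSE)
  }
  .validate_protein(proteome_a, "proteome_a")
  .validate_protein(proteome_b, "proteome_b")
  idx_b <- .kmer_index(proteome_b, kmer)
  ai <- integer(0); bi <- integer(0)
  for (i in seq_along(proteome_a)) {
    s <- proteome_a[[i]]
    n <- nchar(s)
    if (n < kmer) next
    kmers <- unique(substring(s, 1:(n - kmer + 1L), kmer:n))
    cand <- unique(unlist(lapply(kmers, function(km) idx_b[[km]]),
                          use.names = FALSE))
    if (length(cand) == 0L) next
    ai <- c(ai, rep.int(i, length(cand)))
    bi <- c(bi, cand)
  }
  if (length(ai) == 0L) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      score = numeric(0), evalue = numeric(0)))
  }
  score <- numeric(length(ai))
  for (i in unique(ai)) {
    rows <- which(ai == i)
    score[rows] <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(proteome_b[bi[rows]]),
      subject = proteome_a[[i]],
      type = "local", substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
      scoreOnly = TRUE)
  }
  ev <- .evalue(score, nchar(proteome_a)[ai], nchar(proteome_b)[bi], scheme)
  hits <- data.frame(ai = ai, bi = bi, score = score, evalue = ev)
  best_unique <- function(df, by) {
    keep <- logical(nrow(df))
    for (q in unique(df[[by]])) {
      rows <- which(df[[by]] == q)
      mx <- max(df$score[rows])
      top <- rows[df$score[rows] == mx]
      if (length(top) == 1L) keep[top] <- TRUE   # a tie eliminates the query
    }
    keep
  }
  ba <- best_unique(hits, "ai")
  bb <- best_unique(hits, "bi")
  rbh <- hits[ba & bb & hits$evalue <= scheme$evalue_max, , drop = FALSE]
  out <- data.frame(id_a = names(proteome_a)[rbh$ai],
                    id_b = names(proteome_b)[rbh$bi],
                    score = rbh$score, evalue = rbh$evalue,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with affine gaps under the scheme's
#' substitution matrix.  For two sequences this is the exact optimum of the
#' scoring scheme.
#'
#' @param p1,p2 ungapped protein strings.
#' @param scheme a [scoring_scheme()].
#' @return list with aligned strings \code{a1}, \code{a2} (equal length;
#'   removing gaps recovers the inputs) and the alignment \code{score}.
#' @export
align_protein_pair <- function(p1, p2, scheme = scoring_scheme()) {
  if (nchar(p1) == 0L || nchar(p2) == 0L) {
    stop("empty protein sequence", call. = FALSE)
  }
  if (grepl("-", p1, fixed = TRUE) || grepl("-", p2, fixed = TRUE)) {
    stop("input proteins must be ungapped", call. = FALSE)
  }
  .validate_protein(c(p1, p2))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(p1), subject = Biostrings::AAString(p2),
    type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  list(a1 = as.character(Biostrings::alignedPattern(pa)),
       a2 = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

#' Thread CDS codons through a protein alignment
#'
#' Replaces each aligned residue by its source codon and each gap by
#' \code{---}, producing a codon alignment three times the protein
#' alignment length.  Each protein must retranslate exactly from its CDS
#' (terminal stop codons in the CDS are ignored).
#'
#' @param aln protein alignment from [align_protein_pair()] (or any list
#'   with gapped strings \code{a1}, \code{a2}).
#' @param cds_1,cds_2 the coding sequences behind the two proteins.
#' @return list with codon vectors \code{codons_1}, \code{codons_2}
#'   (\code{"---"} at gaps).
#' @export
backtranslate_alignment <- function(aln, cds_1, cds_2) {
  thread_one <- function(a, cds, which) {
    prot <- gsub("-", "", a, fixed = TRUE)
    tr <- translate_cds(cds)
    if (tr != prot) {
      stop(sprintf("protein %s does not retranslate from its CDS", which),
           call. = FALSE)
    }
    codons <- .split_codons(cds)[seq_len(nchar(prot))]
    chars <- strsplit(a, "", fixed = TRUE)[[1]]
    out <- rep("---", length(chars))
    out[chars != "-"] <- codons
    out
  }
  list(codons_1 = thread_one(aln$a1, cds_1, "1"),
       codons_2 = thread_one(aln$a2, cds_2, "2"))
}

# Per-codon synonymous site fractions, NG86 convention: at each position the
# three single-base mutants are classified; mutants that create a stop codon
# are excluded from the denominator at that position.
.ng86_site_table <- function() {
  if (!is.null(.diverscan_env$ng86_sites)) return(.diverscan_env$ng86_sites)
  ct <- .codon_table()
  sense <- .sense_codons()
  nt <- c("A", "C", "G", "T")
  syn <- numeric(length(sense))
  names(syn) <- sense
  for (cod in sense) {
    ch <- strsplit(cod, "", fixed = TRUE)[[1]]
    aa0 <- ct[[cod]]
    tot <- 0
    for (p in 1:3) {
      muts <- vapply(setdiff(nt, ch[p]), function(b) {
        x <- ch; x[p] <- b; paste(x, collapse = "")
      }, character(1))
      aam <- ct[muts]
      valid <- aam != "*"
      if (any(valid)) tot <- tot + sum(aam[valid] == aa0) / sum(valid)
    }
    syn[cod] <- tot
  }
  .diverscan_env$ng86_sites <- syn
  syn
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each codon position the three single-base mutants are enumerated;
#' the position contributes its fraction of synonymous mutants to the
#' synonymous site count, with mutants creating stop codons excluded from
#' the denominator at that position.  The two counts always sum to 3.
#'
#' @param codon character vector of sense codons over \code{A,C,G,T}.
#' @return data frame with columns \code{codon}, \code{syn_sites},
#'   \code{nonsyn_sites}.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  tbl <- .ng86_site_table()
  bad <- !(codon %in% names(tbl))
  if (any(bad)) {
    stop(sprintf("not a sense codon: %s",
                 paste(unique(codon[bad]), collapse = ", ")), call. = FALSE)
  }
  s <- unname(tbl[codon])
  data.frame(codon = codon, syn_sites = s, nonsyn_sites = 3 - s,
             stringsAsFactors = FALSE)
}

.PERMS <- list(matrix(1L, 1, 1),
               rbind(c(1L, 2L), c(2L, 1L)),
               rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                     c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Pathway-averaged (synonymous, nonsynonymous) difference counts between two
# sense codons.  All k! orderings of the k differing positions are walked;
# orderings passing through a stop codon are excluded (when every ordering
# is blocked, all are used).  Memoized.
.codon_pair_diff <- function(c1, c2) {
  if (is.null(.diverscan_env$pair_diff)) {
    .diverscan_env$pair_diff <- new.env(parent = emptyenv(), hash = TRUE)
  }
  memo <- .diverscan_env$pair_diff
  key <- paste0(c1, c2)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  ct <- .codon_table()
  a <- strsplit(c1, "", fixed = TRUE)[[1]]
  b <- strsplit(c2, "", fixed = TRUE)[[1]]
  dpos <- which(a != b)
  k <- length(dpos)
  if (k == 0L) {
    res <- c(sd = 0, nd = 0)
    memo[[key]] <- res
    return(res)
  }
  perms <- .PERMS[[k]]
  syn_per_path <- numeric(nrow(perms))
  valid <- logical(nrow(perms))
  for (pi in seq_len(nrow(perms))) {
    cur <- a
    syn <- 0
    ok <- TRUE
    for (step in perms[pi, ]) {
      nxt <- cur
      nxt[dpos[step]] <- b[dpos[step]]
      aa_cur <- ct[[paste(cur, collapse = "")]]
      aa_nxt <- ct[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*") ok <- FALSE   # endpoint is sense, so this is an
                                       # intermediate stop: pathway excluded
      if (identical(aa_cur, aa_nxt)) syn <- syn + 1
      cur <- nxt
    }
    syn_per_path[pi] <- syn
    valid[pi] <- ok
  }
  use <- if (any(valid)) valid else rep(TRUE, nrow(perms))
  sd <- mean(syn_per_path[use])
  res <- c(sd = sd, nd = k - sd)
  memo[[key]] <- res
  res
}

#' NG86 pairwise divergence from a codon alignment
#'
#' Nei-Gojobori (1986) counting: synonymous and nonsynonymous site totals
#' are averaged over the two sequences; differences at codons diverging at
#' more than one position are averaged over all mutational pathways
#' (excluding pathways through stop codons); proportions are
#' Jukes-Cantor-corrected, \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}.
#' Columns containing a gap, an ambiguous base or a stop codon are skipped.
#'
#' When no synonymous difference is observed but nonsynonymous divergence
#' exists, the ratio is reported capped at 50 with Ks back-set to Ka/50 and
#' \code{capped = TRUE}.  A proportion of 3/4 or more cannot be corrected:
#' the estimate is flagged \code{saturated} and no ratio is reported.
#'
#' @param codons_1,codons_2 codon vectors from [backtranslate_alignment()].
#' @return list with \code{n_codons} (comparable columns), \code{S},
#'   \code{N}, \code{Sd}, \code{Nd}, \code{pS}, \code{pN}, \code{ka},
#'   \code{ks}, \code{ratio} and flags \code{capped}, \code{saturated},
#'   \code{no_divergence}.
#' @export
ng86_pairwise <- function(codons_1, codons_2) {
  stopifnot(length(codons_1) == length(codons_2))
  tbl <- .ng86_site_table()
  ok <- codons_1 %in% names(tbl) & codons_2 %in% names(tbl)
  c1 <- codons_1[ok]; c2 <- codons_2[ok]
  if (length(c1) == 0L) {
    stop("no comparable codon columns in alignment", call. = FALSE)
  }
  S <- (sum(tbl[c1]) + sum(tbl[c2])) / 2
  N <- 3 * length(c1) - S
  diff <- c1 != c2
  Sd <- 0; Nd <- 0
  for (i in which(diff)) {
    d <- .codon_pair_diff(c1[i], c2[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pS <- if (S > 0) Sd / S else 0      # S = 0 only when Sd = 0 too
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ka <- jc(pN); ks <- jc(pS)
  saturated <- is.na(ka) || is.na(ks)
  no_div <- !saturated && Sd == 0 && Nd == 0
  capped <- FALSE
  ratio <- NA_real_
  if (saturated) {
    ratio <- NA_real_
  } else if (no_div) {
    ratio <- NA_real_
  } else if (pS == 0) {
    ratio <- 50
    ks <- ka / 50
    capped <- TRUE
  } else {
    ratio <- ka / ks
  }
  list(n_codons = length(c1), S = S, N = N, Sd = unname(Sd), Nd = unname(Nd),
       pS = pS, pN = pN, ka = ka, ks = ks, ratio = ratio,
       capped = capped, saturated = saturated, no_divergence = no_div)
}

#' Ka/Ks for a table of ortholog pairs
#'
#' For every reciprocal-best-hit pair: global protein alignment,
#' back-translation to a codon alignment, NG86 counting.
#'
#' @param pairs data frame with columns \code{id_a}, \code{id_b} (e.g. from
#'   [reciprocal_best_hits()]).
#' @param cds_a,cds_b named character vectors of coding sequences.
#' @param scheme a [scoring_scheme()].
#' @return data frame with one row per pair: ids, \code{n_codons}, \code{S},
#'   \code{N}, \code{Sd}, \code{Nd}, \code{ka}, \code{ks}, \code{ratio} and
#'   the three flags.
#' @export
kaks_pairs <- function(pairs, cds_a, cds_b, scheme = scoring_scheme()) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ca <- cds_a[[pairs$id_a[i]]]
    cb <- cds_b[[pairs$id_b[i]]]
    aln <- align_protein_pair(translate_cds(ca), translate_cds(cb), scheme)
    cod <- backtranslate_alignment(aln, ca, cb)
    ng <- ng86_pairwise(cod$codons_1, cod$codons_2)
    data.frame(id_a = pairs$id_a[i], id_b = pairs$id_b[i],
               n_codons = ng$n_codons, S = ng$S, N = ng$N,
               Sd = ng$Sd, Nd = ng$Nd, ka = ng$ka, ks = ng$ks,
               ratio = ng$ratio, capped = ng$capped,
               saturated = ng$saturated, no_divergence = ng$no_divergence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the paralog filter and flag positive-selection candidates
#'
#' Pairs with \code{Ks >= ks_max} (default 1) are too synonymously diverged
#' for within-pair orthology and are flagged \code{paralog_filtered};
#' remaining pairs with \code{ratio > 1} are flagged \code{candidate}.
#'
#' @param pairs a [kaks_pairs()] data frame.
#' @param ks_max inclusive paralog cutoff on Ks (default 1).
#' @return the input with logical columns \code{paralog_filtered} and
#'   \code{candidate} added.
#' @export
filter_and_flag <- function(pairs, ks_max = 1) {
  pairs$paralog_filtered <- !is.na(pairs$ks) & pairs$ks >= ks_max
  pairs$paralog_filtered[pairs$saturated] <- TRUE  # cannot bound Ks below 1
  pairs$candidate <- !pairs$paralog_filtered &
    !is.na(pairs$ratio) & pairs$ratio > 1
  pairs
}

#' Candidate marker table: fixed and positively selected transcripts
#'
#' Inner join of the ortholog Ka/Ks table with the per-transcript
#' differentiation table: transcripts whose every SNP is a fixed
#' interspecific difference (\code{all_fixed}) and whose ortholog pair has
#' \code{ratio > 1} and survives the paralog filter.
#'
#' @param pairs a [filter_and_flag()]ed data frame that also carries a
#'   \code{transcript_id} column naming each pair's transcript on the
#'   reference assembly.
#' @param diff a [transcript_Dbar()] data frame on the same reference ids.
#' @return data frame with columns \code{transcript_id}, \code{n_snps},
#'   \code{dbar}, \code{ka}, \code{ks}, \code{ratio}, \code{capped}.
#' @export
candidate_markers <- function(pairs, diff) {
  if (is.null(pairs$transcript_id)) {
    stop("pairs must carry a transcript_id column on the reference assembly",
         call. = FALSE)
  }
  cand <- pairs[pairs$candidate, , drop = FALSE]
  fixed <- diff[diff$all_fixed, , drop = FALSE]
  m <- merge(cand, fixed, by = "transcript_id")
  out <- m[order(m$transcript_id),
           c("transcript_id", "n_snps", "dbar", "ka", "ks", "ratio",
             "capped")]
  rownames(out) <- NULL
  out
}
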