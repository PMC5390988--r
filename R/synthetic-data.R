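#' Simulation configuration for the two-species transcriptome generator
#'
#' Defines the statistical structure the generator plants: a set of
#' ancestral transcripts each carrying one long ORF, a controlled per-site
#' rate of fixed interspecific substitutions (with per-gene omega steering
#' their synonymous/nonsynonymous placement inside the CDS), shared and
#' private polymorphisms, Poisson sequencing depth with a two-level base
#' quality model, and a GO annotation table with one term planted at an
#' elevated rate in the fully fixed transcripts.
#'
#' @param n_transcripts number of unigenes (one isoform each).
#' @param length_range transcript length range in nt, within
#'   \code{[400, 40000]}.
#' @param gc_content target GC fraction.
#' @param fixed_diff_rate per-site probability of a fixed interspecific
#'   substitution.
#' @param shared_poly_rate per-site probability of a polymorphism shared by
#'   both species at equal frequency.
#' @param private_poly_rate per-site, per-species probability of a private
#'   polymorphism.
#' @param minor_allele_freq_range range the polymorphic alternate-allele
#'   frequency is drawn from.
#' @param depth_mean mean sequencing depth per site (Poisson, truncated at
#'   1).
#' @param base_error_rate per-base miscall probability.
#' @param bad_quality_fraction fraction of calls emitted at Phred 20 (below
#'   the quality-30 filter); the rest are Phred 40.
#' @param low_mapq_fraction fraction of reads dropped at generation time to
#'   model the mapping-quality filter (the 6-column text pileup carries no
#'   per-read mapping quality beyond the read-start marker).
#' @param read_marker_rate fraction of pileup lines decorated with a
#'   read-start (\verb{^]}) and read-end (\code{$}) marker.
#' @param min_cds_aa minimum planted ORF length in residues.
#' @param omega_default Ka/Ks ground truth used for genes absent from
#'   \code{omega_per_gene}.
#' @param omega_per_gene optional named vector, transcript id -> omega.
#' @param enriched_go_term GO identifier planted in fixed-difference
#'   transcripts.
#' @param go_n_terms number of background GO terms.
#' @param go_base_rate background per-(transcript, term) annotation
#'   probability.
#' @param go_enrichment_factor factor by which the planted term's rate is
#'   raised in fully fixed transcripts (default 5).
#' @param seed integer seed; identical seed and config give byte-identical
#'   outputs.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_transcripts = 100L,
                       length_range = c(600L, 2000L),
                       gc_content = 0.45,
                       fixed_diff_rate = 0.003,
                       shared_poly_rate = 0.001,
                       private_poly_rate = 0.0005,
                       minor_allele_freq_range = c(0.25, 0.5),
                       depth_mean = 80,
                       base_error_rate = 0,
                       bad_quality_fraction = 0.1,
                       low_mapq_fraction = 0,
                       read_marker_rate = 0.1,
                       min_cds_aa = 100L,
                       omega_default = 0.5,
                       omega_per_gene = NULL,
                       enriched_go_term = "GO:0099001",
                       go_n_terms = 40L,
                       go_base_rate = 0.05,
                       go_enrichment_factor = 5,
                       seed = 1L) {
  if (length(length_range) != 2L || length_range[1] > length_range[2] ||
      length_range[1] < 400L || length_range[2] > 40000L) {
    stop("length_range must be a nondecreasing pair within [400, 40000]",
         call. = FALSE)
  }
  rates <- c(fixed_diff_rate, shared_poly_rate, private_poly_rate,
             gc_content, base_error_rate, bad_quality_fraction,
             low_mapq_fraction, read_marker_rate, go_base_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates and fractions must lie in [0, 1]", call. = FALSE)
  }
  if (fixed_diff_rate + shared_poly_rate + private_poly_rate > 1) {
    stop("fixed_diff_rate + shared_poly_rate + private_poly_rate must not exceed 1",
         call. = FALSE)
  }
  if (any(minor_allele_freq_range < 0 | minor_allele_freq_range > 0.5) ||
      minor_allele_freq_range[1] > minor_allele_freq_range[2]) {
    stop("minor_allele_freq_range must be a nondecreasing pair within [0, 0.5]",
         call. = FALSE)
  }
  stopifnot(n_transcripts >= 1L, depth_mean >= 1, min_cds_aa >= 1L,
            omega_default >= 0, go_enrichment_factor >= 0, go_n_terms >= 1L)
  structure(list(n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 gc_content = gc_content,
                 fixed_diff_rate = fixed_diff_rate,
                 shared_poly_rate = shared_poly_rate,
                 private_poly_rate = private_poly_rate,
                 minor_allele_freq_range = minor_allele_freq_range,
                 depth_mean = depth_mean,
                 base_error_rate = base_error_rate,
                 bad_quality_fraction = bad_quality_fraction,
                 low_mapq_fraction = low_mapq_fraction,
                 read_marker_rate = read_marker_rate,
                 min_cds_aa = as.integer(min_cds_aa),
                 omega_default = omega_default,
                 omega_per_gene = omega_per_gene,
                 enriched_go_term = enriched_go_term,
                 go_n_terms = as.integer(go_n_terms),
                 go_base_rate = go_base_rate,
                 go_enrichment_factor = go_enrichment_factor,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.NT <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

.base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

# Sample sense codons with per-base probabilities implied by the GC target.
.sample_sense_codons <- function(n, gc) {
  sense <- .sense_codons()
  p <- .base_probs(gc)
  w <- vapply(strsplit(sense, "", fixed = TRUE),
              function(ch) prod(p[ch]), numeric(1))
  sample(sense, n, replace = TRUE, prob = w)
}

.sample_stop_codon <- function(gc) {
  stops <- .stop_codons()
  p <- .base_probs(gc)
  w <- vapply(strsplit(stops, "", fixed = TRUE),
              function(ch) prod(p[ch]), numeric(1))
  sample(stops, 1, prob = w)
}

#' Simulate an ancestral transcriptome with planted ORFs
#'
#' Each transcript carries exactly one planted ORF (ATG ... stop) on a
#' random strand, preceded in frame by a guard stop codon so that the
#' ORF's complete call has an exact expected start.  Base composition
#' follows the configured GC content.
#'
#' @param config a [sim_config()].
#' @return list with \code{transcripts} (transcript data frame, ids
#'   \code{c<i>_g1_i1}) and \code{orfs} (truth table: \code{transcript_id},
#'   \code{strand}, \code{frame}, \code{start}, \code{end} in 0-based
#'   half-open strand coordinates including the terminal stop, and
#'   \code{protein}).
#' @export
simulate_ancestral_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- .base_probs(config$gc_content)
  n <- config$n_transcripts
  ids <- sprintf("c%d_g1_i1", seq_len(n))
  seqs <- character(n)
  orfs <- vector("list", n)
  pick <- function(v) if (length(v) == 1L) v else sample(v, 1)
  for (i in seq_len(n)) {
    L <- pick(seq.int(config$length_range[1], config$length_range[2]))
    aa_max <- (L - 6L) %/% 3L - 1L
    aa_min <- min(config$min_cds_aa + 20L, aa_max)
    aa <- pick(seq.int(aa_min, max(aa_min, min(aa_max, 500L))))
    orf_nt <- 3L * (aa + 1L)                 # ATG + body + terminal stop
    pad_total <- L - orf_nt - 3L             # 3 nt guard stop before ATG
    pad_left <- if (pad_total > 0L) pick(0:pad_total) else 0L
    pad_right <- pad_total - pad_left
    body <- if (aa > 1L) {
      paste(.sample_sense_codons(aa - 1L, config$gc_content), collapse = "")
    } else ""
    oriented <- paste0(
      paste(sample(.NT, pad_left, replace = TRUE, prob = p), collapse = ""),
      .sample_stop_codon(config$gc_content),
      "ATG", body, .sample_stop_codon(config$gc_content),
      paste(sample(.NT, pad_right, replace = TRUE, prob = p), collapse = ""))
    strand <- sample(c("+", "-"), 1)
    seqs[i] <- if (strand == "+") oriented else .revcomp(oriented)
    start <- pad_left + 3L
    orfs[[i]] <- data.frame(
      transcript_id = ids[i], strand = strand, frame = start %% 3L,
      start = start, end = start + orf_nt,
      protein = translate_cds(substr(oriented, start + 1L,
                                     start + orf_nt - 3L)),
      stringsAsFactors = FALSE)
  }
  list(transcripts = data.frame(id = ids, species = "ancestor",
                                sequence = seqs, stringsAsFactors = FALSE),
       orfs = do.call(rbind, orfs))
}

# Classify a candidate single-base change at forward position `pos`
# (1-based) given the planted ORF.  Returns "noncoding", "syn", "nonsyn",
# or "blocked" (would touch a stop/guard codon or create a stop).
.change_class <- function(chars, L, orf, pos, new_base) {
  q0 <- if (orf$strand == "+") pos - 1L else L - pos   # 0-based oriented
  if (q0 >= orf$start - 3L && q0 < orf$start) return("blocked")  # guard stop
  if (q0 >= orf$end - 3L && q0 < orf$end) return("blocked")      # stop codon
  if (q0 < orf$start || q0 >= orf$end - 3L) return("noncoding")
  ci <- (q0 - orf$start) %/% 3L
  off <- (q0 - orf$start) %% 3L
  o_pos <- orf$start + 3L * ci + 0:2                   # 0-based oriented
  f_pos <- if (orf$strand == "+") o_pos + 1L else L - o_pos   # 1-based fwd
  codon <- chars[f_pos]
  if (orf$strand == "-") codon <- unname(.COMP[codon])
  mutant <- codon
  mutant[off + 1L] <- if (orf$strand == "+") new_base else
    unname(.COMP[new_base])
  aa0 <- .aa_of(paste(codon, collapse = ""))
  aa1 <- .aa_of(paste(mutant, collapse = ""))
  if (aa1 == "*") return("blocked")
  if (aa0 == aa1) "syn" else "nonsyn"
}

#' Derive two species from an ancestral transcriptome
#'
#' Plants fixed interspecific substitutions (per-site rate
#' \code{fixed_diff_rate}; species B keeps the ancestral state and serves
#' as the reference assembly), shared polymorphisms (equal alternate
#' frequency in both species) and private polymorphisms.  Inside the
#' planted CDS the gene's omega steers the accepted substitutions'
#' synonymous/nonsynonymous mix by rejection sampling, so the expected
#' dN/dS of the planted changes equals omega; changes that would touch a
#' stop codon or create one are rejected.
#'
#' @param ancestor result of [simulate_ancestral_transcriptome()].
#' @param config a [sim_config()].
#' @return list with transcript tables \code{species_a} and
#'   \code{species_b}, the per-site truth table \code{sites}
#'   (\code{transcript_id}, \code{pos} 1-based forward, \code{ref},
#'   \code{alt}, \code{type}, \code{fr_m}, \code{fr_r}, \code{D},
#'   \code{cds_class}), and the per-gene truth table \code{genes}
#'   (\code{transcript_id}, \code{omega_true}, planted counts,
#'   \code{dbar_true}, \code{all_fixed_true}).
#' @export
diverge_species <- function(ancestor, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  tr <- ancestor$transcripts
  orfs <- ancestor$orfs
  n <- nrow(tr)
  seqs_a <- character(n)
  site_rows <- vector("list", n)
  gene_rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- tr$id[i]
    chars <- strsplit(tr$sequence[i], "", fixed = TRUE)[[1]]
    L <- length(chars)
    orf <- orfs[orfs$transcript_id == id, ]
    omega <- config$omega_default
    if (!is.null(config$omega_per_gene) && id %in% names(config$omega_per_gene)) {
      omega <- unname(config$omega_per_gene[[id]])
    }
    p_n <- if (omega <= 1) omega else 1
    p_s <- if (omega <= 1) 1 else 1 / omega
    used <- logical(L)
    rows <- list()
    n_fixed <- stats::rbinom(1, L, config$fixed_diff_rate)
    n_syn <- 0L; n_nonsyn <- 0L
    placed <- 0L
    tries <- 0L
    while (placed < n_fixed && tries < 10000L) {
      tries <- tries + 1L
      pos <- sample.int(L, 1)
      if (used[pos]) next
      new_base <- sample(setdiff(.NT, chars[pos]), 1)
      cls <- .change_class(chars, L, orf, pos, new_base)
      if (cls == "blocked") next
      if (cls == "syn" && stats::runif(1) > p_s) next
      if (cls == "nonsyn" && stats::runif(1) > p_n) next
      ref <- chars[pos]
      chars[pos] <- new_base
      used[pos] <- TRUE
      placed <- placed + 1L
      if (cls == "syn") n_syn <- n_syn + 1L
      if (cls == "nonsyn") n_nonsyn <- n_nonsyn + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, pos = pos, ref = ref, alt = new_base,
        type = "fixed", fr_m = 1, fr_r = 0,
        cds_class = if (cls == "noncoding") NA_character_ else cls,
        stringsAsFactors = FALSE)
    }
    poly_one <- function(type, fr_fun) {
      rate <- if (type == "shared") config$shared_poly_rate else
        config$private_poly_rate
      k <- stats::rbinom(1, L, rate)
      out <- list()
      while (k > 0L) {
        free <- which(!used)
        if (length(free) == 0L) break
        take <- free[sample.int(length(free), min(k, length(free)))]
        used[take] <<- TRUE
        f <- stats::runif(length(take), config$minor_allele_freq_range[1],
                          config$minor_allele_freq_range[2])
        fr <- fr_fun(f)
        alt <- vapply(take, function(p0) sample(setdiff(.NT, chars[p0]), 1),
                      character(1))
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = id, pos = take, ref = chars[take], alt = alt,
          type = type, fr_m = fr$m, fr_r = fr$r,
          cds_class = NA_character_, stringsAsFactors = FALSE)
        k <- k - length(take)
        break
      }
      out
    }
    rows <- c(rows,
              poly_one("shared", function(f) list(m = f, r = f)),
              poly_one("private_a", function(f) list(m = f, r = 0 * f)),
              poly_one("private_b", function(f) list(m = 0 * f, r = f)))
    sites <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
    n_poly <- if (is.null(sites)) 0L else sum(sites$type != "fixed")
    dbar <- if (is.null(sites)) NA_real_ else
      mean(abs(sites$fr_m - sites$fr_r))
    gene_rows[[i]] <- data.frame(
      transcript_id = id, omega_true = omega,
      n_fixed_planted = placed, n_fixed_syn = n_syn,
      n_fixed_nonsyn = n_nonsyn, n_poly_planted = n_poly,
      dbar_true = dbar,
      all_fixed_true = placed > 0L && n_poly == 0L,
      stringsAsFactors = FALSE)
    site_rows[[i]] <- sites
    seqs_a[i] <- paste(chars, collapse = "")
  }
  sites <- do.call(rbind, site_rows[!vapply(site_rows, is.null, logical(1))])
  if (is.null(sites)) {
    sites <- data.frame(transcript_id = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        type = character(0), fr_m = numeric(0),
                        fr_r = numeric(0), cds_class = character(0),
                        stringsAsFactors = FALSE)
  }
  sites$D <- abs(sites$fr_m - sites$fr_r)
  sites <- sites[order(sites$transcript_id, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  list(species_a = data.frame(id = tr$id, species = "A", sequence = seqs_a,
                              stringsAsFactors = FALSE),
       species_b = data.frame(id = tr$id, species = "B",
                              sequence = tr$sequence,
                              stringsAsFactors = FALSE),
       sites = sites,
       genes = do.call(rbind, gene_rows))
}

# Vectorized split of `err` miscalls into the three non-source bases.
.split_errors <- function(err) {
  e1 <- stats::rbinom(length(err), err, 1 / 3)
  e2 <- stats::rbinom(length(err), err - e1, 1 / 2)
  list(e1 = e1, e2 = e2, e3 = err - e1 - e2)
}

#' Simulate a text pileup for one species against the reference
#'
#' Per reference site: depth Poisson(\code{depth_mean}) truncated at 1,
#' thinned by \code{low_mapq_fraction}; base calls drawn binomially from
#' the species' true allele frequency with miscalls at
#' \code{base_error_rate} (uniform over the other three bases); base
#' qualities two-level (Phred 40, or Phred 20 for a
#' \code{bad_quality_fraction} of calls); a \code{read_marker_rate}
#' fraction of lines carries \verb{^]} / \code{$} read markers.  Emits a
#' valid 6-column samtools text pileup over every position.
#'
#' The returned \code{realized} table records, for each truth site, the
#' retained (Phred >= 30) read counts per base that a correct caller
#' should recover; these counts are the generator's ground truth for
#' exact-recovery checks.
#'
#' @param reference transcript data frame of the reference assembly
#'   (species B).
#' @param truth_sites truth site table from [diverge_species()].
#' @param config a [sim_config()].
#' @param species \code{"a"} or \code{"b"}: whose reads to simulate.
#' @return list with \code{lines} (pileup text) and \code{realized}
#'   (data frame \code{transcript_id}, \code{pos}, \code{ref}, \code{A},
#'   \code{C}, \code{G}, \code{T} of retained counts at truth sites).
#' @export
simulate_pileups <- function(reference, truth_sites, config,
                             species = c("a", "b")) {
  stopifnot(inherits(config, "sim_config"))
  species <- match.arg(species)
  set.seed(config$seed + if (species == "a") 2L else 3L)
  missing_tr <- setdiff(truth_sites$transcript_id, reference$id)
  if (length(missing_tr) > 0L) {
    stop(sprintf("truth table references transcripts absent from reference: %s",
                 paste(utils::head(missing_tr, 3), collapse = ", ")),
         call. = FALSE)
  }
  tid_all <- character(0); pos_all <- integer(0); ref_all <- character(0)
  freq_all <- numeric(0); alt_all <- character(0)
  for (i in seq_len(nrow(reference))) {
    ch <- strsplit(reference$sequence[i], "", fixed = TRUE)[[1]]
    L <- length(ch)
    tid_all <- c(tid_all, rep.int(reference$id[i], L))
    pos_all <- c(pos_all, seq_len(L))
    ref_all <- c(ref_all, ch)
    fq <- numeric(L); al <- rep(NA_character_, L)
    ts <- truth_sites[truth_sites$transcript_id == reference$id[i], ]
    if (nrow(ts) > 0L) {
      fq[ts$pos] <- if (species == "a") ts$fr_m else ts$fr_r
      al[ts$pos] <- ts$alt
    }
    freq_all <- c(freq_all, fq)
    alt_all <- c(alt_all, al)
  }
  M <- length(pos_all)
  # canonical ordering of the three non-reference bases; the first slot is
  # the planted alternate where one exists
  others_by_ref <- t(vapply(.NT, function(r) setdiff(.NT, r), character(3)))
  others <- others_by_ref[match(ref_all, .NT), , drop = FALSE]
  dimnames(others) <- NULL
  has_alt <- !is.na(alt_all)
  o1 <- others[, 1]; o2 <- others[, 2]; o3 <- others[, 3]
  alt <- ifelse(has_alt, alt_all, o1)
  swap <- has_alt & o1 != alt
  # keep {alt, two remaining} disjoint when alt is o2 or o3
  tmp2 <- ifelse(swap & o2 == alt, o1, o2)
  tmp3 <- ifelse(swap & o3 == alt, o1, o3)
  o2 <- tmp2; o3 <- tmp3
  d <- stats::rpois(M, config$depth_mean)
  while (any(d == 0L)) d[d == 0L] <- stats::rpois(sum(d == 0L),
                                                  config$depth_mean)
  if (config$low_mapq_fraction > 0) {
    d <- d - stats::rbinom(M, d, config$low_mapq_fraction)
    d <- pmax(d, 1L)
  }
  n_alt <- stats::rbinom(M, d, freq_all)
  n_ref <- d - n_alt
  e <- config$base_error_rate
  err_ref <- stats::rbinom(M, n_ref, e)
  er <- .split_errors(err_ref)          # ref miscalls -> alt, o2, o3
  err_alt <- stats::rbinom(M, n_alt, e)
  ea <- .split_errors(err_alt)          # alt miscalls -> ref, o2, o3
  cnt_ref <- n_ref - err_ref + ea$e1
  cnt_alt <- n_alt - err_alt + er$e1
  cnt_o2 <- er$e2 + ea$e2
  cnt_o3 <- er$e3 + ea$e3
  bad <- config$bad_quality_fraction
  good_ref <- stats::rbinom(M, cnt_ref, 1 - bad)
  good_alt <- stats::rbinom(M, cnt_alt, 1 - bad)
  good_o2 <- stats::rbinom(M, cnt_o2, 1 - bad)
  good_o3 <- stats::rbinom(M, cnt_o3, 1 - bad)
  # base string: forward/reverse split of reference calls is cosmetic
  ref_fwd <- good_ref - good_ref %/% 2L
  bases <- paste0(strrep(".", ref_fwd), strrep(",", good_ref - ref_fwd),
                  strrep(".", cnt_ref - good_ref),
                  strrep(alt, good_alt),
                  strrep(tolower(alt), cnt_alt - good_alt),
                  strrep(o2, good_o2), strrep(tolower(o2), cnt_o2 - good_o2),
                  strrep(o3, good_o3), strrep(tolower(o3), cnt_o3 - good_o3))
  quals <- paste0(strrep("I", good_ref), strrep("5", cnt_ref - good_ref),
                  strrep("I", good_alt), strrep("5", cnt_alt - good_alt),
                  strrep("I", good_o2), strrep("5", cnt_o2 - good_o2),
                  strrep("I", good_o3), strrep("5", cnt_o3 - good_o3))
  marked <- stats::runif(M) < config$read_marker_rate
  bases[marked] <- paste0("^]", bases[marked], "$")
  depth_emitted <- cnt_ref + cnt_alt + cnt_o2 + cnt_o3
  lines <- paste(tid_all, pos_all, ref_all, depth_emitted, bases, quals,
                 sep = "\t")
  # retained (Phred >= 30) counts at truth sites, as a caller should see
  key <- paste(tid_all, pos_all)
  tkey <- paste(truth_sites$transcript_id, truth_sites$pos)
  ti <- match(tkey, key)
  nts <- nrow(truth_sites)
  realized <- data.frame(transcript_id = truth_sites$transcript_id,
                         pos = truth_sites$pos,
                         ref = if (nts) ref_all[ti] else character(0),
                         A = integer(nts), C = integer(nts),
                         G = integer(nts), T = integer(nts),
                         stringsAsFactors = FALSE)
  add_counts <- function(realized, base_vec, count_vec) {
    for (b in .NT) {
      sel <- base_vec[ti] == b
      realized[[b]][sel] <- realized[[b]][sel] + count_vec[ti][sel]
    }
    realized
  }
  realized <- add_counts(realized, ref_all, good_ref)
  realized <- add_counts(realized, alt, good_alt)
  realized <- add_counts(realized, o2, good_o2)
  realized <- add_counts(realized, o3, good_o3)
  list(lines = lines, realized = realized)
}

#' Emit a transcript-to-GO annotation table with one planted enriched term
#'
#' Background terms are assigned uniformly at random at
#' \code{go_base_rate}; the configured enriched term is assigned to fully
#' fixed transcripts (per the truth table) at
#' \code{go_enrichment_factor} times that rate and at the background rate
#' elsewhere.
#'
#' @param gene_truth per-gene truth table from [diverge_species()] (or any
#'   data frame with \code{transcript_id} and \code{all_fixed_true}).
#' @param config a [sim_config()].
#' @return data frame \code{transcript_id}, \code{go_id},
#'   \code{namespace}.
#' @export
emit_go_annotations <- function(gene_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$enriched_go_term) || !nzchar(config$enriched_go_term)) {
    stop("enriched_go_term must be set", call. = FALSE)
  }
  set.seed(config$seed + 4L)
  ids <- gene_truth$transcript_id
  terms <- sprintf("GO:%07d", seq_len(config$go_n_terms))
  terms <- setdiff(terms, config$enriched_go_term)
  ns_of <- function(k) c("BP", "MF", "CC")[(k %% 3L) + 1L]
  rows <- list()
  for (k in seq_along(terms)) {
    hit <- stats::runif(length(ids)) < config$go_base_rate
    if (any(hit)) {
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = ids[hit], go_id = terms[k],
        namespace = ns_of(k), stringsAsFactors = FALSE)
    }
  }
  rate <- ifelse(gene_truth$all_fixed_true,
                 pmin(1, config$go_enrichment_factor * config$go_base_rate),
                 config$go_base_rate)
  hit <- stats::runif(length(ids)) < rate
  if (any(hit)) {
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = ids[hit], go_id = config$enriched_go_term,
      namespace = "CC", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a GO annotation table as three-column TSV
#'
#' @param annotations data frame \code{transcript_id}, \code{go_id},
#'   \code{namespace}.
#' @param path output path.
#' @export
write_go_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Run the whole generator under one configuration
#'
#' Convenience wrapper chaining [simulate_ancestral_transcriptome()],
#' [diverge_species()], [simulate_pileups()] (both species) and
#' [emit_go_annotations()].
#'
#' @param config a [sim_config()].
#' @return list with \code{config}, \code{ancestor}, \code{species_a},
#'   \code{species_b}, \code{orfs}, \code{sites}, \code{genes},
#'   \code{pileup_a}, \code{pileup_b} (each with \code{lines} and
#'   \code{realized}) and \code{annotations}.
#' @export
simulate_two_species <- function(config = sim_config()) {
  anc <- simulate_ancestral_transcriptome(config)
  div <- diverge_species(anc, config)
  pa <- simulate_pileups(div$species_b, div$sites, config, "a")
  pb <- simulate_pileups(div$species_b, div$sites, config, "b")
  ann <- emit_go_annotations(div$genes, config)
  list(config = config, ancestor = anc$transcripts, orfs = anc$orfs,
       species_a = div$species_a, species_b = div$species_b,
       sites = div$sites, genes = div$genes,
       pileup_a = pa, pileup_b = pb, annotations = ann)
}
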