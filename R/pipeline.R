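#' Pipeline run configuration
#'
#' Collects every input path and tuning parameter of the end-to-end
#' divergence scan.  Both species' pileups must be mapped against the same
#' reference assembly (the more complete of the two); \code{reference}
#' names which species that is.
#'
#' @param fasta_a,fasta_b per-species transcript FASTA paths.
#' @param pileup_a,pileup_b per-species samtools text pileup paths, both
#'   against the reference assembly.
#' @param annotations transcript-to-GO annotation TSV path.
#' @param outdir output directory (created if absent).
#' @param reference which species' assembly the pileups are mapped to
#'   (\code{"a"} or \code{"b"}; default \code{"b"}).
#' @param thresholds a [caller_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @param min_cds_aa minimum predicted CDS length in residues.
#' @param dbar_high strict lower bound of the highly differentiated
#'   D-bar class.
#' @param min_fixed_snps minimum SNPs for the supported all-fixed class.
#' @param alpha enrichment significance level on BH q.
#' @param min_term_size smallest tested GO term.
#' @param ks_max inclusive paralog cutoff on Ks.
#' @param seed integer seed (stages are deterministic given it).
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(fasta_a, fasta_b, pileup_a, pileup_b, annotations,
                       outdir, reference = "b",
                       thresholds = caller_thresholds(),
                       scheme = scoring_scheme(), min_cds_aa = 100L,
                       dbar_high = 0.9, min_fixed_snps = 3L, alpha = 0.05,
                       min_term_size = 3L, ks_max = 1, seed = 1L) {
  stopifnot(reference %in% c("a", "b"))
  structure(list(fasta_a = fasta_a, fasta_b = fasta_b,
                 pileup_a = pileup_a, pileup_b = pileup_b,
                 annotations = annotations, outdir = outdir,
                 reference = reference, thresholds = thresholds,
                 scheme = scheme, min_cds_aa = as.integer(min_cds_aa),
                 dbar_high = dbar_high,
                 min_fixed_snps = as.integer(min_fixed_snps),
                 alpha = alpha, min_term_size = as.integer(min_term_size),
                 ks_max = ks_max, seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration (lossless round trip)
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return \code{read_run_config} returns the configuration.
#' @export
write_run_config <- function(config, path) {
  dput(unclass(config), file = path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- dget(path)
  class(x$thresholds) <- "caller_thresholds"
  class(x$scheme) <- "scoring_scheme"
  structure(x, class = "run_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.check_inputs <- function(config) {
  paths <- c(config$fasta_a, config$fasta_b, config$pileup_a,
             config$pileup_b, config$annotations)
  ok <- file.exists(paths)
  if (!all(ok)) {
    stop(sprintf("missing input file: %s", paths[!ok][1]), call. = FALSE)
  }
  invisible(TRUE)
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  dput(unclass(config), file = f)
  unname(tools::md5sum(f))
}

#' Run the full divergence scan
#'
#' Stages, in dependency order: longest-isoform reduction, CDS prediction,
#' per-species pileup summarization and joint SNP calling, per-SNP D and
#' per-transcript D-bar with classification, reciprocal-best-hit ortholog
#' Ka/Ks with the paralog filter, candidate markers, and GO enrichment of
#' the fully differentiated transcripts.  Every stage's table is written
#' under \code{config$outdir} before the report is assembled, so any stage
#' can be re-consumed standalone.
#'
#' @param config a [run_config()].
#' @return a \code{diverscan_report} (invisible list of stage outputs,
#'   counts, runtimes and the configuration hash).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  .check_inputs(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  times <- c()
  tick <- function() Sys.time()
  stage <- function(name, t0) {
    times[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  t0 <- tick()
  tr_a <- select_longest_isoform(read_transcripts(config$fasta_a, "a"))
  tr_b <- select_longest_isoform(read_transcripts(config$fasta_b, "b"))
  stage("isoform_filter", t0)

  t0 <- tick()
  cds_a <- predict_cds(tr_a, config$min_cds_aa, longest_only = TRUE)
  cds_b <- predict_cds(tr_b, config$min_cds_aa, longest_only = TRUE)
  .write_tsv(cds_a, file.path(config$outdir, "cds_a.tsv"))
  .write_tsv(cds_b, file.path(config$outdir, "cds_b.tsv"))
  stage("cds", t0)

  t0 <- tick()
  counts_a <- pileup_site_counts(config$pileup_a, config$thresholds)
  counts_b <- pileup_site_counts(config$pileup_b, config$thresholds)
  joint <- joint_sites(counts_a, counts_b, config$thresholds)
  joint$D <- compute_D(joint$freq_a, joint$freq_b)
  .write_tsv(joint, file.path(config$outdir, "joint_sites.tsv"))
  stage("snp_calling", t0)

  t0 <- tick()
  diff <- transcript_Dbar(joint)
  classes <- classify_differentiation(diff, joint, high = config$dbar_high,
                                      min_fixed_snps = config$min_fixed_snps)
  hist <- histogram_D(joint$D)
  .write_tsv(diff, file.path(config$outdir, "transcript_dbar.tsv"))
  .write_tsv(hist, file.path(config$outdir, "histogram_D.tsv"))
  stage("differentiation", t0)

  t0 <- tick()
  seq_a <- stats::setNames(tr_a$sequence, tr_a$id)
  seq_b <- stats::setNames(tr_b$sequence, tr_b$id)
  nt_a <- stats::setNames(vapply(seq_len(nrow(cds_a)), function(i) {
    cds_sequence(seq_a[[cds_a$transcript_id[i]]], cds_a[i, ])
  }, character(1)), cds_a$transcript_id)
  nt_b <- stats::setNames(vapply(seq_len(nrow(cds_b)), function(i) {
    cds_sequence(seq_b[[cds_b$transcript_id[i]]], cds_b[i, ])
  }, character(1)), cds_b$transcript_id)
  prot_a <- vapply(nt_a, translate_cds, character(1))
  prot_b <- vapply(nt_b, translate_cds, character(1))
  rbh <- reciprocal_best_hits(prot_a, prot_b, config$scheme)
  pairs <- if (nrow(rbh) > 0L) {
    filter_and_flag(kaks_pairs(rbh, nt_a, nt_b, config$scheme),
                    config$ks_max)
  } else {
    cbind(rbh, data.frame(paralog_filtered = logical(0),
                          candidate = logical(0)))
  }
  if (nrow(pairs) > 0L) {
    pairs$transcript_id <- if (config$reference == "b") pairs$id_b else
      pairs$id_a
  } else {
    pairs$transcript_id <- character(0)
  }
  .write_tsv(pairs, file.path(config$outdir, "orthologs.tsv"))
  stage("kaks", t0)

  t0 <- tick()
  markers <- if (nrow(pairs) > 0L) candidate_markers(pairs, diff) else
    data.frame(transcript_id = character(0), n_snps = integer(0),
               dbar = numeric(0), ka = numeric(0), ks = numeric(0),
               ratio = numeric(0), capped = logical(0))
  .write_tsv(markers, file.path(config$outdir, "markers.tsv"))
  stage("markers", t0)

  t0 <- tick()
  ann <- read_go_annotations(config$annotations)
  background <- if (config$reference == "b") tr_b$id else tr_a$id
  study <- intersect(classes$at_fixed, background)
  enr <- run_enrichment(study, background, ann, config$alpha,
                        config$min_term_size)
  .write_tsv(enr, file.path(config$outdir, "enrichment.tsv"))
  stage("enrichment", t0)

  report <- structure(list(
    counts = list(
      transcripts_a = nrow(tr_a), transcripts_b = nrow(tr_b),
      cds_a = nrow(cds_a), cds_b = nrow(cds_b),
      cds_a_complete = sum(cds_a$completeness == "complete"),
      cds_b_complete = sum(cds_b$completeness == "complete"),
      joint_snps = nrow(joint),
      fixed_snps = classes$n_snps_fixed,
      transcripts_with_snps = classes$n_transcripts,
      dbar_above_high = classes$n_above_high,
      dbar_fixed = classes$n_at_fixed,
      dbar_fixed_supported = classes$n_fixed_supported,
      ortholog_pairs = nrow(pairs),
      ks_filtered_pairs = sum(pairs$paralog_filtered),
      ratio_gt1_pairs = sum(pairs$candidate),
      candidate_markers = nrow(markers),
      go_terms_tested = nrow(enr),
      go_terms_significant = sum(enr$significant)),
    runtimes = times,
    config_hash = .config_hash(config),
    outdir = config$outdir,
    joint = joint, diff = diff, classes = classes, pairs = pairs,
    markers = markers, enrichment = enr),
    class = "diverscan_report")
  .write_tsv(data.frame(key = names(unlist(report$counts)),
                        value = unlist(report$counts)),
             file.path(config$outdir, "report.tsv"))
  invisible(report)
}

#' @export
print.diverscan_report <- function(x, ...) {
  cat("Divergence scan report\n")
  for (k in names(x$counts)) cat(sprintf("  %-24s %s\n", k, x$counts[[k]]))
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}

#' Generate a self-contained fixture directory (and optionally verify it)
#'
#' Runs the synthetic generator and writes a complete pipeline input set
#' plus truth tables.  With \code{verify = TRUE} the pipeline is run over
#' the fixture and checked against the truth: joint SNP calls are compared
#' with the calls implied by the generator's realized retained read counts,
#' and recall/precision of the planted fixed differences is reported.
#'
#' @param config a [sim_config()].
#' @param dir fixture directory (created).
#' @param verify run the pipeline and score truth recovery.
#' @param thresholds caller thresholds used for verification.
#' @return invisible list with the fixture paths, a ready-made
#'   [run_config()], and (if requested) the \code{verify} scores.
#' @export
make_fixture <- function(config = sim_config(), dir = tempfile("fixture"),
                         verify = FALSE,
                         thresholds = caller_thresholds()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_two_species(config)
  paths <- list(
    fasta_a = file.path(dir, "species_a.fasta"),
    fasta_b = file.path(dir, "species_b.fasta"),
    pileup_a = file.path(dir, "species_a.pileup"),
    pileup_b = file.path(dir, "species_b.pileup"),
    annotations = file.path(dir, "go_annotations.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_genes = file.path(dir, "truth_genes.tsv"),
    truth_orfs = file.path(dir, "truth_orfs.tsv"),
    realized_a = file.path(dir, "realized_counts_a.tsv"),
    realized_b = file.path(dir, "realized_counts_b.tsv"))
  write_transcripts(sim$species_a, paths$fasta_a)
  write_transcripts(sim$species_b, paths$fasta_b)
  writeLines(sim$pileup_a$lines, paths$pileup_a)
  writeLines(sim$pileup_b$lines, paths$pileup_b)
  write_go_annotations(sim$annotations, paths$annotations)
  .write_tsv(sim$sites, paths$truth_sites)
  .write_tsv(sim$genes, paths$truth_genes)
  .write_tsv(sim$orfs, paths$truth_orfs)
  .write_tsv(sim$pileup_a$realized, paths$realized_a)
  .write_tsv(sim$pileup_b$realized, paths$realized_b)
  rc <- run_config(fasta_a = paths$fasta_a, fasta_b = paths$fasta_b,
                   pileup_a = paths$pileup_a, pileup_b = paths$pileup_b,
                   annotations = paths$annotations,
                   outdir = file.path(dir, "out"),
                   thresholds = thresholds, seed = config$seed)
  write_run_config(rc, file.path(dir, "run_config.R"))
  out <- list(dir = dir, paths = paths, run_config = rc, sim = sim)
  if (verify) out$verify <- verify_fixture(sim, thresholds)
  invisible(out)
}

#' Score truth recovery of the SNP stage on a simulated data set
#'
#' The expected call set is obtained by running the joint caller on the
#' generator's realized retained read counts (its ground truth of what a
#' correct parser and filter chain should see); the observed set comes
#' from parsing the emitted pileup text.  Returns exact set-comparison
#' counts plus recall and precision of the planted fixed differences.
#'
#' @param sim result of [simulate_two_species()].
#' @param thresholds a [caller_thresholds()].
#' @return list of verification scores.
#' @export
verify_fixture <- function(sim, thresholds = caller_thresholds()) {
  counts_a <- pileup_site_counts(parse_pileup(text = sim$pileup_a$lines),
                                 thresholds)
  counts_b <- pileup_site_counts(parse_pileup(text = sim$pileup_b$lines),
                                 thresholds)
  called <- joint_sites(counts_a, counts_b, thresholds)
  called$D <- compute_D(called$freq_a, called$freq_b)
  expected <- joint_sites(sim$pileup_a$realized, sim$pileup_b$realized,
                          thresholds)
  key <- function(df) paste(df$transcript_id, df$pos)
  called_k <- key(called); expected_k <- key(expected)
  truth_fixed <- sim$sites[sim$sites$type == "fixed", ]
  fixed_k <- paste(truth_fixed$transcript_id, truth_fixed$pos)
  planted_k <- paste(sim$sites$transcript_id, sim$sites$pos)
  list(
    n_called = nrow(called),
    n_expected = nrow(expected),
    set_equal = setequal(called_k, expected_k),
    d_match = {
      common <- intersect(called_k, expected_k)
      all(called$D[match(common, called_k)] ==
            compute_D(expected$freq_a, expected$freq_b)[match(common,
                                                              expected_k)])
    },
    snp_recall = if (length(planted_k)) {
      length(intersect(called_k, planted_k)) / length(planted_k)
    } else NA_real_,
    snp_precision = if (nrow(called)) {
      length(intersect(called_k, planted_k)) / nrow(called)
    } else NA_real_,
    fixed_recall = if (length(fixed_k)) {
      length(intersect(called_k, fixed_k)) / length(fixed_k)
    } else NA_real_,
    fixed_precision = {
      # of calls that look fixed (D = 1), how many are planted fixed sites
      look_fixed <- called_k[called$D == 1]
      if (length(look_fixed)) {
        length(intersect(look_fixed, fixed_k)) / length(look_fixed)
      } else NA_real_
    })
}
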