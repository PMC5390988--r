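#' Interspecific differentiation index D
#'
#' The differentiation index of one SNP is the absolute difference between
#' the frequencies of the shared alternate allele in the two species,
#' \eqn{D = |FR_m - FR_r|}.  \eqn{D = 1} means the species are fixed for
#' different nucleotides at the site.
#'
#' @param fr_m,fr_r alternate-allele frequencies in the two species, both in
#'   \code{[0, 1]}; vectorized.
#' @return numeric vector of D values in \code{[0, 1]}.
#' @export
compute_D <- function(fr_m, fr_r) {
  if (any(fr_m < 0 | fr_m > 1 | fr_r < 0 | fr_r > 1, na.rm = TRUE)) {
    stop("allele frequencies must lie in [0, 1]", call. = FALSE)
  }
  abs(fr_m - fr_r)
}

#' Per-transcript mean differentiation (D-bar)
#'
#' Averages D over all SNPs of each transcript (unweighted arithmetic mean)
#' and counts fixed differences (D = 1, decided on exact count ratios).
#' Transcripts without SNPs do not appear.
#'
#' @param sites a [joint_sites()] data frame; D is computed from
#'   \code{freq_a}/\code{freq_b} if not already present.
#' @return data frame with columns \code{transcript_id}, \code{n_snps},
#'   \code{dbar}, \code{n_fixed}, \code{all_fixed}.
#' @export
transcript_Dbar <- function(sites) {
  if (is.null(sites$D)) sites$D <- compute_D(sites$freq_a, sites$freq_b)
  if (nrow(sites) == 0L) {
    return(data.frame(transcript_id = character(0), n_snps = integer(0),
                      dbar = numeric(0), n_fixed = integer(0),
                      all_fixed = logical(0), stringsAsFactors = FALSE))
  }
  # D = 1 exactly: one species all-alternate, the other all-reference.
  # freq values are ratios n/n = 1 and 0/n = 0, exact in floating point.
  fixed <- (sites$freq_a == 1 & sites$freq_b == 0) |
    (sites$freq_a == 0 & sites$freq_b == 1)
  tid <- factor(sites$transcript_id, levels = unique(sites$transcript_id))
  n_snps <- as.integer(tapply(sites$D, tid, length))
  dbar <- as.numeric(tapply(sites$D, tid, mean))
  n_fixed <- as.integer(tapply(fixed, tid, sum))
  data.frame(transcript_id = levels(tid), n_snps = n_snps, dbar = dbar,
             n_fixed = n_fixed, all_fixed = n_fixed == n_snps,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify SNPs and transcripts by differentiation
#'
#' Produces the summary counts behind a divergence scan: total SNPs, fixed
#' SNPs (D = 1), transcripts with mean differentiation strictly above
#' \code{high}, transcripts at exactly \code{fixed}, and all-fixed
#' transcripts carrying at least \code{min_fixed_snps} SNPs.
#'
#' @param diff a [transcript_Dbar()] data frame.
#' @param sites the per-SNP [joint_sites()] data frame used to build it.
#' @param fixed D-bar value defining the fully fixed class (default 1.0).
#' @param high strict lower bound of the highly differentiated class
#'   (default 0.9, i.e. "above 90\%").
#' @param min_fixed_snps minimum SNP count for the supported all-fixed class
#'   (default 3).
#' @return a list of class \code{diverscan_classification} with counts and
#'   per-class transcript id vectors.
#' @export
classify_differentiation <- function(diff, sites, fixed = 1.0, high = 0.9,
                                     min_fixed_snps = 3L) {
  if (is.null(sites$D)) sites$D <- compute_D(sites$freq_a, sites$freq_b)
  snp_fixed <- (sites$freq_a == 1 & sites$freq_b == 0) |
    (sites$freq_a == 0 & sites$freq_b == 1)
  above_high <- diff$transcript_id[diff$dbar > high]
  at_fixed <- diff$transcript_id[diff$all_fixed & diff$dbar == fixed]
  supported <- diff$transcript_id[diff$all_fixed & diff$dbar == fixed &
                                    diff$n_snps >= min_fixed_snps]
  structure(list(
    n_snps = nrow(sites),
    n_snps_fixed = sum(snp_fixed),
    n_transcripts = nrow(diff),
    n_above_high = length(above_high),
    n_at_fixed = length(at_fixed),
    n_fixed_supported = length(supported),
    thresholds = list(fixed = fixed, high = high,
                      min_fixed_snps = as.integer(min_fixed_snps)),
    above_high = above_high,
    at_fixed = at_fixed,
    fixed_supported = supported),
    class = "diverscan_classification")
}

#' @export
print.diverscan_classification <- function(x, ...) {
  cat("Differentiation classification\n")
  cat(sprintf("  SNPs: %d (fixed D=1: %d)\n", x$n_snps, x$n_snps_fixed))
  cat(sprintf("  transcripts with SNPs: %d\n", x$n_transcripts))
  cat(sprintf("  D-bar > %.2f: %d\n", x$thresholds$high, x$n_above_high))
  cat(sprintf("  D-bar = %.2f: %d\n", x$thresholds$fixed, x$n_at_fixed))
  cat(sprintf("  D-bar = %.2f with >= %d SNPs: %d\n", x$thresholds$fixed,
              x$thresholds$min_fixed_snps, x$n_fixed_supported))
  invisible(x)
}

#' Histogram of D values
#'
#' Bins are left-closed right-open except the last, which is closed at 1, so
#' the fully fixed class D = 1 falls in the top bin.
#'
#' @param D numeric vector of D values in \code{[0, 1]}.
#' @param n_bins number of equal-width bins over \code{[0, 1]}.
#' @return data frame with columns \code{lower}, \code{upper}, \code{count}.
#' @export
histogram_D <- function(D, n_bins = 10L) {
  stopifnot(n_bins >= 1L)
  if (any(D < 0 | D > 1)) stop("D values must lie in [0, 1]", call. = FALSE)
  idx <- pmin(floor(D * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(lower = (seq_len(n_bins) - 1L) / n_bins,
             upper = seq_len(n_bins) / n_bins,
             count = counts)
}
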