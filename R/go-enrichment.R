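#' Read a transcript-to-GO annotation table
#'
#' @param path three-column TSV \code{transcript_id}, \code{go_id},
#'   \code{namespace} (no header required; a header line is detected and
#'   skipped).
#' @return data frame with those three columns.
#' @export
read_go_annotations <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("transcript_id", "go_id",
                                        "namespace"))
  if (nrow(df) > 0 && df$transcript_id[1] == "transcript_id") {
    df <- df[-1, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Hypergeometric over-representation p-value from counts
#'
#' One-sided upper tail \eqn{P(X \ge x)} for drawing \code{study_size}
#' transcripts from a background of \code{pop_size} of which
#' \code{pop_annotated} carry the term.  Exact (no normal approximation).
#'
#' @param study_annotated annotated transcripts in the study set.
#' @param study_size study set size.
#' @param pop_annotated annotated transcripts in the background.
#' @param pop_size background size.
#' @return p-value.
#' @export
hyper_test_counts <- function(study_annotated, study_size, pop_annotated,
                              pop_size) {
  stopifnot(study_annotated <= study_size, study_annotated <= pop_annotated,
            study_size <= pop_size, pop_annotated <= pop_size)
  stats::phyper(study_annotated - 1, pop_annotated,
                pop_size - pop_annotated, study_size, lower.tail = FALSE)
}

#' Over-representation test of one GO term
#'
#' @param study character vector of study transcript ids (a subset of the
#'   background).
#' @param background character vector of background transcript ids.
#' @param annotations annotation data frame (\code{transcript_id},
#'   \code{go_id}, \code{namespace}).
#' @param go_id the term to test.
#' @return the raw one-sided p-value.
#' @export
fisher_term_test <- function(study, background, annotations, go_id) {
  study <- unique(study); background <- unique(background)
  missing <- setdiff(study, background)
  if (length(missing) > 0L) {
    stop(sprintf("study ids absent from background: %s",
                 paste(utils::head(missing, 3), collapse = ", ")),
         call. = FALSE)
  }
  with_term <- unique(annotations$transcript_id[annotations$go_id == go_id])
  with_term <- intersect(with_term, background)
  hyper_test_counts(length(intersect(study, with_term)), length(study),
                    length(with_term), length(background))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \code{[0, 1]}.
#' @return q-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' GO term enrichment of a study set with BH-FDR control
#'
#' Tests every term annotated to at least \code{min_term_size} background
#' transcripts with the one-sided hypergeometric test and adjusts across
#' all tested terms jointly (all namespaces together) by
#' Benjamini-Hochberg.
#'
#' @param study study transcript ids (e.g. the fully differentiated set).
#' @param background background transcript ids.
#' @param annotations annotation data frame (\code{transcript_id},
#'   \code{go_id}, \code{namespace}).
#' @param alpha significance level on the adjusted q (default 0.05).
#' @param min_term_size smallest background annotation count tested
#'   (default 3, suppressing singleton-term noise).
#' @return data frame sorted by q then p: \code{go_id}, \code{namespace},
#'   \code{study_annotated}, \code{study_size}, \code{pop_annotated},
#'   \code{pop_size}, \code{p_raw}, \code{q_bh}, \code{significant}.
#' @export
run_enrichment <- function(study, background, annotations, alpha = 0.05,
                           min_term_size = 3L) {
  if (is.null(annotations) || nrow(annotations) == 0L) {
    stop("empty annotation table", call. = FALSE)
  }
  study <- unique(study); background <- unique(background)
  missing <- setdiff(study, background)
  if (length(missing) > 0L) {
    stop(sprintf("study ids absent from background: %s",
                 paste(utils::head(missing, 3), collapse = ", ")),
         call. = FALSE)
  }
  ann <- annotations[annotations$transcript_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("transcript_id", "go_id", "namespace")])
  pop_counts <- table(ann$go_id)
  terms <- names(pop_counts)[pop_counts >= min_term_size]
  if (length(terms) == 0L) {
    return(data.frame(go_id = character(0), namespace = character(0),
                      study_annotated = integer(0), study_size = integer(0),
                      pop_annotated = integer(0), pop_size = integer(0),
                      p_raw = numeric(0), q_bh = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  in_study <- ann$transcript_id %in% study
  study_counts <- table(factor(ann$go_id[in_study], levels = terms))
  ns <- ann$namespace[match(terms, ann$go_id)]
  study_annotated <- as.integer(study_counts[terms])
  pop_annotated <- as.integer(pop_counts[terms])
  p <- vapply(seq_along(terms), function(i) {
    hyper_test_counts(study_annotated[i], length(study), pop_annotated[i],
                      length(background))
  }, numeric(1))
  q <- bh_adjust(p)
  out <- data.frame(go_id = terms, namespace = ns,
                    study_annotated = study_annotated,
                    study_size = length(study),
                    pop_annotated = pop_annotated,
                    pop_size = length(background),
                    p_raw = p, q_bh = q, significant = q <= alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$q_bh, out$p_raw, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
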