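#' Published Rhodnius ortholog Ka/Ks estimates bundled with the package
#'
#' A small worked-example table of reported Ka, Ks and Ka/Ks values for
#' ortholog CDS pairs between \emph{R. montenegrensis} and
#' \emph{R. robustus}: a screen of rapidly evolving salivary/sensory
#' proteins (\code{table == "selection_screen"}) and the highly
#' differentiated fixed candidate markers (\code{table == "fixed_markers"},
#' which also carry SNP counts and per-transcript mean differentiation).
#'
#' @return data frame with columns \code{table}, \code{label},
#'   \code{n_snps}, \code{dbar}, \code{ka}, \code{ks}, \code{ratio}.
#' @export
reported_kaks <- function() {
  path <- system.file("extdata", "rhodnius_reported_kaks.tsv",
                      package = "diverscan", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Ratio consistency of reported Ka/Ks rows
#'
#' Recomputes each row's Ka/Ks as the quotient of its reported Ka and Ks
#' and, for rows reported at the cap of 50, checks the capping convention
#' \code{Ks = Ka / 50} that the estimator applies when no synonymous
#' difference is observed.  \code{rel_err} is the relative disagreement
#' between the reported value and the recomputation (quotient vs ratio for
#' uncapped rows; reported Ks vs Ka/50 for capped rows); \code{consistent}
#' flags rows whose disagreement is within printed rounding (\code{tol},
#' default 5\%: the half-unit-in-last-place bound for values printed to
#' two significant figures).
#'
#' @param reported a [reported_kaks()]-shaped data frame.
#' @param cap the ratio cap (default 50).
#' @param tol relative tolerance for printed rounding.
#' @return the input with \code{recomputed_ratio}, \code{capped},
#'   \code{rel_err} and \code{consistent} columns added.
#' @export
kaks_ratio_consistency <- function(reported = reported_kaks(), cap = 50,
                                   tol = 0.05) {
  out <- reported
  out$recomputed_ratio <- out$ka / out$ks
  out$capped <- out$ratio == cap
  out$rel_err <- ifelse(out$capped,
                        abs(out$ks - out$ka / cap) / (out$ka / cap),
                        abs(out$recomputed_ratio - out$ratio) / out$ratio)
  out$consistent <- out$rel_err <= tol
  out
}
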