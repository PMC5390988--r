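# Independent oracles used to cross-check the package's computations.
# They deliberately share no code with the implementation: enumeration and
# textbook formulas only (the genetic code table itself is taken from
# Biostrings, which is not under test).

GC_TABLE <- Biostrings::GENETIC_CODE
NT4 <- c("A", "C", "G", "T")

oracle_translate <- function(nt) {
  n <- nchar(nt)
  cods <- substring(nt, seq(1, n, 3), seq(3, n, 3))
  paste(unname(GC_TABLE[cods]), collapse = "")
}

# NG86 site counts by direct enumeration of the nine single-base mutants.
oracle_ng86_sites <- function(codon) {
  ch <- strsplit(codon, "", fixed = TRUE)[[1]]
  aa0 <- GC_TABLE[[codon]]
  syn <- 0
  for (p in 1:3) {
    aas <- vapply(setdiff(NT4, ch[p]), function(b) {
      x <- ch; x[p] <- b; GC_TABLE[[paste(x, collapse = "")]]
    }, character(1))
    valid <- aas != "*"
    if (any(valid)) syn <- syn + sum(aas[valid] == aa0) / sum(valid)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# All permutations of 1..k (k <= 3), written out recursively.
oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    for (tail in oracle_perms(k - 1)) {
      out[[length(out) + 1L]] <- c(first, rest[tail])
    }
  }
  out
}

# Pathway-enumeration oracle for the (synonymous, nonsynonymous) difference
# counts between two sense codons: walk every ordering of the differing
# positions, drop orderings whose intermediates are stops (fall back to all
# orderings when none survives), average the per-step classifications.
oracle_pair_diff <- function(c1, c2) {
  a <- strsplit(c1, "", fixed = TRUE)[[1]]
  b <- strsplit(c2, "", fixed = TRUE)[[1]]
  dpos <- which(a != b)
  k <- length(dpos)
  if (k == 0) return(c(sd = 0, nd = 0))
  paths <- oracle_perms(k)
  res <- list()
  for (ord in paths) {
    cur <- a; syn <- 0; blocked <- FALSE
    for (step in ord) {
      nxt <- cur; nxt[dpos[step]] <- b[dpos[step]]
      aa1 <- GC_TABLE[[paste(cur, collapse = "")]]
      aa2 <- GC_TABLE[[paste(nxt, collapse = "")]]
      if (aa2 == "*") blocked <- TRUE
      if (aa1 == aa2) syn <- syn + 1
      cur <- nxt
    }
    res[[length(res) + 1L]] <- c(syn = syn, blocked = blocked)
  }
  m <- do.call(rbind, res)
  use <- if (any(m[, "blocked"] == 0)) m[, "blocked"] == 0 else
    rep(TRUE, nrow(m))
  sd <- mean(m[use, "syn"])
  c(sd = sd, nd = k - sd)
}

# Whole-alignment NG86 counting oracle (site sums + pathway differences).
oracle_ng86_alignment <- function(cod1, cod2) {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  ok <- cod1 %in% sense & cod2 %in% sense
  c1 <- cod1[ok]; c2 <- cod2[ok]
  site <- function(cods) sum(vapply(cods, function(x)
    oracle_ng86_sites(x)[["syn"]], numeric(1)))
  S <- (site(c1) + site(c2)) / 2
  N <- 3 * length(c1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(c1)) {
    d <- oracle_pair_diff(c1[i], c2[i])
    sd <- sd + d[["sd"]]; nd <- nd + d[["nd"]]
  }
  c(S = S, N = N, Sd = sd, Nd = nd)
}

# Gotoh affine-gap global alignment score; a gap of length L costs
# open + L * extend, matching the pairwiseAlignment convention.
oracle_global_score <- function(p1, p2, mat, open, extend) {
  a <- strsplit(p1, "", fixed = TRUE)[[1]]
  b <- strsplit(p2, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in p2 (consume a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in p1 (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Textbook hypergeometric upper tail by log-space summation of binomial
# coefficients.
oracle_hyper_tail <- function(x, K, N, n) {
  hi <- min(K, n)
  if (x > hi) return(0)
  i <- x:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Textbook Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, cummin((m / (m:1)) * p[o][m:1])[m:1])
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# A random sense codon, optionally mutated at up to k positions without
# creating a stop codon.
random_sense_codon <- function() {
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  sample(sense, 1)
}

mutate_codon <- function(codon, k) {
  repeat {
    ch <- strsplit(codon, "", fixed = TRUE)[[1]]
    pos <- sample(1:3, k)
    for (p in pos) ch[p] <- sample(setdiff(NT4, ch[p]), 1)
    out <- paste(ch, collapse = "")
    if (GC_TABLE[[out]] != "*") return(out)
  }
}
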