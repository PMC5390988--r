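test_that("reciprocal best hits pair identical and planted orthologs", {
  p <- paste(vapply(1:200, function(i) random_sense_codon(), character(1)),
             collapse = "")
  set.seed(19)
  prot <- oracle_translate(p)
  rbh <- reciprocal_best_hits(c(A1 = prot), c(B1 = prot))
  expect_equal(nrow(rbh), 1)
  expect_equal(rbh$id_a, "A1")
  expect_lt(rbh$evalue, 1e-12)
  # an exact score tie (two identical subjects) eliminates the query
  rbh <- reciprocal_best_hits(c(A1 = prot), c(B1 = prot, B2 = prot))
  expect_equal(nrow(rbh), 0)
  expect_error(reciprocal_best_hits(character(0), c(B1 = prot)),
               "empty proteome")
})

test_that("RBH recovers all planted ortholog pairs on synthetic species", {
  sim <- small_sim()
  cds_of <- function(tr) {
    cds <- predict_cds(tr, 100, longest_only = TRUE)
    setNames(vapply(seq_len(nrow(cds)), function(i)
      cds_sequence(tr$sequence[tr$id == cds$transcript_id[i]], cds[i, ]),
      character(1)), cds$transcript_id)
  }
  nta <- cds_of(sim$species_a)
  ntb <- cds_of(sim$species_b)
  pa <- vapply(nta, translate_cds, character(1))
  pb <- vapply(ntb, translate_cds, character(1))
  rbh <- reciprocal_best_hits(pa, pb)
  expect_equal(sort(rbh$id_a), sort(names(pa)))
  expect_true(all(rbh$id_a == rbh$id_b))
})

test_that("global protein alignment matches an affine-gap DP oracle", {
  aln <- align_protein_pair("MKV", "MV")
  expect_equal(nchar(aln$a1), nchar(aln$a2))
  expect_equal(gsub("-", "", aln$a1), "MKV")
  expect_equal(gsub("-", "", aln$a2), "MV")
  expect_equal(lengths(regmatches(aln$a2, gregexpr("-", aln$a2))), 1)
  ident <- align_protein_pair("MKVLL", "MKVLL")
  expect_false(grepl("-", paste(ident$a1, ident$a2)))
  expect_error(align_protein_pair("MK-", "MK"), "ungapped")
  expect_error(align_protein_pair("MK1", "MK"), "non-amino-acid")
  data(BLOSUM62, package = "Biostrings", envir = environment())
  scheme <- scoring_scheme()
  set.seed(23)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")
  for (rep in 1:50) {
    p1 <- paste(sample(aas, sample(5:30, 1), replace = TRUE), collapse = "")
    p2 <- paste(sample(aas, sample(5:30, 1), replace = TRUE), collapse = "")
    got <- align_protein_pair(p1, p2, scheme)$score
    want <- oracle_global_score(p1, p2, BLOSUM62, scheme$gap_open,
                                scheme$gap_extend)
    expect_equal(got, want)
  }
})

test_that("back-translation threads codons and round-trips", {
  aln <- list(a1 = "MK", a2 = "MK")
  cod <- backtranslate_alignment(aln, "ATGAAA", "ATGAAG")
  expect_equal(cod$codons_1, c("ATG", "AAA"))
  expect_equal(cod$codons_2, c("ATG", "AAG"))
  aln <- list(a1 = "M-K", a2 = "MVK")
  cod <- backtranslate_alignment(aln, "ATGAAA", "ATGGTTAAG")
  expect_equal(cod$codons_1, c("ATG", "---", "AAA"))
  expect_equal(cod$codons_2, c("ATG", "GTT", "AAG"))
  # degapped codons retranslate to the aligned proteins
  expect_equal(translate_cds(paste(setdiff(cod$codons_1, "---"),
                                   collapse = "")), "MK")
  expect_error(backtranslate_alignment(list(a1 = "MK", a2 = "MK"),
                                       "ATGAAA", "ATGCCC"),
               "does not retranslate")
})

test_that("NG86 site counts equal exhaustive single-mutant enumeration", {
  got <- ng86_sites("TTT")
  expect_equal(got$syn_sites, 1 / 3)
  expect_equal(got$nonsyn_sites, 8 / 3)
  got <- ng86_sites("ATG")
  expect_equal(got$syn_sites, 0)
  expect_equal(got$nonsyn_sites, 3)
  sense <- names(GC_TABLE)[GC_TABLE != "*"]
  got <- ng86_sites(sense)
  for (i in seq_along(sense)) {
    want <- oracle_ng86_sites(sense[i])
    expect_equal(got$syn_sites[i], want[["syn"]])
    expect_equal(got$nonsyn_sites[i], want[["nonsyn"]])
  }
  expect_error(ng86_sites("TAA"), "not a sense codon")
})

test_that("pairwise NG86 counting matches the pathway-enumeration oracle", {
  # single synonymous transition among identical codons: hand-checkable
  c1 <- c(rep("GCT", 100), "TTT")
  c2 <- c(rep("GCT", 100), "TTC")
  ng <- ng86_pairwise(c1, c2)
  expect_equal(ng$Sd, 1)
  expect_equal(ng$Nd, 0)
  expect_equal(ng$ka, 0)
  set.seed(31)
  for (rep in 1:25) {
    n <- 40
    cod1 <- vapply(1:n, function(i) random_sense_codon(), character(1))
    cod2 <- cod1
    mut <- sample(n, 12)
    for (i in mut) cod2[i] <- mutate_codon(cod1[i], sample(1:3, 1))
    ng <- ng86_pairwise(cod1, cod2)
    want <- oracle_ng86_alignment(cod1, cod2)
    expect_equal(ng$S, want[["S"]], tolerance = 1e-12)
    expect_equal(ng$N, want[["N"]], tolerance = 1e-12)
    expect_equal(ng$Sd, want[["Sd"]], tolerance = 1e-12)
    expect_equal(ng$Nd, want[["Nd"]], tolerance = 1e-12)
    # symmetry under swapping the sequences
    ng_sw <- ng86_pairwise(cod2, cod1)
    expect_equal(ng_sw[c("S", "N", "Sd", "Nd", "ka", "ks")],
                 ng[c("S", "N", "Sd", "Nd", "ka", "ks")])
    # per-column conservation: Sd + Nd equals the nucleotide mismatches
    mism <- sum(mapply(function(x, y) {
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }, cod1, cod2))
    expect_equal(ng$Sd + ng$Nd, mism, tolerance = 1e-12)
  }
})

test_that("NG86 handles degenerate alignments", {
  cods <- c("ATG", "GCT", "AAA")
  ng <- ng86_pairwise(cods, cods)
  expect_true(ng$no_divergence)
  expect_equal(ng$ka, 0)
  expect_equal(ng$ks, 0)
  expect_true(is.na(ng$ratio))
  expect_equal(ng$S + ng$N, 9, tolerance = 1e-9)
  # gapped and ambiguous columns are skipped
  ng <- ng86_pairwise(c("ATG", "---", "ANA"), c("ATG", "GCT", "AAA"))
  expect_equal(ng$n_codons, 1)
  expect_error(ng86_pairwise("---", "GCT"), "no comparable")
  # purely synonymous fourfold third-position differences: Ka exactly 0
  ng <- ng86_pairwise(c(rep("GTT", 20), "GCT", "GGA", "CTC"),
                      c(rep("GTT", 20), "GCC", "GGG", "CTG"))
  expect_equal(ng$ka, 0)
  expect_gt(ng$ks, 0)
  # and a fully saturated synonymous proportion is flagged, not corrected
  sat <- ng86_pairwise(c("GCT", "GGA", "CTC"), c("GCC", "GGG", "CTG"))
  expect_true(sat$saturated)
  expect_true(is.na(sat$ratio))
})

test_that("the Ks cap convention and paralog boundary are enforced", {
  # no synonymous difference but nonsynonymous divergence: capped at 50
  c1 <- c(rep("GCT", 60), "TGG")
  c2 <- c(rep("GCT", 60), "CGG")
  ng <- ng86_pairwise(c1, c2)
  expect_true(ng$capped)
  expect_equal(ng$ratio, 50)
  expect_equal(ng$ks, ng$ka / 50)
  pairs <- data.frame(id_a = c("x", "y", "z"), id_b = c("x", "y", "z"),
                      ks = c(1.0, 0.99, NA), ratio = c(1.5, 1.2, NA),
                      saturated = c(FALSE, FALSE, TRUE))
  out <- filter_and_flag(pairs)
  expect_equal(out$paralog_filtered, c(TRUE, FALSE, TRUE))
  expect_equal(out$candidate, c(FALSE, TRUE, FALSE))
})

test_that("candidate markers require fixation AND positive selection", {
  pairs <- data.frame(
    id_a = c("t1", "t2", "t3"), id_b = c("t1", "t2", "t3"),
    transcript_id = c("t1", "t2", "t3"),
    ka = c(0.01, 0.02, 0.01), ks = c(0.005, 0.005, 0.02),
    ratio = c(2, 4, 0.5), capped = FALSE,
    paralog_filtered = FALSE, candidate = c(TRUE, TRUE, FALSE))
  diff <- data.frame(transcript_id = c("t1", "t2", "t3"),
                     n_snps = c(4L, 2L, 5L), dbar = c(1, 0.95, 1),
                     n_fixed = c(4L, 1L, 5L),
                     all_fixed = c(TRUE, FALSE, TRUE))
  out <- candidate_markers(pairs, diff)
  expect_equal(out$transcript_id, "t1")   # t2 not fixed, t3 ratio <= 1
  expect_named(out, c("transcript_id", "n_snps", "dbar", "ka", "ks",
                      "ratio", "capped"))
})
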