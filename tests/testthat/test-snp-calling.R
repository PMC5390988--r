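test_that("pileup parser decodes plain columns, markers and indels", {
  col <- parse_pileup(text = "t1\t10\tA\t5\t..,,.\tIIIII")[[1]]
  expect_equal(col$depth, 5)
  expect_true(all(col$base == "A"))
  expect_equal(col$qual, rep(40, 5))
  expect_equal(col$strand, c("+", "+", "-", "-", "+"))
  # read-start marker: the ']' is a mapping quality (Q60), one call parsed
  col <- parse_pileup(text = "t1\t1\tC\t1\t^].\tI")[[1]]
  expect_equal(col$depth, 1)
  expect_equal(col$mapq, 60L)
  # read end, case-coded mismatch
  col <- parse_pileup(text = "t1\t2\tC\t3\t.$Tg\tII5")[[1]]
  expect_equal(col$base, c("C", "T", "G"))
  expect_equal(col$strand, c("+", "+", "-"))
  expect_equal(col$qual, c(40, 40, 20))
  # indel suffix consumed and ignored; deletion placeholder dropped
  col <- parse_pileup(text = "t1\t3\tG\t4\t.+2AC.,*\tIIII")[[1]]
  expect_equal(col$depth, 3)
  expect_equal(col$base, c("G", "G", "G"))
  expect_error(parse_pileup(text = "t1\t4\tG\t2\t..\tIII"),
               "line 1.*does not match")
  expect_error(parse_pileup(text = "t1\t4\tG\t2\t.."), "6 tab-separated")
})

test_that("generated pileup columns round-trip to the realized truth counts", {
  sim <- small_sim()
  thr <- caller_thresholds()
  counts <- pileup_site_counts(parse_pileup(text = sim$pileup_a$lines), thr)
  key <- paste(counts$transcript_id, counts$pos)
  r <- sim$pileup_a$realized
  i <- match(paste(r$transcript_id, r$pos), key)
  for (b in c("A", "C", "G", "T")) {
    expect_equal(counts[[b]][i], r[[b]])
  }
})

test_that("coverage and quality thresholds gate the call", {
  thr <- caller_thresholds()
  # retained depth 41 (one alt-rich site): below the 42 minimum, no call
  col <- toy_column(base = c(rep("A", 21), rep("G", 20)), qual = rep(40, 41))
  expect_null(call_site(col, thr))
  # depth 60 but every call below Phred 30: everything filtered, no call
  col <- toy_column(base = c(rep("A", 30), rep("G", 30)), qual = rep(29, 60))
  expect_null(call_site(col, thr))
  # clean 30/30 split at Q40: frequency one half
  col <- toy_column(base = c(rep("A", 30), rep("G", 30)), qual = rep(40, 60))
  call <- call_site(col, thr)
  expect_equal(call$alt, "G")
  expect_equal(call$frequency, 0.5)
  expect_equal(call$ref_count + call$alt_count, 60)
  # low mapping quality on a read-start call removes it
  col <- toy_column(base = rep("A", 50), qual = rep(40, 50), mapq = 10L)
  expect_equal(unname(diverscan::pileup_site_counts(list(col), thr)$depth), 0)
  # alt support floor: one alternate read is not a call
  col <- toy_column(base = c(rep("A", 59), "G"), qual = rep(40, 60))
  expect_null(call_site(col, thr))
})

test_that("joint sites honor the shared-alternate and coverage rules", {
  thr <- caller_thresholds()
  # A fixed alternate, B all reference: joint site (1, 0)
  a <- toy_counts("t1", 1, "A", G = 50)
  b <- toy_counts("t1", 1, "A", A = 50)
  j <- joint_sites(a, b, thr)
  expect_equal(nrow(j), 1)
  expect_equal(j$freq_a, 1)
  expect_equal(j$freq_b, 0)
  expect_equal(j$alt, "G")
  # B below minimum coverage: no site
  j <- joint_sites(toy_counts("t1", 1, "A", A = 25, G = 25),
                   toy_counts("t1", 1, "A", A = 41), thr)
  expect_equal(nrow(j), 0)
  # discordant alternates: excluded as multiallelic
  j <- joint_sites(toy_counts("t1", 1, "A", A = 25, C = 25),
                   toy_counts("t1", 1, "A", A = 25, G = 25), thr)
  expect_equal(nrow(j), 0)
  # same alternate both species: frequencies from exact counts
  j <- joint_sites(toy_counts("t1", 1, "A", A = 30, G = 30),
                   toy_counts("t1", 1, "A", A = 40, G = 10), thr)
  expect_equal(j$freq_a, 0.5)
  expect_equal(j$freq_b, 0.2)
  # reference disagreement is a consistency error
  expect_error(joint_sites(toy_counts("t1", 1, "A", A = 50),
                           toy_counts("t1", 1, "C", C = 50), thr),
               "mismatch")
})

test_that("raising min_coverage never increases the joint-site count", {
  set.seed(8)
  n <- 60
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  mk <- function() {
    df <- toy_counts("t1", 1:n, ref)
    for (b in c("A", "C", "G", "T")) df[[b]] <- rpois(n, 18)
    df$depth <- df$A + df$C + df$G + df$T
    df
  }
  a <- mk(); b <- mk()
  sizes <- vapply(c(10, 30, 42, 60, 80), function(mc) {
    nrow(joint_sites(a, b, caller_thresholds(min_coverage = mc)))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("counts are conserved and frequencies stay in [0, 1]", {
  sim <- small_sim()
  thr <- caller_thresholds()
  ca <- pileup_site_counts(parse_pileup(text = sim$pileup_a$lines), thr)
  cb <- pileup_site_counts(parse_pileup(text = sim$pileup_b$lines), thr)
  j <- joint_sites(ca, cb, thr)
  expect_true(all(j$freq_a >= 0 & j$freq_a <= 1))
  expect_true(all(j$freq_b >= 0 & j$freq_b <= 1))
  expect_true(all(j$ref_count_a + j$alt_count_a <= j$depth_a))
  expect_true(all(j$ref_count_b + j$alt_count_b <= j$depth_b))
})
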