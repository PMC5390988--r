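test_that("generator is deterministic and honors forced lengths", {
  cfg <- sim_config(n_transcripts = 1, length_range = c(600, 600), seed = 7)
  a1 <- simulate_ancestral_transcriptome(cfg)
  a2 <- simulate_ancestral_transcriptome(cfg)
  expect_identical(a1, a2)
  expect_equal(nchar(a1$transcripts$sequence), 600)
  f1 <- tempfile(); f2 <- tempfile()
  write_transcripts(a1$transcripts, f1)
  write_transcripts(a2$transcripts, f2)
  expect_identical(readLines(f1), readLines(f2))
  sim1 <- simulate_two_species(sim_config(n_transcripts = 4, seed = 5))
  sim2 <- simulate_two_species(sim_config(n_transcripts = 4, seed = 5))
  expect_identical(sim1, sim2)
})

test_that("GC content of the generated transcriptome tracks the target", {
  for (gc in c(0.35, 0.5)) {
    cfg <- sim_config(n_transcripts = 200, length_range = c(500, 900),
                      gc_content = gc, seed = 21)
    anc <- simulate_ancestral_transcriptome(cfg)
    all_nt <- paste(anc$transcripts$sequence, collapse = "")
    obs <- sum(strsplit(all_nt, "")[[1]] %in% c("G", "C")) / nchar(all_nt)
    expect_gt(obs, gc - 0.03)
    expect_lt(obs, gc + 0.03)
  }
})

test_that("config validation rejects impossible rate combinations", {
  expect_error(sim_config(fixed_diff_rate = 0.6, shared_poly_rate = 0.5),
               "exceed 1")
  expect_error(sim_config(length_range = c(600, 500)), "length_range")
  expect_error(sim_config(gc_content = 1.2), "rates")
})

test_that("planted fixed-site counts follow the configured binomial rate", {
  cfg <- sim_config(n_transcripts = 100, length_range = c(1000, 1000),
                    fixed_diff_rate = 0.01, shared_poly_rate = 0,
                    private_poly_rate = 0, seed = 33)
  anc <- simulate_ancestral_transcriptome(cfg)
  div <- diverge_species(anc, cfg)
  counts <- div$genes$n_fixed_planted
  # mean of 100 draws from Binomial(1000, 0.01): within 3 SE of 10
  se <- sqrt(1000 * 0.01 * 0.99 / 100)
  expect_lt(abs(mean(counts) - 10), 3 * se)
  expect_true(all(div$sites$type == "fixed"))
  expect_true(all(div$sites$fr_m == 1 & div$sites$fr_r == 0))
})

test_that("zero fixed rate plants nothing and omega = 0 forces synonymy", {
  cfg0 <- sim_config(n_transcripts = 10, fixed_diff_rate = 0,
                     shared_poly_rate = 0, private_poly_rate = 0, seed = 2)
  div0 <- diverge_species(simulate_ancestral_transcriptome(cfg0), cfg0)
  expect_equal(sum(div0$sites$D == 1), 0)
  cfgw <- sim_config(n_transcripts = 10, length_range = c(900, 1500),
                     fixed_diff_rate = 0.02, shared_poly_rate = 0,
                     private_poly_rate = 0, omega_default = 0, seed = 3)
  divw <- diverge_species(simulate_ancestral_transcriptome(cfgw), cfgw)
  cds <- divw$sites$cds_class[!is.na(divw$sites$cds_class)]
  expect_gt(length(cds), 0)
  expect_true(all(cds == "syn"))
  expect_equal(sum(divw$genes$n_fixed_nonsyn), 0)
})

test_that("species sequences differ from the ancestor exactly at fixed sites", {
  sim <- small_sim()
  for (i in seq_len(nrow(sim$species_b))) {
    a <- strsplit(sim$species_a$sequence[i], "")[[1]]
    b <- strsplit(sim$species_b$sequence[i], "")[[1]]
    fixed <- sim$sites[sim$sites$transcript_id == sim$species_b$id[i] &
                         sim$sites$type == "fixed", ]
    expect_identical(which(a != b), as.integer(sort(fixed$pos)))
    expect_true(all(fixed$pos >= 1 & fixed$pos <= length(b)))
  }
})

test_that("truth table D equals |FRm - FRr| everywhere", {
  sim <- small_sim()
  expect_equal(sim$sites$D, abs(sim$sites$fr_m - sim$sites$fr_r))
})

test_that("pileup stream is valid and round-trips through the parser", {
  sim <- small_sim()
  cols <- parse_pileup(text = sim$pileup_a$lines[1:500])
  expect_equal(length(cols), 500)
  # depth column equals emitted calls; parser retains them all here
  emitted <- as.integer(vapply(strsplit(sim$pileup_a$lines[1:500], "\t"),
                               `[[`, character(1), 4))
  expect_equal(vapply(cols, `[[`, integer(1), "depth"), emitted)
  # error-free deep coverage at a monomorphic site: all reference calls
  cfg <- sim_config(n_transcripts = 1, length_range = c(600, 600),
                    fixed_diff_rate = 0, shared_poly_rate = 0,
                    private_poly_rate = 0, base_error_rate = 0,
                    bad_quality_fraction = 0, depth_mean = 60, seed = 9)
  sim0 <- simulate_two_species(cfg)
  col <- parse_pileup(text = sim0$pileup_a$lines[10])[[1]]
  expect_true(all(col$base == col$ref))
  expect_true(all(col$qual == 40))
})

test_that("simulated allele fractions concentrate around the truth", {
  cfg <- sim_config(n_transcripts = 1, length_range = c(600, 600),
                    depth_mean = 10000, base_error_rate = 0,
                    bad_quality_fraction = 0, fixed_diff_rate = 0,
                    shared_poly_rate = 0, private_poly_rate = 0, seed = 12)
  sim <- simulate_two_species(cfg)
  truth <- data.frame(transcript_id = sim$species_b$id[1], pos = 50L,
                      ref = substr(sim$species_b$sequence[1], 50, 50),
                      alt = setdiff(c("A", "C", "G", "T"),
                                    substr(sim$species_b$sequence[1],
                                           50, 50))[1],
                      type = "shared", fr_m = 0.5, fr_r = 0.5,
                      cds_class = NA_character_, D = 0)
  pl <- simulate_pileups(sim$species_b, truth, cfg, "a")
  r <- pl$realized[1, ]
  frac <- r[[truth$alt]] / (r$A + r$C + r$G + r$T)
  expect_gt(frac, 0.48)
  expect_lt(frac, 0.52)
})

test_that("pileup simulation rejects transcripts missing from the reference", {
  sim <- small_sim()
  bad <- sim$sites
  bad$transcript_id[1] <- "c999_g1_i1"
  expect_error(simulate_pileups(sim$species_b, bad, sim$config, "a"),
               "absent from reference")
})

test_that("GO annotations have the planted odds and the documented format", {
  genes <- data.frame(transcript_id = sprintf("c%d_g1_i1", 1:2000),
                      all_fixed_true = c(rep(TRUE, 200), rep(FALSE, 1800)))
  cfg <- sim_config(n_transcripts = 4, go_base_rate = 0.05,
                    go_enrichment_factor = 5, seed = 77)
  ann <- emit_go_annotations(genes, cfg)
  expect_named(ann, c("transcript_id", "go_id", "namespace"))
  f <- tempfile()
  write_go_annotations(ann, f)
  reread <- read_go_annotations(f)
  expect_equal(nrow(reread), nrow(ann))
  expect_true(all(reread$namespace %in% c("BP", "MF", "CC")))
  planted <- ann[ann$go_id == cfg$enriched_go_term, ]
  rate_fixed <- mean(genes$transcript_id[genes$all_fixed_true] %in%
                       planted$transcript_id)
  rate_bg <- mean(genes$transcript_id[!genes$all_fixed_true] %in%
                    planted$transcript_id)
  expect_gt(rate_fixed / rate_bg, 3)   # planted factor 5, sampling error
  expect_lt(rate_fixed / rate_bg, 7)
  # factor 1: enrichment disappears by construction
  cfg1 <- sim_config(go_enrichment_factor = 1, seed = 77)
  ann1 <- emit_go_annotations(genes, cfg1)
  planted1 <- ann1[ann1$go_id == cfg1$enriched_go_term, ]
  r1 <- mean(genes$transcript_id[genes$all_fixed_true] %in%
               planted1$transcript_id)
  r0 <- mean(genes$transcript_id[!genes$all_fixed_true] %in%
               planted1$transcript_id)
  expect_lt(abs(r1 - r0), 0.05)
})

test_that("every truth site lies inside its transcript", {
  sim <- small_sim()
  len <- setNames(nchar(sim$species_b$sequence), sim$species_b$id)
  expect_true(all(sim$sites$pos >= 1))
  expect_true(all(sim$sites$pos <= len[sim$sites$transcript_id]))
})
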