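# Read-count genotype scoring (93%/29%/20%/5-read rules, strictness exactly
# as stated) and the two labs' locus/individual filters, checked against
# explicit brute-force re-implementations.

test_that("genotype scoring follows the read-share rules", {
  hom <- call_genotype(c(A = 10))
  expect_equal(hom$genotype, "hom")
  expect_equal(hom$alleles, c("A", "A"))
  expect_false(hom$flagged)

  het <- call_genotype(c(A = 6, B = 4))        # second share 0.40 > 0.29
  expect_equal(het$genotype, "het")
  expect_equal(het$alleles, c("A", "B"))

  pop <- call_genotype(c(A = 8, B = 2), population_haplotypes = "B")
  expect_equal(pop$genotype, "het")            # 20% with population support
  nopop <- call_genotype(c(A = 8, B = 2))
  expect_true(nopop$flagged)
  expect_equal(nopop$alleles, c("A", NA))

  low <- call_genotype(c(A = 3, B = 1))        # 4 reads < 5
  expect_true(low$flagged)
  expect_match(low$reason, "min_reads")
  expect_equal(low$alleles, c("A", NA))

  excess <- call_genotype(c(A = 4, B = 3, C = 3))
  expect_true(excess$flagged)
  expect_match(excess$reason, "more than two")

  expect_error(call_genotype(numeric()), "empty")
})

test_that("scoring thresholds are strict or inclusive exactly as specified", {
  # top share exactly 0.93 is NOT homozygous (rule is strictly > 93%)
  at_hom <- call_genotype(c(A = 93, B = 7))
  expect_true(at_hom$flagged)
  # second share exactly 0.29 fails the plain het rule ...
  at_het <- call_genotype(c(A = 71, B = 29))
  expect_true(at_het$flagged)
  # ... but qualifies via population support (>= 20%), either condition suffices
  at_het_pop <- call_genotype(c(A = 71, B = 29), population_haplotypes = "B")
  expect_equal(at_het_pop$genotype, "het")
  # second share just above 0.29 is heterozygous without support
  above_het <- call_genotype(c(A = 70, B = 30))
  expect_equal(above_het$genotype, "het")
  # exactly 5 reads is enough; 4 is not
  expect_false(call_genotype(c(A = 5))$flagged)
  expect_true(call_genotype(c(A = 4))$flagged)
  # share just below 0.20 never qualifies even with population support
  below_pop <- call_genotype(c(A = 81, B = 19), population_haplotypes = "B")
  expect_true(below_pop$flagged)
})

test_that("wsu filtering removes a missing-heavy locus and an undergenotyped individual", {
  gm <- matrix(0L, 10, 10,
               dimnames = list(sprintf("i%02d", 1:10), sprintf("L%02d", 1:10)))
  gm[1:3, "L01"] <- NA                     # 30% missing > 20% cap
  res <- filter_matrix(gm, cfg = filter_config("wsu"))
  expect_false("L01" %in% colnames(res$genotypes))
  expect_equal(ncol(res$genotypes), 9)
  expect_true("L01" %in% res$report$id)

  gm2 <- matrix(0L, 10, 20,
                dimnames = list(sprintf("i%02d", 1:10), sprintf("L%02d", 1:20)))
  gm2["i01", 1:6] <- NA                    # genotyped at 70% < 75% of retained
  res2 <- filter_matrix(gm2, cfg = filter_config("wsu"))
  expect_false("i01" %in% rownames(res2$genotypes))
  # exactly 75% genotyped is retained (rule removes only "fewer than 75%")
  gm3 <- gm2; gm3["i01", 1:6] <- 0L; gm3["i01", 1:5] <- NA
  res3 <- filter_matrix(gm3, cfg = filter_config("wsu"))
  expect_true("i01" %in% rownames(res3$genotypes))
})

test_that("locus boundary fractions are non-strict as quoted", {
  gm <- matrix(0L, 20, 5,
               dimnames = list(sprintf("i%02d", 1:20), sprintf("L%02d", 1:5)))
  gm[1:4, "L01"] <- NA                     # exactly 20% missing: retained
  flags <- matrix(FALSE, 20, 5, dimnames = dimnames(gm))
  flags[1, "L02"] <- TRUE                  # exactly 5% flagged: retained
  res <- filter_matrix(gm, flags, filter_config("wsu"))
  expect_true(all(c("L01", "L02") %in% colnames(res$genotypes)))

  # cornell: exactly 80% presence retained, exactly 25% missing individual kept
  gmc <- matrix(0L, 10, 4,
                dimnames = list(sprintf("i%02d", 1:10), sprintf("L%02d", 1:4)))
  gmc[1:2, "L01"] <- NA                    # presence exactly 0.8
  resc <- filter_matrix(gmc, cfg = filter_config("cornell"))
  expect_true("L01" %in% colnames(resc$genotypes))
  gmi <- matrix(0L, 4, 8,
                dimnames = list(sprintf("i%02d", 1:4), sprintf("L%02d", 1:8)))
  gmi["i01", 1:2] <- NA                    # individual missing exactly 25%
  resi <- filter_matrix(gmi, cfg = filter_config("cornell"))
  expect_true("i01" %in% rownames(resi$genotypes))
})

test_that("cornell preset keeps one SNP per RAD locus and drops Z-linked sites last", {
  gm <- matrix(0L, 6, 4,
               dimnames = list(sprintf("i%d", 1:6), c("s1", "s2", "s3", "s4")))
  loci <- data.frame(locus_id = c("s1", "s2", "s3", "s4"),
                     rad_locus = c("r1", "r1", "r2", "r3"),
                     chrom = c("chr1", "chr1", "Z", "chr2"),
                     pos = c(100, 50, 10, 10))
  res <- filter_matrix(gm, cfg = filter_config("cornell"), loci = loci)
  # s2 precedes s1 on r1; s3 is Z-linked
  expect_setequal(colnames(res$genotypes), c("s2", "s4"))
  expect_setequal(res$report$id[res$report$stage == "one_snp_per_locus"], "s1")
  expect_setequal(res$report$id[res$report$stage == "z_chromosome"], "s3")
})

test_that("the presets are order-sensitive and can disagree on crafted input", {
  # a locus with 10% flagged genotypes: removed by wsu (cap 5%), kept by cornell
  gm <- matrix(0L, 10, 3,
               dimnames = list(sprintf("i%02d", 1:10), c("L1", "L2", "L3")))
  flags <- matrix(FALSE, 10, 3, dimnames = dimnames(gm))
  flags[1, "L1"] <- TRUE
  wsu <- filter_matrix(gm, flags, filter_config("wsu"))
  cor <- filter_matrix(gm, flags, filter_config("cornell"))
  expect_false("L1" %in% colnames(wsu$genotypes))
  expect_true("L1" %in% colnames(cor$genotypes))

  # cornell's second presence pass: removing a missing-heavy individual that
  # WAS genotyped at L1 pushes L1's presence among the survivors below 80%,
  # so cornell drops it on re-export while wsu (loci judged once, against all
  # individuals) keeps it
  gm2 <- matrix(0L, 10, 8,
                dimnames = list(sprintf("i%02d", 1:10), sprintf("L%d", 1:8)))
  gm2["i10", c("L2", "L3", "L4")] <- NA    # 37.5% missing: removed by both presets
  gm2[c("i01", "i02"), "L1"] <- NA         # L1: 20% missing, presence exactly 0.8
  wsu2 <- filter_matrix(gm2, cfg = filter_config("wsu"))
  cor2 <- filter_matrix(gm2, cfg = filter_config("cornell"))
  expect_true("L1" %in% colnames(wsu2$genotypes))
  expect_false("L1" %in% colnames(cor2$genotypes))
  expect_true("L1" %in%
    cor2$report$id[cor2$report$stage == "locus_presence_reexport"])
})

test_that("filtering is idempotent and empty results raise errors", {
  rm <- random_genotype_matrix(12, 20, seed = 5)
  for (preset in c("wsu", "cornell")) {
    res <- filter_matrix(rm$gm, rm$flags, filter_config(preset))
    res2 <- filter_matrix(res$genotypes, res$flags, filter_config(preset),
                          loci = res$loci)
    expect_identical(res2$genotypes, res$genotypes)
    expect_equal(nrow(res2$report), 0)
  }
  gm <- matrix(NA_integer_, 4, 3,
               dimnames = list(paste0("i", 1:4), paste0("L", 1:3)))
  gm[1, ] <- 0L                             # every locus 75% missing
  expect_error(filter_matrix(gm, cfg = filter_config("wsu")),
               class = "dh_empty_result")
  expect_error(filter_matrix(matrix(0, 0, 0)), "non-empty")
})

test_that("both presets reproduce a brute-force oracle on 100 random matrices", {
  for (rep in 1:100) {
    rm <- random_genotype_matrix(n_ind = 8 + rep %% 5, n_loci = 12 + rep %% 7,
                                 p_missing = 0.10 + 0.15 * (rep %% 3),
                                 p_flag = 0.04 + 0.02 * (rep %% 2), seed = rep)
    got_w <- tryCatch(filter_matrix(rm$gm, rm$flags, filter_config("wsu")),
                      dh_empty_result = function(e) NULL)
    exp_w <- naive_filter_wsu(rm$gm, rm$flags)
    if (is.null(got_w)) {
      expect_length(exp_w$loci, 0)
    } else {
      expect_identical(colnames(got_w$genotypes), exp_w$loci)
      expect_identical(rownames(got_w$genotypes), exp_w$individuals)
    }
    loci <- data.frame(locus_id = colnames(rm$gm), rad_locus = colnames(rm$gm),
                       chrom = NA_character_, pos = seq_len(ncol(rm$gm)))
    got_c <- tryCatch(filter_matrix(rm$gm, rm$flags, filter_config("cornell"),
                                    loci = loci),
                      dh_empty_result = function(e) NULL)
    exp_c <- naive_filter_cornell(rm$gm, loci)
    if (is.null(got_c)) {
      expect_length(exp_c$loci, 0)
    } else {
      expect_identical(colnames(got_c$genotypes), exp_c$loci)
      expect_identical(rownames(got_c$genotypes), exp_c$individuals)
    }
  }
})
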