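test_that("Hardy-Weinberg exact test matches brute-force enumeration", {
  expect_equal(hwe_exact_test(100, 0, 0), 1.0)
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25))
  expect_error(hwe_exact_test(-1, 0, 5), ">= 0")
  # exhaustive sweep over small totals; spot checks at larger ones
  for (n in c(1:25, 40, 60)) {
    for (m in 0:n) {
      d_imp <- exocall:::hwe_het_distribution(n, m)
      d_or <- hwe_oracle_distribution(n, m)
      expect_equal(sum(d_imp$prob), 1, tolerance = 1e-12)
      expect_identical(d_imp$n_het, d_or$n_het)
      expect_lt(max(abs(d_imp$prob - d_or$prob)), 1e-12)
    }
  }
  set.seed(7)
  for (i in 1:50) {
    cnt <- rmultinom(1, sample(10:200, 1), runif(3))[, 1]
    if (sum(cnt) == 0) next
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("IBD estimation separates duplicates, parent-offspring, unrelated", {
  cfg <- sim_config(n_samples = 24, n_variants = 5000, x_chrom_fraction = 0,
                    maf_spectrum = common_spectrum(),
                    dup_pairs = 1, rel_pairs = 1, seed = 17)
  b <- simulate_dataset(cfg)
  ibd <- estimate_ibd(b$truth)
  sm <- b$sample_meta
  pair_pi <- function(a, b_) {
    ibd$PI_HAT[(ibd$id1 == a & ibd$id2 == b_) | (ibd$id1 == b_ & ibd$id2 == a)]
  }
  dup <- sm$sample_id[sm$rel_type == "dup"]
  off <- sm$sample_id[sm$rel_type == "offspring"]
  expect_gte(pair_pi(dup, sm$rel_partner[match(dup, sm$sample_id)]), 0.95)
  po <- pair_pi(off, sm$rel_partner[match(off, sm$sample_id)])
  expect_equal(po, 0.5, tolerance = 0.05 / 0.5)
  rel_ids <- c(dup, off, sm$rel_partner[sm$rel_type != "none"])
  unrel <- ibd$PI_HAT[!(ibd$id1 %in% rel_ids | ibd$id2 %in% rel_ids)]
  expect_true(all(unrel <= 0.1))
  # parent-offspring sharing is Z1-dominant
  i <- which((ibd$id1 == off | ibd$id2 == off) &
               (ibd$id1 == sm$rel_partner[match(off, sm$sample_id)] |
                  ibd$id2 == sm$rel_partner[match(off, sm$sample_id)]))
  expect_gt(ibd$Z1[i], ibd$Z0[i])
  expect_gt(ibd$Z1[i], ibd$Z2[i])
  # monomorphic-only input is an error
  mono <- new_genotype_matrix(matrix(0L, 50, 4,
                                     dimnames = list(paste0("v", 1:50),
                                                     paste0("s", 1:4))))
  expect_error(estimate_ibd(mono), "monomorphic")
})

test_that("the X-heterozygosity sex check infers sexes and flags conflicts", {
  cfg <- sim_config(n_samples = 80, n_variants = 300, x_chrom_fraction = 1,
                    maf_spectrum = common_spectrum(), seed = 19)
  b <- simulate_dataset(cfg)
  st <- check_sex(b$truth, b$sample_meta$sex)
  males <- b$sample_meta$sex == "M"
  expect_true(all(st$F[males] > 0.99))  # hemizygous: no X heterozygotes
  expect_true(all(st$inferred[males] == "M"))
  expect_true(all(st$inferred[!males] == "F"))
  expect_true(all(st$status == "ok"))
  # a declared female who is genetically male fails
  declared <- b$sample_meta$sex
  flip <- which(males)[1]
  declared[flip] <- "F"
  st2 <- check_sex(b$truth, declared)
  expect_identical(st2$status[flip], "fail")
  # missing declared sex is skipped with a warning
  declared[2] <- NA
  expect_warning(st3 <- check_sex(b$truth, declared), "declared sex")
  expect_identical(st3$status[2], "skipped")
})

test_that("sample QC excludes relatives, sex failures and low call rates", {
  cfg <- sim_config(n_samples = 40, n_variants = 4000, x_chrom_fraction = 0.1,
                    maf_spectrum = common_spectrum(), dup_pairs = 1,
                    seed = 23)
  b <- simulate_dataset(cfg)
  g <- dose(b$truth)
  is_x <- b$variant_meta$chrom == "X"
  # degrade one sample's call rate to 98%
  victim <- 10L
  miss <- sample(which(!is_x), round(0.02 * sum(!is_x)))
  g[miss, victim] <- NA
  auto <- new_genotype_matrix(g[!is_x, , drop = FALSE])
  xg <- new_genotype_matrix(g[is_x, , drop = FALSE])
  ex <- qc_samples(auto, xg, b$sample_meta$sex)
  dup <- b$sample_meta$sample_id[b$sample_meta$rel_type == "dup"]
  partner <- b$sample_meta$rel_partner[b$sample_meta$rel_type == "dup"]
  rel_ex <- ex$sample_id[ex$reason == "relatedness"]
  expect_length(rel_ex, 1)
  expect_true(rel_ex %in% c(dup, partner))
  expect_true(b$sample_meta$sample_id[victim] %in%
                ex$sample_id[ex$reason == "low_call_rate"])
  # a clean cohort has no exclusions
  cfg2 <- sim_config(n_samples = 30, n_variants = 3000,
                     x_chrom_fraction = 0.1,
                     maf_spectrum = common_spectrum(), seed = 29)
  b2 <- simulate_dataset(cfg2)
  g2 <- dose(b2$truth)
  is_x2 <- b2$variant_meta$chrom == "X"
  ex2 <- qc_samples(new_genotype_matrix(g2[!is_x2, , drop = FALSE]),
                    new_genotype_matrix(g2[is_x2, , drop = FALSE]),
                    b2$sample_meta$sex)
  expect_identical(nrow(ex2), 0L)
})

test_that("variant QC applies its filters with the documented reasons", {
  set.seed(31)
  n_s <- 60
  meta <- data.frame(variant_id = paste0("v", 1:6),
                     chrom = rep("1", 6), pos = c(10, 20, 30, 40, 50, 50),
                     ref = "A", alt = "G", stringsAsFactors = FALSE)
  g <- rbind(
    rep(NA_integer_, n_s),                                  # all NC
    c(rep(1L, 30), rep(0L, 15), rep(2L, 15)),               # HWE-consistent
    c(1L, rep(0L, n_s - 1)),                                # singleton
    c(rep(1L, 60)),                                         # all het: HWE out
    rep(c(0L, 1L, 1L, 2L), 15),                             # dup-position pair
    c(rep(c(0L, 1L, 1L, 2L), 14), 0L, 1L, 1L, NA))
  rownames(g) <- meta$variant_id
  colnames(g) <- paste0("s", 1:n_s)
  ex <- qc_variants(new_genotype_matrix(g), meta)
  reason <- setNames(ex$reason, ex$variant_id)
  expect_identical(unname(reason["v1"]), "low_call_rate")
  expect_false("v2" %in% ex$variant_id)
  expect_identical(unname(reason["v3"]), "low_mac")
  expect_identical(unname(reason["v4"]), "hwe")
  # of the duplicated position pair, the lower-call-rate record goes
  expect_identical(unname(reason["v6"]), "duplicate")
  expect_false("v5" %in% ex$variant_id)
  # monomorphic variants get their own reason
  g2 <- matrix(0L, 1, n_s, dimnames = list("m1", colnames(g)))
  ex2 <- qc_variants(new_genotype_matrix(g2),
                     data.frame(variant_id = "m1", chrom = "1", pos = 1,
                                ref = "A", alt = "G"))
  expect_identical(ex2$reason, "monomorphic")
})

test_that("the QC cascade is deterministic and monotone in its thresholds", {
  cfg <- sim_config(n_samples = 50, n_variants = 600, x_chrom_fraction = 0.1,
                    dup_pairs = 1, seed = 37)
  b <- simulate_dataset(cfg)
  q1 <- run_qc(b$truth, b$variant_meta, b$sample_meta$sex)
  q2 <- run_qc(b$truth, b$variant_meta, b$sample_meta$sex)
  expect_identical(q1, q2)
  # tightening the variant call-rate threshold never reduces exclusions
  loose <- run_qc(b$truth, b$variant_meta, b$sample_meta$sex,
                  qc_config(variant_call_rate_min = 0.9))
  tight <- run_qc(b$truth, b$variant_meta, b$sample_meta$sex,
                  qc_config(variant_call_rate_min = 0.999))
  expect_gte(nrow(tight$variants_excluded), nrow(loose$variants_excluded))
  # tightening the MAC threshold likewise
  mac4 <- run_qc(b$truth, b$variant_meta, b$sample_meta$sex,
                 qc_config(mac_min = 4L))
  expect_gte(nrow(mac4$variants_excluded), nrow(q1$variants_excluded))
  # survivors plus excluded partition the input
  expect_identical(q1$dim_after[1] + nrow(q1$variants_excluded),
                   q1$dim_before[1])
  expect_identical(q1$dim_after[2] + nrow(q1$samples_excluded),
                   q1$dim_before[2])
})
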