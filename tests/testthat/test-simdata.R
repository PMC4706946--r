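test_that("MAF spectrum sampling respects the interval masses", {
  # degenerate spectrum: everything monomorphic
  cfg <- sim_config(maf_spectrum = data.frame(lo = 0, hi = 0, prop = 1),
                    seed = 1)
  expect_true(all(sample_maf_spectrum(cfg, 100) == 0))

  # single common interval: containment
  cfg2 <- sim_config(maf_spectrum = data.frame(lo = 0.05, hi = 0.5, prop = 1),
                     seed = 2)
  maf <- sample_maf_spectrum(cfg2, 1000)
  expect_true(all(maf > 0.05 & maf <= 0.5))

  # default spectrum: monomorphic fraction matches its mass at large n
  cfg3 <- sim_config(seed = 3)
  maf3 <- sample_maf_spectrum(cfg3, 1e5)
  expect_equal(mean(maf3 == 0), 0.667, tolerance = 0.01 / 0.667)

  # invalid spectra are configuration errors
  expect_error(sim_config(maf_spectrum = data.frame(lo = 0, hi = 0,
                                                    prop = 0.9)),
               "sum to 1")
  expect_error(sim_config(maf_spectrum = data.frame(lo = c(0, 0),
                                                    hi = c(0, 0.5),
                                                    prop = c(1.5, -0.5))),
               "non-negative")
})

test_that("simulated bundles are deterministic and respect the config", {
  cfg <- sim_config(n_samples = 40, n_variants = 30, seed = 11,
                    dup_pairs = 1, rel_pairs = 1,
                    error_mode_rates = c(low_r_wide_theta = 0.1))
  b1 <- simulate_dataset(cfg)
  b2 <- simulate_dataset(cfg)
  expect_identical(b1, b2)

  # monomorphic forcing: all truth AA
  cfg0 <- sim_config(n_samples = 20, n_variants = 10,
                     maf_spectrum = data.frame(lo = 0, hi = 0, prop = 1),
                     x_chrom_fraction = 0, seed = 4)
  b0 <- simulate_dataset(cfg0)
  expect_true(all(dose(b0$truth) == 0L))

  # truth carries no no-calls; dimensions agree
  expect_false(anyNA(dose(b1$truth)))
  expect_identical(dim(b1$intensities$theta), dim(dose(b1$truth)))
  expect_true(all(b1$error_registry$variant_id %in%
                    b1$variant_meta$variant_id))
})

test_that("simulated genotypes follow HWE and planted relationships", {
  cfg <- sim_config(n_samples = 600, n_variants = 60,
                    maf_spectrum = common_spectrum(),
                    x_chrom_fraction = 0, dup_pairs = 1, rel_pairs = 1,
                    seed = 21)
  b <- simulate_dataset(cfg)
  g <- dose(b$truth)
  unrelated <- b$sample_meta$rel_type == "none"
  for (v in seq_len(nrow(g))) {
    p <- b$variant_meta$true_maf[v]
    o <- mean(g[v, unrelated] == 1L)
    e <- 2 * p * (1 - p)
    se <- sqrt(e * (1 - e) / sum(unrelated))
    expect_lt(abs(o - e), 3 * se + 1e-12)
  }
  # duplicates copy genotypes exactly
  dup <- which(b$sample_meta$rel_type == "dup")
  par <- match(b$sample_meta$rel_partner[dup], b$sample_meta$sample_id)
  expect_identical(g[, dup], g[, par])
  # parent-offspring share at least one allele everywhere
  off <- which(b$sample_meta$rel_type == "offspring")
  par2 <- match(b$sample_meta$rel_partner[off], b$sample_meta$sample_id)
  expect_true(all(abs(g[, off] - g[, par2]) <= 1L))
})

test_that("X-chromosome males are hemizygous (no heterozygotes)", {
  cfg <- sim_config(n_samples = 100, n_variants = 50, x_chrom_fraction = 1,
                    maf_spectrum = common_spectrum(), seed = 8)
  b <- simulate_dataset(cfg)
  g <- dose(b$truth)
  males <- b$sample_meta$sex == "M"
  expect_true(all(g[, males] %in% c(0L, 2L)))
  expect_true(any(g[, !males] == 1L))
})

test_that("error injection modifies exactly the registered points", {
  base_cfg <- sim_config(n_samples = 80, n_variants = 40, seed = 31)
  err_cfg <- sim_config(n_samples = 80, n_variants = 40, seed = 31,
                        error_mode_rates = c(ab_misassign = 0.1,
                                             low_r_wide_theta = 0.1,
                                             short_boundary = 0.1))
  b0 <- simulate_dataset(base_cfg)
  b1 <- simulate_dataset(err_cfg)
  changed <- which(b0$intensities$theta != b1$intensities$theta |
                     b0$intensities$r != b1$intensities$r, arr.ind = TRUE)
  listed <- do.call(rbind, lapply(seq_len(nrow(b1$error_registry)),
    function(i) {
      sids <- strsplit(b1$error_registry$samples[i], ",")[[1]]
      if (!length(sids) || !nzchar(sids[1])) return(NULL)
      cbind(match(b1$error_registry$variant_id[i],
                  b1$variant_meta$variant_id),
            match(sids, b1$sample_meta$sample_id))
    }))
  key <- function(m) paste(m[, 1], m[, 2])
  expect_true(all(key(changed) %in% key(listed)))
  expect_true(all(key(listed) %in% key(changed)))
  # short_boundary touches no intensities but is registered
  sb <- b1$error_registry[b1$error_registry$mode == "short_boundary", ]
  expect_gt(nrow(sb), 0)
  expect_true(all(sb$samples == ""))
})

test_that("inject_error_mode honours its contracts", {
  theta <- rep(0.1, 20); r <- rep(1, 20); truth <- rep(0L, 20)
  # k = 0 is a no-op with an empty affected list
  res <- inject_error_mode(list(theta = theta, r = r), truth,
                           "ab_misassign", params = list(ab_k = 0L))
  expect_identical(res$theta, theta)
  expect_length(res$affected, 0)
  # k exceeding the homozygote pool errors
  expect_error(inject_error_mode(list(theta = theta, r = r), truth,
                                 "ab_misassign", params = list(ab_k = 21L)),
               "exceeds")
  # low_r_wide_theta forces R below 0.4x the cluster mean by construction
  set.seed(1)
  res2 <- inject_error_mode(list(theta = theta, r = r), truth,
                            "low_r_wide_theta",
                            params = list(lowr_fraction = 0.25,
                                          lowr_factor = 0.3))
  expect_true(all(res2$r[res2$affected] < mean(r[-res2$affected]) * 0.4))
  expect_error(inject_error_mode(list(theta = theta, r = r), truth,
                                 "bogus_mode"), "unknown error mode")
})

test_that("sequencing-truth surrogate flips at the configured rate", {
  cfg <- sim_config(n_samples = 100, n_variants = 100,
                    maf_spectrum = common_spectrum(),
                    x_chrom_fraction = 0, seed = 10)
  b <- simulate_dataset(cfg)
  # identity when error-free and fully on-target
  s0 <- simulate_truth_seq(b$truth, 0, 0, seed = 1)
  expect_identical(dose(s0$genotypes), dose(b$truth))
  expect_length(s0$off_target, 0)
  # flip count is binomial: 100 +/- 30 at rate 0.01 over 10,000 genotypes
  flips <- vapply(1:5, function(s) {
    sq <- simulate_truth_seq(b$truth, 0.01, 0, seed = s)
    sum(dose(sq$genotypes) != dose(b$truth))
  }, numeric(1))
  expect_true(all(flips >= 70 & flips <= 130))
  # off-target count is exact by construction
  s2 <- simulate_truth_seq(b$truth, 0, 0.2, seed = 3)
  expect_length(s2$off_target, 20)
})
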