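test_that("builtin rulesets have 17 rules differing only in four rows", {
  ch <- builtin_ruleset("charge")
  ad <- builtin_ruleset("adjusted")
  expect_length(ch$rules, 17)
  expect_length(ad$rules, 17)
  ids <- vapply(ch$rules, `[[`, character(1), "id")
  expect_identical(ids, vapply(ad$rules, `[[`, character(1), "id"))
  differing <- ids[!mapply(identical, ch$rules, ad$rules)]
  expect_setequal(differing, c("maf_low_callfreq", "aa_only_callfreq",
                               "no_het_maf", "bb_only_callfreq"))
  shared <- c("cluster_sep_low", "het_excess_high", "het_excess_low")
  expect_true(all(shared %in% ids))
  expect_error(builtin_ruleset("nope"), "charge, adjusted")
})

test_that("rules fire on the documented example variants", {
  ad <- builtin_ruleset("adjusted")
  ch <- builtin_ruleset("charge")

  # call_freq 0.97, all else nominal: only the call-frequency band fires
  row <- nominal_metrics_row(call_freq = 0.97, n_NC = 3L, n_called = 97L)
  rep <- apply_ruleset(row, ad)
  expect_identical(rep$hits$rule_id, "call_freq_band")

  # fully nominal variant: zero flags
  rep0 <- apply_ruleset(nominal_metrics_row(), ad)
  expect_identical(nrow(rep0$hits), 0L)
  expect_identical(rep0$total_redundant, 0L)

  # singleton with no heterozygotes among 14,000 calls: flagged by the
  # CHARGE missing-heterozygote rule but not by the adjusted one
  row2 <- nominal_metrics_row(
    n_AA = 13999L, n_AB = 0L, n_BB = 1L, n_NC = 0L, n_called = 14000L,
    freq_AA = 13999 / 14000, freq_AB = 0, freq_BB = 1 / 14000,
    maf = 2 / 28000, mac = 2L, het_excess = het_excess(13999, 0, 1),
    t_mean_AB = NA_real_, t_dev_AB = NA_real_, ab_r_mean = NA_real_)
  expect_true("no_het_maf" %in% apply_ruleset(row2, ch)$hits$rule_id)
  expect_false("no_het_maf" %in% apply_ruleset(row2, ad)$hits$rule_id)

  # absent fields never satisfy a predicate
  row3 <- nominal_metrics_row(t_dev_BB = NA_real_)
  expect_false("bb_t_dev_high" %in% apply_ruleset(row3, ad)$hits$rule_id)

  # equality rules are count-based: call_freq 1 but stored as 1 - 1e-16
  row4 <- nominal_metrics_row(n_AB = 0L, n_BB = 0L, n_AA = 100L,
                              freq_AA = 1, freq_AB = 0, freq_BB = 0,
                              maf = 0, mac = 0L, n_NC = 0L,
                              call_freq = 1 - 1e-16)
  expect_false("aa_only_callfreq" %in% apply_ruleset(row4, ch)$hits$rule_id)
})

test_that("flag reports are order-independent and summarize correctly", {
  set.seed(5)
  rows <- do.call(rbind, lapply(1:20, function(i) {
    nominal_metrics_row(variant_id = paste0("v", i),
                        call_freq = sample(c(1, 0.97, 0.9), 1),
                        het_excess = sample(c(0, 0.2), 1),
                        cluster_sep = sample(c(0.8, 0.3), 1))
  }))
  rows$n_NC <- ifelse(rows$call_freq < 1, 5L, 0L)
  ad <- builtin_ruleset("adjusted")
  rep <- apply_ruleset(rows, ad)
  perm <- ad
  perm$rules <- rev(perm$rules)
  rep_perm <- apply_ruleset(rows, perm)
  o <- order(rep$hits$variant_id, rep$hits$rule_id)
  op <- order(rep_perm$hits$variant_id, rep_perm$hits$rule_id)
  expect_identical(rep$hits[o, ], rep_perm$hits[op, ],
                   ignore_attr = TRUE)
  expect_identical(rep$total_redundant, rep_perm$total_redundant)

  s <- summarize_flags(rep)
  expect_identical(attr(s, "total_redundant"), rep$total_redundant)
  expect_identical(s$n[s$rule_id == "total_redundant"],
                   rep$total_redundant)
  # one variant flagged by three rules counts three with redundancy, one unique
  one <- nominal_metrics_row(call_freq = 0.97, n_NC = 3L, n_called = 97L,
                             het_excess = 0.5, cluster_sep = 0.2)
  rep1 <- apply_ruleset(one, ad)
  expect_identical(rep1$total_redundant, 3L)
  expect_identical(rep1$n_unique, 1L)
})

test_that("adjusted flags are contained in CHARGE flags on simulated data", {
  bold <- c("maf_low_callfreq", "aa_only_callfreq", "no_het_maf",
            "bb_only_callfreq")
  ch <- builtin_ruleset("charge"); ad <- builtin_ruleset("adjusted")
  for (seed in 1:3) {
    cfg <- sim_config(n_samples = 120, n_variants = 150, seed = seed,
                      error_mode_rates = c(ab_misassign = 0.05,
                                           low_r_wide_theta = 0.05,
                                           short_boundary = 0.05))
    b <- simulate_dataset(cfg)
    models <- bundle_models(b)
    mt <- variant_metrics_table(call_genotypes(b$intensities, models),
                                b$intensities, models)
    rep_ch <- apply_ruleset(mt, ch)
    rep_ad <- apply_ruleset(mt, ad)
    for (rid in bold) {
      va <- rep_ad$hits$variant_id[rep_ad$hits$rule_id == rid]
      vc <- rep_ch$hits$variant_id[rep_ch$hits$rule_id == rid]
      expect_true(all(va %in% vc))
    }
    expect_lte(rep_ad$total_redundant, rep_ch$total_redundant)
  }
})

test_that("most planted-error variants are flagged by the adjusted rules", {
  hits <- 0L; total <- 0L
  for (seed in 1:4) {
    cfg <- sim_config(n_samples = 500, n_variants = 100, seed = seed,
                      error_mode_rates = c(ab_misassign = 0.1,
                                           low_r_wide_theta = 0.1,
                                           short_boundary = 0.1))
    b <- simulate_dataset(cfg)
    models <- bundle_models(b)
    mt <- variant_metrics_table(call_genotypes(b$intensities, models),
                                b$intensities, models)
    rep <- apply_ruleset(mt, builtin_ruleset("adjusted"))
    planted <- unique(b$error_registry$variant_id)
    hits <- hits + sum(planted %in% rep$hits$variant_id)
    total <- total + length(planted)
  }
  expect_gte(hits / total, 0.9)
})

test_that("rulesets round-trip through YAML and JSON", {
  ad <- builtin_ruleset("adjusted")
  for (ext in c("yaml", "json")) {
    path <- file.path(tempdir(), paste0("ruleset.", ext))
    write_ruleset(ad, path)
    back <- read_ruleset(path)
    row <- nominal_metrics_row(call_freq = 0.97, n_NC = 3L, n_called = 97L,
                               cluster_sep = 0.2)
    expect_identical(apply_ruleset(row, back)$hits,
                     apply_ruleset(row, ad)$hits)
    unlink(path)
  }
})
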