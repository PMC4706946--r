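test_that("model building handles degenerate cluster configurations", {
  cfg <- caller_config()
  # all points in one tight cluster: only AA populated, mean recovered
  m1 <- build_cluster_model(rep(0.1, 50), rep(1, 50), cfg)
  expect_identical(unname(m1$populated), c(TRUE, FALSE, FALSE))
  expect_equal(unname(m1$theta_mean["AA"]), 0.1)

  # homozygote-only variant: AB unpopulated
  set.seed(5)
  th <- c(rnorm(40, 0.1, 0.02), rnorm(40, 0.9, 0.02))
  m2 <- build_cluster_model(clip_unit(th), rep(1, 80), cfg)
  expect_identical(unname(m2$populated), c(TRUE, FALSE, TRUE))

  # all-missing input: every cluster unpopulated
  m3 <- build_cluster_model(rep(NA_real_, 10), rep(NA_real_, 10), cfg)
  expect_false(any(m3$populated))
})

test_that("model building recovers well-separated generating clusters", {
  set.seed(7)
  n <- c(150, 200, 150)
  th <- clip_unit(c(rnorm(n[1], 0.1, 0.025), rnorm(n[2], 0.5, 0.025),
                    rnorm(n[3], 0.9, 0.025)))
  r <- rlnorm(sum(n), 0, 0.1)
  m <- build_cluster_model(th, r)
  expect_true(all(m$populated))
  expect_equal(unname(m$theta_mean), c(0.1, 0.5, 0.9), tolerance = 0.01)
  expect_true(all(diff(m$theta_mean) > 0))
})

test_that("calling follows the posterior and no-call rules", {
  set.seed(9)
  th <- clip_unit(c(rnorm(50, 0.1, 0.02), rnorm(50, 0.5, 0.02),
                    rnorm(50, 0.9, 0.02)))
  r <- rlnorm(150, 0, 0.1)
  m <- build_cluster_model(th, r)
  # a point at the AB centre is called AB
  res <- exocall:::call_variant(m$theta_mean["AB"], m$r_mean["AB"], m)
  expect_identical(res$dosage, 1L)
  expect_gt(res$score, 0.99)
  # missing intensity is NC
  expect_true(is.na(exocall:::call_variant(NA_real_, 1, m)$dosage))
  # theta = 0.5 with AB unpopulated and both homozygotes far: NC
  m2 <- m
  m2$populated["AB"] <- FALSE
  expect_true(is.na(exocall:::call_variant(0.5, 1, m2)$dosage))
})

test_that("calling is idempotent and matches truth on clean simulations", {
  cfg <- sim_config(n_samples = 200, n_variants = 60, seed = 13)
  b <- simulate_dataset(cfg)
  gen <- generating_models(cfg, b$variant_meta$variant_id)
  c1 <- call_genotypes(b$intensities, gen)
  c2 <- call_genotypes(b$intensities, gen)
  expect_identical(c1, c2)
  expect_gte(called_concordance(c1, b$truth), 0.999)
  # built-from-data models do as well
  own <- bundle_models(b)
  expect_gte(called_concordance(call_genotypes(b$intensities, own),
                                b$truth), 0.999)
  # variants absent from the model set are an error naming the variant
  sub <- structure(list(models = own$models[-1], config = own$config),
                   class = "cluster_model_set")
  expect_error(call_genotypes(b$intensities, sub), "var00001")
})

test_that("a planted pseudo-heterozygote spur is called AB then repaired", {
  set.seed(42)
  theta <- clip_unit(rnorm(500, 0.10, 0.025))
  r <- rlnorm(500, 0, 0.1)
  set.seed(99)
  res <- inject_error_mode(list(theta = theta, r = r), rep(0L, 500),
                           "ab_misassign", params = list(ab_k = 5L))
  m <- build_cluster_model(res$theta, res$r)
  calls <- exocall:::call_variant(res$theta, res$r, m)
  # exactly the 5 drifted samples are called AB by the default model
  expect_identical(which(calls$dosage == 1L), res$affected)

  mt <- compute_variant_metrics(calls$dosage, res$theta, res$r, m)
  flags <- apply_ruleset(as.data.frame(c(list(variant_id = "v"), mt)),
                         builtin_ruleset("adjusted"))
  expect_true("ab_t_mean_low_band" %in% flags$hits$rule_id)

  rec <- recluster_variant(res$theta, res$r, m, flags$hits$rule_id)
  expect_identical(rec$status, "reclustered")
  # post-repair calls match truth (AA) for at least 4 of the 5 moved samples
  expect_gte(sum(rec$calls[res$affected] == 0L, na.rm = TRUE), 4)
  validate <- exocall:::validate_cluster_model(rec$model)
  expect_s3_class(validate, "cluster_model")
})

test_that("reclustering statuses cover unchanged and zeroed cases", {
  # frequency-only flag with clean geometry: unchanged
  set.seed(3)
  theta <- clip_unit(rnorm(400, 0.1, 0.02))
  theta[1:2] <- NA  # a couple of missing points: call freq 0.995
  r <- rlnorm(400, 0, 0.1)
  m <- build_cluster_model(theta, r)
  rec <- recluster_variant(theta, r, m, flags = "maf_low_callfreq")
  expect_identical(rec$status, "unchanged")
  expect_identical(rec$model, m)

  # uniform theta admits no three-cluster structure: zeroed
  set.seed(4)
  th_u <- runif(300)
  r_u <- rlnorm(300, 0, 0.1)
  m_u <- build_cluster_model(th_u, r_u)
  rec_u <- recluster_variant(th_u, r_u, m_u, flags = "cluster_sep_low")
  expect_identical(rec_u$status, "zeroed")
})

test_that("reclustering never increases the truth-mismatch count", {
  for (seed in 1:20) {
    cfg <- sim_config(n_samples = 120, n_variants = 30, seed = seed,
                      error_mode_rates = c(ab_misassign = 0.1,
                                           low_r_wide_theta = 0.1,
                                           short_boundary = 0.1))
    b <- simulate_dataset(cfg)
    models <- bundle_models(b)
    calls <- call_genotypes(b$intensities, models)
    mt <- variant_metrics_table(calls, b$intensities, models)
    flags <- apply_ruleset(mt, builtin_ruleset("adjusted"))
    tr <- dose(b$truth)
    g <- dose(calls)
    planted <- unique(b$error_registry$variant_id)
    for (vid in intersect(planted, unique(flags$hits$variant_id))) {
      v <- match(vid, rownames(g))
      rec <- recluster_variant(
        b$intensities$theta[v, ], b$intensities$r[v, ],
        models$models[[vid]],
        flags$hits$rule_id[flags$hits$variant_id == vid])
      if (rec$status == "unchanged") next
      pre <- sum(g[v, ] != tr[v, ], na.rm = TRUE)
      post <- sum(rec$calls != tr[v, ], na.rm = TRUE)
      expect_lte(post, pre)
      expect_true(all(diff(rec$model$theta_mean[rec$model$populated]) > 0))
    }
  }
})
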