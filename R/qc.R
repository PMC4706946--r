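# Sample and variant quality-control cascade (PLINK-equivalent computations
# implemented natively): identity-by-descent relatedness, X-chromosome sex
# check, call-rate filters, Hardy-Weinberg exact test, minor-allele-count and
# duplicate-record filters. Sample QC runs first; variant QC runs on the
# surviving samples.

#' QC thresholds
#'
#' @param sample_call_rate_min Samples below this call rate are excluded.
#' @param variant_call_rate_min Variants below this call rate are excluded
#'   (this also removes completely missing variants).
#' @param hwe_p_min Variants with a Hardy-Weinberg exact-test p-value below
#'   this are excluded (computed on females only for X variants).
#' @param mac_min Variants with minor allele count below this are excluded;
#'   `mac_min = 2` removes both monomorphic variants and singletons.
#' @param pi_hat_max Pairs sharing more than this estimated IBD proportion
#'   lose one member (the default 0.1875 is the midpoint between the
#'   second- and third-degree relative expectations).
#' @param sex_f_female_max,sex_f_male_min X-heterozygosity F bounds for
#'   inferring female / male.
#' @param ibd_min_variants Minimum polymorphic autosomal variants required
#'   before the relatedness screen runs; below it the method-of-moments
#'   PI_HAT is too noisy to separate relatives from unrelateds at the
#'   default threshold, so the screen is skipped with a warning.
#' @param sex_min_x_variants Minimum polymorphic X variants required before
#'   the sex check runs (skipped with a warning below).
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(sample_call_rate_min = 0.99,
                      variant_call_rate_min = 0.95,
                      hwe_p_min = 1e-6,
                      mac_min = 2L,
                      pi_hat_max = 0.1875,
                      sex_f_female_max = 0.2,
                      sex_f_male_min = 0.8,
                      ibd_min_variants = 1000L,
                      sex_min_x_variants = 20L) {
  stopifnot(sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            variant_call_rate_min >= 0, variant_call_rate_min <= 1,
            hwe_p_min >= 0, hwe_p_min <= 1, mac_min >= 0,
            pi_hat_max >= 0, pi_hat_max <= 1,
            sex_f_female_max <= sex_f_male_min)
  structure(as.list(environment()), class = "qc_config")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, all heterozygote
#' counts of the same parity are enumerated, each configuration's probability
#' under random mating is computed (by a numerically stable recurrence from
#' the distribution's mode), and the p-value is the sum of probabilities not
#' exceeding the observed configuration's (with a tiny relative tie
#' tolerance). The p-value lies in (0, 1].
#'
#' @param n_AA,n_AB,n_BB Non-negative genotype counts, total >= 1.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(n_AA, n_AB, n_BB) {
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_AB + n_BB
  if (n < 1) stop("hwe_exact_test requires at least one genotype")
  m <- min(2 * n_AA + n_AB, 2 * n_BB + n_AB)  # minor allele count
  dist <- hwe_het_distribution(n, m)
  p_obs <- dist$prob[match(n_AB, dist$n_het)]
  sum(dist$prob[dist$prob <= p_obs * (1 + 1e-7)])
}

# Probability distribution of the heterozygote count given n genotypes and
# minor allele count m, via recurrence from the (near-)modal configuration.
hwe_het_distribution <- function(n, m) {
  if (m == 0) return(list(n_het = 0L, prob = 1))
  hets <- seq.int(m %% 2L, m, by = 2L)
  # start near the mode of the conditional distribution
  mid <- round(m * (2 * n - m) / (2 * n))
  if (mid %% 2L != m %% 2L) mid <- mid + 1L
  mid <- max(min(mid, m), m %% 2L)
  prob <- numeric(length(hets))
  i_mid <- match(mid, hets)
  prob[i_mid] <- 1
  # downward: P(h - 2) = P(h) * h (h - 1) / (4 (hom_r + 1)(hom_c + 1))
  if (i_mid > 1L) {
    for (i in seq(i_mid, 2L)) {
      h <- hets[i]
      hom_r <- (m - h) / 2
      hom_c <- n - h - hom_r
      prob[i - 1L] <- prob[i] * h * (h - 1) /
        (4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  # upward: P(h + 2) = P(h) * 4 hom_r hom_c / ((h + 2)(h + 1))
  if (i_mid < length(hets)) {
    for (i in seq(i_mid, length(hets) - 1L)) {
      h <- hets[i]
      hom_r <- (m - h) / 2
      hom_c <- n - h - hom_r
      prob[i + 1L] <- prob[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  }
  list(n_het = hets, prob = prob / sum(prob))
}

#' Method-of-moments identity-by-descent estimation
#'
#' Estimates per-pair IBD sharing probabilities (Z0, Z1, Z2) from
#' identity-by-state counts using sample allele frequencies, then
#' `PI_HAT = Z2 + Z1/2`. Z estimates are clipped to `[0, 1]` and
#' renormalized. Monomorphic and missing-frequency variants are dropped; a
#' warning is issued below 100 usable variants.
#'
#' @param genotypes A `genotype_matrix` (dosage coding) of autosomal
#'   variants.
#' @param pairs Optional two-column matrix/data frame of sample ids or
#'   indices; default all pairs.
#' @return Data frame with `id1`, `id2`, `Z0`, `Z1`, `Z2`, `PI_HAT`,
#'   `n_variants`.
#' @export
estimate_ibd <- function(genotypes, pairs = NULL) {
  g <- unclass_geno(genotypes)
  sids <- colnames(g) %||% as.character(seq_len(ncol(g)))
  p <- rowMeans(g, na.rm = TRUE) / 2
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("IBD is undefined on monomorphic-only input")
  if (sum(use) < 100L) {
    warning("fewer than 100 polymorphic variants; IBD estimates are noisy")
  }
  g <- g[use, , drop = FALSE]
  p <- p[use]
  q <- 1 - p
  # per-variant conditional IBS probabilities given IBD state
  p0_0 <- 2 * p^2 * q^2
  p1_0 <- 4 * p^3 * q + 4 * p * q^3
  p2_0 <- p^4 + q^4 + 4 * p^2 * q^2
  p1_1 <- 2 * p * q
  p2_1 <- p^2 + q^2

  if (is.null(pairs)) {
    idx <- utils::combn(length(sids), 2)
    pairs <- cbind(idx[1, ], idx[2, ])
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) {
      pairs <- cbind(match(pairs[, 1], sids), match(pairs[, 2], sids))
    }
  }
  res <- apply(pairs, 1L, function(pr) {
    a <- g[, pr[1]]; b <- g[, pr[2]]
    ok <- !is.na(a) & !is.na(b)
    ibs <- 2L - abs(a[ok] - b[ok])
    n0 <- sum(ibs == 0L); n1 <- sum(ibs == 1L); n2 <- sum(ibs == 2L)
    s0_0 <- sum(p0_0[ok]); s1_0 <- sum(p1_0[ok]); s2_0 <- sum(p2_0[ok])
    s1_1 <- sum(p1_1[ok]); s2_1 <- sum(p2_1[ok])
    z0 <- n0 / s0_0
    z1 <- (n1 - z0 * s1_0) / s1_1
    z2 <- (n2 - z0 * s2_0 - z1 * s2_1) / sum(ok)
    z <- clip(c(z0, z1, z2), 0, 1)
    if (sum(z) == 0) z <- c(1, 0, 0)
    z <- z / sum(z)
    c(z, z[3] + z[2] / 2, sum(ok))
  })
  data.frame(id1 = sids[pairs[, 1]], id2 = sids[pairs[, 2]],
             Z0 = res[1, ], Z1 = res[2, ], Z2 = res[3, ],
             PI_HAT = res[4, ], n_variants = as.integer(res[5, ]),
             stringsAsFactors = FALSE)
}

#' X-chromosome sex check
#'
#' Per-sample X heterozygosity statistic `F = 1 - O(het)/E(het)` over
#' polymorphic X variants, where `O(het)` is the sample's observed
#' heterozygote rate and `E(het)` the Hardy-Weinberg expectation from the
#' cohort allele frequencies of the same variants. Samples with
#' `F < sex_f_female_max` are inferred female, `F > sex_f_male_min` male,
#' otherwise unknown. Status is `"fail"` only when a definite inference
#' contradicts the declared sex; samples without a declared sex are skipped
#' with a warning record.
#'
#' @param x_genotypes A `genotype_matrix` of X-chromosome variants.
#' @param declared Character vector (`"M"`/`"F"`, NA allowed) per sample.
#' @param config A [qc_config()].
#' @return Data frame with `sample_id`, `F`, `inferred`, `declared`,
#'   `status`.
#' @export
check_sex <- function(x_genotypes, declared, config = qc_config()) {
  g <- unclass_geno(x_genotypes)
  sids <- colnames(g) %||% as.character(seq_len(ncol(g)))
  stopifnot(length(declared) == ncol(g))
  p <- rowMeans(g, na.rm = TRUE) / 2
  use <- !is.na(p) & p > 0 & p < 1
  if (!any(use)) stop("sex check requires at least one polymorphic X variant")
  g <- g[use, , drop = FALSE]
  e_het <- 2 * p[use] * (1 - p[use])
  f <- vapply(seq_len(ncol(g)), function(s) {
    ok <- !is.na(g[, s])
    if (!any(ok)) return(NA_real_)
    1 - mean(g[ok, s] == 1L) / mean(e_het[ok])
  }, numeric(1))
  inferred <- ifelse(is.na(f), "unknown",
               ifelse(f < config$sex_f_female_max, "F",
               ifelse(f > config$sex_f_male_min, "M", "unknown")))
  status <- ifelse(is.na(declared), "skipped",
             ifelse(inferred == "unknown", "unknown",
             ifelse(inferred == declared, "ok", "fail")))
  if (any(is.na(declared))) {
    warning(sum(is.na(declared)), " sample(s) lack a declared sex; skipped")
  }
  data.frame(sample_id = sids, F = f, inferred = inferred,
             declared = declared, status = status, stringsAsFactors = FALSE)
}

#' Sample-level QC
#'
#' Applies, in order: relatedness exclusion (one member of each pair with
#' `PI_HAT` above the threshold is dropped -- the lower-call-rate member),
#' the X-chromosome sex check, and the sample call-rate filter. Each sample
#' records the first reason it fails.
#'
#' @param genotypes Autosomal `genotype_matrix` (dosage coding).
#' @param x_genotypes X-chromosome `genotype_matrix` (or NULL to skip the sex
#'   check).
#' @param declared_sex Character vector per sample.
#' @param config A [qc_config()].
#' @return Data frame with `sample_id`, `reason` (one of `relatedness`,
#'   `sex_mismatch`, `low_call_rate`); attribute `sex_table` holds the full
#'   sex-check table.
#' @export
qc_samples <- function(genotypes, x_genotypes = NULL, declared_sex = NULL,
                       config = qc_config()) {
  g <- unclass_geno(genotypes)
  sids <- colnames(g) %||% as.character(seq_len(ncol(g)))
  call_rate <- colMeans(!is.na(g))
  excluded <- character(0); reason <- character(0)

  p <- rowMeans(g, na.rm = TRUE) / 2
  n_poly <- sum(!is.na(p) & p > 0 & p < 1)
  ibd <- NULL
  if (n_poly >= config$ibd_min_variants) {
    ibd <- tryCatch(estimate_ibd(genotypes), error = function(e) NULL)
  } else {
    warning("relatedness screen skipped: ", n_poly,
            " polymorphic autosomal variants (need ",
            config$ibd_min_variants, " for a stable PI_HAT)")
  }
  if (!is.null(ibd)) {
    flagged <- ibd[ibd$PI_HAT > config$pi_hat_max, , drop = FALSE]
    flagged <- flagged[order(-flagged$PI_HAT), , drop = FALSE]
    for (i in seq_len(nrow(flagged))) {
      a <- flagged$id1[i]; b <- flagged$id2[i]
      if (a %in% excluded || b %in% excluded) next
      drop <- if (call_rate[match(a, sids)] <= call_rate[match(b, sids)])
        a else b
      excluded <- c(excluded, drop); reason <- c(reason, "relatedness")
    }
  }

  sex_table <- NULL
  if (!is.null(x_genotypes) && !is.null(declared_sex)) {
    alive <- setdiff(sids, excluded)
    xs <- unclass_geno(x_genotypes)[, match(alive, sids), drop = FALSE]
    px <- rowMeans(xs, na.rm = TRUE) / 2
    n_poly_x <- sum(!is.na(px) & px > 0 & px < 1)
    st <- if (n_poly_x >= config$sex_min_x_variants) {
      tryCatch(
        check_sex(new_genotype_matrix(xs), declared_sex[match(alive, sids)],
                  config),
        error = function(e) NULL)
    } else {
      warning("sex check skipped: ", n_poly_x,
              " polymorphic X variants (need ",
              config$sex_min_x_variants, ")")
      NULL
    }
    if (!is.null(st)) {
      sex_table <- st
      bad <- st$sample_id[st$status == "fail"]
      excluded <- c(excluded, bad)
      reason <- c(reason, rep("sex_mismatch", length(bad)))
    }
  }

  alive <- setdiff(sids, excluded)
  low <- alive[call_rate[match(alive, sids)] < config$sample_call_rate_min]
  excluded <- c(excluded, low)
  reason <- c(reason, rep("low_call_rate", length(low)))

  out <- data.frame(sample_id = excluded, reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "sex_table") <- sex_table
  out
}

#' Variant-level QC
#'
#' Applies, in order: call-rate (< `variant_call_rate_min`, which also
#' removes completely missing variants), Hardy-Weinberg exact test
#' (p < `hwe_p_min`; on X variants the test uses females only and is skipped
#' when no sexes are supplied), minor-allele-count (`mac = 0` is reported as
#' `monomorphic`, `0 < mac < mac_min` as `low_mac`), and duplicate records at
#' the same chromosome/position with the same allele set (the
#' higher-call-rate record is kept; ties keep the first by position then
#' id). Each variant records the first reason it fails.
#'
#' @param genotypes A `genotype_matrix` (dosage coding).
#' @param variant_meta Data frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` aligned to the rows.
#' @param config A [qc_config()].
#' @param declared_sex Optional per-sample sexes, used for female-only HWE on
#'   X variants.
#' @return Data frame with `variant_id`, `reason` (one of `low_call_rate`,
#'   `hwe`, `monomorphic`, `low_mac`, `duplicate`).
#' @export
qc_variants <- function(genotypes, variant_meta, config = qc_config(),
                        declared_sex = NULL) {
  g <- unclass_geno(genotypes)
  vids <- variant_meta$variant_id
  stopifnot(nrow(g) == length(vids))
  excluded <- character(0); reason <- character(0)
  fail <- function(ids, why) {
    new <- setdiff(ids, excluded)
    excluded <<- c(excluded, new)
    reason <<- c(reason, rep(why, length(new)))
  }

  call_rate <- rowMeans(!is.na(g))
  fail(vids[call_rate < config$variant_call_rate_min], "low_call_rate")

  is_x <- variant_meta$chrom %in% c("X", "23", "chrX")
  for (v in seq_along(vids)) {
    if (vids[v] %in% excluded) next
    gv <- g[v, ]
    if (is_x[v]) {
      if (is.null(declared_sex)) next
      gv <- gv[declared_sex == "F" & !is.na(declared_sex)]
    }
    cnt <- c(sum(gv == 0L, na.rm = TRUE), sum(gv == 1L, na.rm = TRUE),
             sum(gv == 2L, na.rm = TRUE))
    if (sum(cnt) == 0) next
    if (hwe_exact_test(cnt[1], cnt[2], cnt[3]) < config$hwe_p_min) {
      fail(vids[v], "hwe")
    }
  }

  for (v in seq_along(vids)) {
    if (vids[v] %in% excluded) next
    cnt <- c(sum(g[v, ] == 0L, na.rm = TRUE), sum(g[v, ] == 1L, na.rm = TRUE),
             sum(g[v, ] == 2L, na.rm = TRUE))
    if (sum(cnt) == 0) next
    mac <- maf_mac(cnt[1], cnt[2], cnt[3])$mac
    if (mac < config$mac_min) {
      fail(vids[v], if (mac == 0L) "monomorphic" else "low_mac")
    }
  }

  alive <- !(vids %in% excluded)
  key <- paste(variant_meta$chrom, variant_meta$pos,
               pmin(variant_meta$ref, variant_meta$alt),
               pmax(variant_meta$ref, variant_meta$alt))
  for (k in unique(key[alive][duplicated(key[alive])])) {
    members <- which(key == k & alive)
    o <- order(-call_rate[members], variant_meta$pos[members],
               vids[members])
    fail(vids[members[o[-1]]], "duplicate")
  }

  data.frame(variant_id = excluded, reason = reason,
             stringsAsFactors = FALSE)
}

#' Run the full QC cascade
#'
#' Sample QC first (relatedness, sex check, call rate), then variant QC on
#' the surviving samples (call rate, HWE, MAC, duplicates).
#'
#' @param genotypes A `genotype_matrix` over all variants.
#' @param variant_meta Data frame aligned to the rows (needs `chrom` for the
#'   X/autosome split).
#' @param declared_sex Per-sample sexes.
#' @param config A [qc_config()].
#' @return An object of class `qc_report`: excluded samples/variants with
#'   reasons, per-reason counts, input and surviving dimensions, and the
#'   surviving `genotype_matrix`.
#' @export
run_qc <- function(genotypes, variant_meta, declared_sex = NULL,
                   config = qc_config()) {
  g <- unclass_geno(genotypes)
  is_x <- variant_meta$chrom %in% c("X", "23", "chrX")
  auto <- new_genotype_matrix(g[!is_x, , drop = FALSE])
  xg <- if (any(is_x)) new_genotype_matrix(g[is_x, , drop = FALSE]) else NULL

  samp_ex <- qc_samples(auto, xg, declared_sex, config)
  keep_s <- !(colnames(g) %in% samp_ex$sample_id)
  g2 <- new_genotype_matrix(g[, keep_s, drop = FALSE])
  var_ex <- qc_variants(g2, variant_meta, config,
                        declared_sex = declared_sex[keep_s])
  keep_v <- !(variant_meta$variant_id %in% var_ex$variant_id)

  structure(list(
    samples_excluded = samp_ex,
    variants_excluded = var_ex,
    sample_reason_counts = table(samp_ex$reason),
    variant_reason_counts = table(var_ex$reason),
    dim_before = dim(g),
    dim_after = c(sum(keep_v), sum(keep_s)),
    survivors = new_genotype_matrix(g[keep_v, keep_s, drop = FALSE]),
    surviving_variants = variant_meta$variant_id[keep_v],
    surviving_samples = colnames(g)[keep_s],
    config = config), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$dim_before[1], "x", x$dim_before[2], "->",
      x$dim_after[1], "x", x$dim_after[2], "(variants x samples)\n")
  if (nrow(x$samples_excluded)) {
    cat("  samples excluded:",
        paste(names(x$sample_reason_counts), x$sample_reason_counts,
              sep = "=", collapse = ", "), "\n")
  }
  if (nrow(x$variants_excluded)) {
    cat("  variants excluded:",
        paste(names(x$variant_reason_counts), x$variant_reason_counts,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
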