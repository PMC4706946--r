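# Shared fixtures and small oracles, built in code at test time.

clip_unit <- function(x) pmin(pmax(x, 0), 1)

# raw dosage matrix from a genotype_matrix
dose <- function(g) {
  attr(g, "score") <- NULL
  unclass(g)
}

# concordance among pairs called on both sides
called_concordance <- function(calls, truth) {
  a <- dose(calls); b <- dose(truth)
  ok <- !is.na(a) & !is.na(b)
  mean(a[ok] == b[ok])
}

# a clean common-variant spectrum (all polymorphic, well above rare)
common_spectrum <- function() data.frame(lo = 0.05, hi = 0.5, prop = 1)

# independent Hardy-Weinberg exact-test oracle: direct log-factorial
# enumeration of every heterozygote configuration
hwe_oracle_distribution <- function(n, m) {
  if (m == 0) return(list(n_het = 0L, prob = 1))
  hets <- seq.int(m %% 2L, m, by = 2L)
  lp <- vapply(hets, function(h) {
    hom_r <- (m - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) - lgamma(h + 1) +
      h * log(2) + lgamma(m + 1) + lgamma(2 * n - m + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(lp - max(lp))
  list(n_het = hets, prob = p / sum(p))
}

hwe_oracle <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  m <- min(2 * n_AA + n_AB, 2 * n_BB + n_AB)
  d <- hwe_oracle_distribution(n, m)
  po <- d$prob[match(n_AB, d$n_het)]
  sum(d$prob[d$prob <= po * (1 + 1e-7)])
}

# A genotype fixture with constructed QC failures: one duplicate sample
# pair, one sex mismatch, three low-call-rate samples, and planted variants
# failing HWE (2), MAC (2 singletons, 1 monomorphic), call rate (1) and the
# duplicate-position filter (1).
qc_fixture <- function() {
  cfg <- sim_config(n_samples = 40, n_variants = 2000,
                    x_chrom_fraction = 0.05,
                    maf_spectrum = data.frame(lo = 0.2, hi = 0.5, prop = 1),
                    dup_pairs = 1, seed = 107)
  b <- simulate_dataset(cfg)
  g <- dose(b$truth)
  sm <- b$sample_meta
  sex <- sm$sex
  plain <- which(sm$rel_type == "none" &
                   !(sm$sample_id %in% sm$rel_partner))
  # declared-sex flip
  flip <- plain[1]
  sex[flip] <- ifelse(sex[flip] == "M", "F", "M")
  # three samples at 98% call rate
  set.seed(1)
  auto_rows <- which(b$variant_meta$chrom != "X")
  low_cr <- plain[2:4]
  for (s in low_cr) {
    g[sample(auto_rows, ceiling(0.02 * nrow(g))), s] <- NA
  }
  survivors <- setdiff(seq_len(nrow(sm)), c(flip, low_cr, 1L, 2L))
  # planted variant rows over all 40 samples
  hwe_row <- rep(1L, 40)
  hw_ok <- rep(c(0L, 1L, 1L, 2L), 10)   # HWE-consistent common pattern
  single <- rep(0L, 40); single[survivors[5]] <- 1L
  lowcr_row <- hw_ok; lowcr_row[survivors[1:4]] <- NA
  dup_b <- hw_ok; dup_b[survivors[6]] <- NA
  extra <- rbind(hwe1 = hwe_row, hwe2 = hwe_row,
                 single1 = single, single2 = single,
                 mono1 = rep(0L, 40),
                 lowcr1 = lowcr_row,
                 dupA = hw_ok, dupB = dup_b)
  colnames(extra) <- colnames(g)
  extra_meta <- data.frame(
    variant_id = rownames(extra), chrom = "2",
    pos = c(9e7 + 1:6, 9.5e7, 9.5e7), ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  list(genotypes = new_genotype_matrix(rbind(g, extra)),
       variant_meta = rbind(b$variant_meta[, names(extra_meta)],
                            extra_meta),
       sex = sex)
}

# metrics row with every field nominal (no rule should fire on it)
nominal_metrics_row <- function(variant_id = "v1", ...) {
  row <- data.frame(
    variant_id = variant_id, call_freq = 1.0, cluster_sep = 0.8,
    freq_AA = 0.25, freq_AB = 0.5, freq_BB = 0.25,
    ab_r_mean = 1.0, het_excess = 0.0,
    t_mean_AA = 0.1, t_dev_AA = 0.02, t_mean_AB = 0.5, t_dev_AB = 0.02,
    t_mean_BB = 0.9, t_dev_BB = 0.02,
    maf = 0.3, mac = 60L, n_AA = 25L, n_AB = 50L, n_BB = 25L, n_NC = 0L,
    n_called = 100L, stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) row[[nm]] <- mods[[nm]]
  row
}
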