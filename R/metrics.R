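# GenomeStudio-style per-variant SNP statistics.
#
# The cluster-separation and heterozygote-excess formulas used by array
# software are proprietary; the formulas here are documented surrogates
# calibrated so the standard flagging thresholds (cluster separation 0.4,
# heterozygote excess 0.1 / -0.9) are meaningful on simulated data.
# Frequencies are computed over CALLED samples only; equality-against-constant
# rules are evaluated on the integer counts, never on floating-point
# frequencies.

#' Heterozygote-excess statistic
#'
#' With `p` the allele frequency from the counts, `e = 2p(1-p)` the expected
#' and `o = n_AB / n_called` the observed heterozygote frequency, returns
#' `(o - e) / (1 - e)` when `o >= e` and `(o - e) / e` otherwise, so the
#' statistic is bounded in `[-1, 1]` (0 when both `e` and `o` are 0, i.e.
#' monomorphic).
#'
#' @param n_AA,n_AB,n_BB Genotype counts (at least one call in total).
#' @return Numeric in `[-1, 1]`.
#' @export
het_excess <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  if (any(c(n_AA, n_AB, n_BB) < 0)) stop("genotype counts must be >= 0")
  if (n < 1) stop("het_excess requires at least one called sample")
  p <- (2 * n_AA + n_AB) / (2 * n)
  e <- 2 * p * (1 - p)
  o <- n_AB / n
  if (e == 0) return(if (o == 0) 0 else 1)
  if (o >= e) (o - e) / (1 - e) else (o - e) / e
}

#' Cluster-separation score
#'
#' For each adjacent pair of populated clusters with theta means
#' `mu1 < mu2` and deviations `s1, s2`, the pair's separation is
#' `dmu / (dmu + 4 (s1 + s2))`; the variant's score is the minimum over
#' adjacent pairs, or 1 when at most one cluster is populated. The score is
#' strictly increasing in the gap and strictly decreasing in either
#' deviation, and lies in `[0, 1]`.
#'
#' @param model A `cluster_model`.
#' @return Numeric score in `[0, 1]`.
#' @export
cluster_separation <- function(model) {
  pop <- which(model$populated)
  if (length(pop) <= 1L) return(1.0)
  seps <- vapply(seq_len(length(pop) - 1L), function(i) {
    g1 <- pop[i]; g2 <- pop[i + 1L]
    dmu <- model$theta_mean[g2] - model$theta_mean[g1]
    dmu / (dmu + 4 * (model$theta_dev[g1] + model$theta_dev[g2]))
  }, numeric(1))
  min(seps)
}

#' Minor allele frequency and count from genotype counts
#'
#' Allele counts `a = 2 n_AA + n_AB`, `b = 2 n_BB + n_AB`;
#' `mac = min(a, b)`, `maf = mac / (a + b)`.
#'
#' @param n_AA,n_AB,n_BB Genotype counts (at least one called sample).
#' @return List with `maf` and integer `mac`.
#' @export
maf_mac <- function(n_AA, n_AB, n_BB) {
  if (n_AA + n_AB + n_BB < 1) stop("maf_mac requires at least one call")
  a <- 2 * n_AA + n_AB
  b <- 2 * n_BB + n_AB
  list(maf = min(a, b) / (a + b), mac = as.integer(min(a, b)))
}

#' Compute the per-variant statistic vector consumed by the flagging rules
#'
#' Call frequency, cluster separation, per-class genotype frequencies, mean R
#' of AB-called samples, heterozygote excess, per-class theta mean/deviation
#' of the *called* samples, MAF/MAC and the raw counts. Fields undefined for
#' classes with no calls are `NA` (absent), never zero. Theta deviations need
#' at least two calls in the class.
#'
#' @param calls Integer dosage vector (NA = no-call) for one variant.
#' @param theta,r The variant's intensities.
#' @param model The variant's `cluster_model`.
#' @return Named list of metrics.
#' @export
compute_variant_metrics <- function(calls, theta, r, model) {
  n_AA <- sum(calls == 0L, na.rm = TRUE)
  n_AB <- sum(calls == 1L, na.rm = TRUE)
  n_BB <- sum(calls == 2L, na.rm = TRUE)
  n_NC <- sum(is.na(calls))
  n_called <- n_AA + n_AB + n_BB
  n_total <- n_called + n_NC
  out <- list(call_freq = if (n_total > 0) n_called / n_total else 0,
              cluster_sep = cluster_separation(model),
              freq_AA = NA_real_, freq_AB = NA_real_, freq_BB = NA_real_,
              ab_r_mean = NA_real_, het_excess = NA_real_,
              t_mean_AA = NA_real_, t_dev_AA = NA_real_,
              t_mean_AB = NA_real_, t_dev_AB = NA_real_,
              t_mean_BB = NA_real_, t_dev_BB = NA_real_,
              maf = NA_real_, mac = NA_integer_,
              n_AA = n_AA, n_AB = n_AB, n_BB = n_BB, n_NC = n_NC,
              n_called = n_called)
  if (n_called == 0L) return(out)
  out$freq_AA <- n_AA / n_called
  out$freq_AB <- n_AB / n_called
  out$freq_BB <- n_BB / n_called
  out$het_excess <- het_excess(n_AA, n_AB, n_BB)
  mm <- maf_mac(n_AA, n_AB, n_BB)
  out$maf <- mm$maf; out$mac <- mm$mac
  for (g in 0:2) {
    idx <- which(!is.na(calls) & calls == g)
    if (length(idx)) {
      cls <- GENO_CLASSES[g + 1L]
      out[[paste0("t_mean_", cls)]] <- mean(theta[idx])
      if (length(idx) >= 2L) {
        out[[paste0("t_dev_", cls)]] <- stats::sd(theta[idx])
      }
    }
  }
  if (n_AB > 0L) out$ab_r_mean <- mean(r[!is.na(calls) & calls == 1L])
  out
}

#' Metrics table for all variants of a called data set
#'
#' @param genotypes A `genotype_matrix`.
#' @param intensities The matching `intensity_matrix`.
#' @param models The `cluster_model_set` used for calling.
#' @return Data frame, one row per variant, first column `variant_id`,
#'   followed by every [compute_variant_metrics()] field.
#' @export
variant_metrics_table <- function(genotypes, intensities, models) {
  vids <- rownames(unclass_geno(genotypes))
  rows <- lapply(seq_along(vids), function(v) {
    m <- compute_variant_metrics(unclass_geno(genotypes)[v, ],
                                 intensities$theta[v, ],
                                 intensities$r[v, ],
                                 models$models[[vids[v]]])
    as.data.frame(m, stringsAsFactors = FALSE)
  })
  cbind(data.frame(variant_id = vids, stringsAsFactors = FALSE),
        do.call(rbind, rows))
}
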