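# Synthetic exome-array intensity data with planted clustering pathologies.
#
# Generation happens directly in normalized polar coordinates: theta in [0,1]
# is the allelic angle (0 = pure A signal, 1 = pure B signal) and R >= 0 is the
# total normalized intensity. No raw two-channel fluorescence is simulated.

#' Default minor-allele-frequency spectrum
#'
#' Interval masses of the MAF spectrum observed on an exome chip in a large
#' East Asian cohort: two thirds of designed variants are monomorphic, and
#' most polymorphic variants are rare. Each row is an interval `(lo, hi]`
#' (the monomorphic row has `lo == hi == 0`) with the proportion of variants
#' falling in it.
#'
#' @return A data frame with columns `lo`, `hi`, `prop`.
#' @export
default_maf_spectrum <- function() {
  data.frame(
    lo   = c(0, 0, 0.001, 0.005, 0.01, 0.05),
    hi   = c(0, 0.001, 0.005, 0.01, 0.05, 0.5),
    prop = c(0.6670, 0.1466, 0.0321, 0.0150, 0.0298, 0.1095)
  )
}

#' Default cluster geometry in (theta, R) space
#'
#' Homozygote clusters sit near the axes (theta 0.10 and 0.90) and the
#' heterozygote cluster at 0.50, each with standard deviation 0.015 on theta.
#' R is lognormal with median 1 and sdlog 0.1. The geometry is chosen so that
#' the default flagging thresholds cleanly discriminate planted-bad variants
#' from clean ones: in particular the theta deviation of a clean cluster must
#' sit clearly below the "T Dev > 0.025" criterion, otherwise sampling noise
#' alone flags half of all clean variants. Every element is configurable.
#'
#' @return A list with `theta_centers` (named AA/AB/BB), `theta_dev`,
#'   `r_meanlog`, `r_sdlog`.
#' @export
default_cluster_geometry <- function() {
  list(
    theta_centers = c(AA = 0.10, AB = 0.50, BB = 0.90),
    theta_dev = c(AA = 0.015, AB = 0.015, BB = 0.015),
    r_meanlog = 0,
    r_sdlog = 0.1
  )
}

#' Simulation configuration
#'
#' @param n_samples Number of samples (>= 2).
#' @param n_variants Number of variants (>= 1).
#' @param maf_spectrum Data frame of `(lo, hi]` MAF intervals with a `prop`
#'   column summing to 1; see [default_maf_spectrum()].
#' @param cluster_geometry See [default_cluster_geometry()].
#' @param x_chrom_fraction Proportion of variants placed on chromosome X.
#' @param dup_pairs Number of planted duplicate sample pairs.
#' @param rel_pairs Number of planted parent-offspring sample pairs.
#' @param error_mode_rates Named proportions of variants receiving each
#'   planted misclassification mode (`ab_misassign`, `low_r_wide_theta`,
#'   `short_boundary`).
#' @param error_params Mode parameters: per ab_misassign variant, a fraction
#'   `ab_frac` of the majority-homozygote samples (or a fixed count `ab_k`,
#'   when given) drifts to an off-center pseudo-heterozygote position;
#'   `ab_offset` the theta offset of that position from the nearest homozygote
#'   anchor; `lowr_fraction`/`lowr_factor` the affected-sample fraction and R
#'   shrink factor for low_r_wide_theta; `theta_widen_sd` the extra theta
#'   noise for affected samples; `dev_shrink` the factor by which a
#'   short_boundary variant's model deviations are shrunk when the cluster
#'   model honours the registry.
#' @param seed Global integer seed; all stochastic steps consume named
#'   substreams derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500L,
                       n_variants = 200L,
                       maf_spectrum = default_maf_spectrum(),
                       cluster_geometry = default_cluster_geometry(),
                       x_chrom_fraction = 0.05,
                       dup_pairs = 0L,
                       rel_pairs = 0L,
                       error_mode_rates = c(ab_misassign = 0,
                                            low_r_wide_theta = 0,
                                            short_boundary = 0),
                       error_params = list(),
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_variants = as.integer(n_variants),
    maf_spectrum = maf_spectrum,
    cluster_geometry = cluster_geometry,
    x_chrom_fraction = x_chrom_fraction,
    dup_pairs = as.integer(dup_pairs),
    rel_pairs = as.integer(rel_pairs),
    error_mode_rates = error_mode_rates,
    error_params = utils::modifyList(list(
      ab_frac = 0.02, ab_offset = 0.18, ab_offset_sd = 0.02,
      lowr_fraction = 0.10, lowr_factor = 0.3, theta_widen_sd = 0.15,
      dev_shrink = 0.66
    ), error_params),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  sp <- cfg$maf_spectrum
  if (!is.data.frame(sp) || !all(c("lo", "hi", "prop") %in% names(sp))) {
    stop("maf_spectrum must be a data frame with columns lo, hi, prop")
  }
  if (any(sp$prop < 0)) stop("maf_spectrum proportions must be non-negative")
  if (abs(sum(sp$prop) - 1) > 1e-9) {
    stop("maf_spectrum proportions must sum to 1 (got ", sum(sp$prop), ")")
  }
  if (any(sp$lo > sp$hi)) stop("maf_spectrum intervals need lo <= hi")
  g <- cfg$cluster_geometry
  tc <- g$theta_centers
  if (!(tc["AA"] < tc["AB"] && tc["AB"] < tc["BB"])) {
    stop("theta centers must be strictly increasing AA < AB < BB")
  }
  if (any(g$theta_dev <= 0)) stop("theta deviations must be positive")
  if (cfg$n_samples < 2L) stop("n_samples must be >= 2")
  if (cfg$n_variants < 1L) stop("n_variants must be >= 1")
  if (cfg$x_chrom_fraction < 0 || cfg$x_chrom_fraction > 1) {
    stop("x_chrom_fraction must lie in [0, 1]")
  }
  rates <- cfg$error_mode_rates
  bad <- setdiff(names(rates), c("ab_misassign", "low_r_wide_theta",
                                 "short_boundary"))
  if (length(bad)) stop("unknown error modes: ", paste(bad, collapse = ", "))
  if (any(rates < 0) || sum(rates) > 1) {
    stop("error_mode_rates must be non-negative and sum to at most 1")
  }
  if (2L * (cfg$dup_pairs + cfg$rel_pairs) > cfg$n_samples) {
    stop("not enough samples for the requested duplicate/relative pairs")
  }
  invisible(cfg)
}

#' Draw per-variant true minor allele frequencies from an interval spectrum
#'
#' Each variant is first assigned a MAF interval with the configured interval
#' masses, then a MAF uniform within the interval. The degenerate monomorphic
#' interval (`lo == hi == 0`) yields MAF exactly 0.
#'
#' @param config A [sim_config()].
#' @param n Number of variants to draw (defaults to `config$n_variants`).
#' @return Numeric vector of true MAFs in `[0, 0.5]`.
#' @export
sample_maf_spectrum <- function(config, n = config$n_variants) {
  validate_sim_config(config)
  sp <- config$maf_spectrum
  with_substream(config$seed, "maf_spectrum", {
    iv <- sample.int(nrow(sp), n, replace = TRUE, prob = sp$prop)
    maf <- stats::runif(n, min = sp$lo[iv], max = sp$hi[iv])
    maf[sp$lo[iv] == sp$hi[iv]] <- sp$lo[iv][sp$lo[iv] == sp$hi[iv]]
    maf
  })
}

#' Simulate a complete intensity bundle
#'
#' Truth genotypes are drawn per variant under Hardy-Weinberg equilibrium at
#' the variant's true MAF (on X, males are hemizygous and represented as
#' homozygous calls whose intensities come from the homozygote clusters).
#' Intensities are drawn per genotype class from the configured geometry.
#' Planted duplicates copy genotypes exactly; planted first-degree relatives
#' are parent-offspring pairs sharing one transmitted allele per variant.
#' Misclassification modes are injected per `error_mode_rates` and recorded in
#' an error registry. The whole bundle is a deterministic function of the
#' configuration, including the seed.
#'
#' Reference and alternate alleles are drawn as non-complementary base pairs,
#' so no simulated site is strand-ambiguous.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_bundle`: list with `intensities`
#'   (class `intensity_matrix`), `truth` (class `genotype_matrix`, no
#'   no-calls), `sample_meta`, `variant_meta`, `error_registry`, `config`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  nS <- config$n_samples; nV <- config$n_variants
  sample_ids <- sprintf("S%04d", seq_len(nS))
  variant_ids <- sprintf("var%05d", seq_len(nV))

  maf <- sample_maf_spectrum(config)

  # variant metadata: chromosome, position, alleles
  variant_meta <- with_substream(config$seed, "variant_meta", {
    n_x <- round(config$x_chrom_fraction * nV)
    chrom <- c(rep("X", n_x), sample(as.character(1:22), nV - n_x,
                                     replace = TRUE))
    chrom <- sample(chrom)  # shuffle X placement
    pos <- sample.int(5e7, nV, replace = TRUE)
    # non-ambiguous ref/alt pairs (never A/T or C/G together)
    pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))
    pick <- sample.int(4L, nV, replace = TRUE)
    swap <- sample(c(TRUE, FALSE), nV, replace = TRUE)
    ref <- ifelse(swap, pairs[pick, 2], pairs[pick, 1])
    alt <- ifelse(swap, pairs[pick, 1], pairs[pick, 2])
    data.frame(variant_id = variant_ids, chrom = chrom, pos = pos,
               ref = ref, alt = alt, true_maf = maf,
               stringsAsFactors = FALSE)
  })

  # sample metadata: sex and planted relationships
  sample_meta <- with_substream(config$seed, "sample_meta", {
    sex <- sample(c("M", "F"), nS, replace = TRUE)
    rel_type <- rep("none", nS)
    rel_partner <- rep(NA_character_, nS)
    idx <- seq_len(2L * (config$dup_pairs + config$rel_pairs))
    k <- 1L
    for (i in seq_len(config$dup_pairs)) {
      a <- idx[2L * k - 1L]; b <- idx[2L * k]
      rel_type[b] <- "dup"; rel_partner[b] <- sample_ids[a]
      sex[b] <- sex[a]
      k <- k + 1L
    }
    for (i in seq_len(config$rel_pairs)) {
      a <- idx[2L * k - 1L]; b <- idx[2L * k]
      rel_type[b] <- "offspring"; rel_partner[b] <- sample_ids[a]
      k <- k + 1L
    }
    data.frame(sample_id = sample_ids, sex = sex, rel_type = rel_type,
               rel_partner = rel_partner, stringsAsFactors = FALSE)
  })

  is_x <- variant_meta$chrom == "X"
  is_male <- sample_meta$sex == "M"

  # truth genotypes: B-allele dosage matrix (0/1/2), HWE at true MAF
  truth <- with_substream(config$seed, "truth_genotypes", {
    g <- matrix(0L, nV, nS, dimnames = list(variant_ids, sample_ids))
    for (v in seq_len(nV)) {
      p <- maf[v]
      if (is_x[v]) {
        d <- integer(nS)
        d[!is_male] <- stats::rbinom(sum(!is_male), 2L, p)
        # hemizygous males: one allele, represented as homozygous dosage
        d[is_male] <- 2L * stats::rbinom(sum(is_male), 1L, p)
        g[v, ] <- d
      } else {
        g[v, ] <- stats::rbinom(nS, 2L, p)
      }
    }
    g
  })

  # planted relationships overwrite the independent draws
  truth <- with_substream(config$seed, "relationships", {
    for (b in which(sample_meta$rel_type == "dup")) {
      a <- match(sample_meta$rel_partner[b], sample_ids)
      truth[, b] <- truth[, a]
    }
    for (b in which(sample_meta$rel_type == "offspring")) {
      a <- match(sample_meta$rel_partner[b], sample_ids)
      # one allele transmitted from the parent, one from the population
      transmitted <- stats::rbinom(nV, 1L, truth[, a] / 2)
      pop <- stats::rbinom(nV, 1L, maf)
      d <- transmitted + pop
      if (any(is_x)) {
        # X transmission: keep hemizygous representation for male offspring
        if (is_male[b]) d[is_x] <- 2L * pop[is_x]
      }
      truth[, b] <- as.integer(d)
    }
    truth
  })

  # intensities per genotype class
  geom <- config$cluster_geometry
  ints <- with_substream(config$seed, "intensities", {
    theta <- matrix(NA_real_, nV, nS, dimnames = list(variant_ids, sample_ids))
    r <- matrix(NA_real_, nV, nS, dimnames = list(variant_ids, sample_ids))
    centers <- geom$theta_centers
    devs <- rep(geom$theta_dev, length.out = 3L)
    for (v in seq_len(nV)) {
      cls <- truth[v, ] + 1L  # 1=AA, 2=AB, 3=BB
      theta[v, ] <- clip(stats::rnorm(nS, centers[cls], devs[cls]), 0, 1)
      r[v, ] <- stats::rlnorm(nS, geom$r_meanlog, geom$r_sdlog)
    }
    list(theta = theta, r = r)
  })
  intensities <- new_intensity_matrix(ints$theta, ints$r)

  # planted misclassification modes
  registry <- data.frame(variant_id = character(0), mode = character(0),
                         samples = character(0), stringsAsFactors = FALSE)
  rates <- config$error_mode_rates
  if (length(rates) && sum(rates) > 0) {
    err <- with_substream(config$seed, "error_modes", {
      modes <- names(rates)
      n_each <- round(rates * nV)
      victims <- sample.int(nV, sum(n_each))
      assign_mode <- rep(modes, n_each)
      out <- list(intensities = intensities, registry = registry)
      for (j in seq_along(victims)) {
        v <- victims[j]
        res <- inject_error_mode(
          variant_intensities = list(theta = out$intensities$theta[v, ],
                                     r = out$intensities$r[v, ]),
          truth_column = truth[v, ],
          mode = assign_mode[j],
          params = config$error_params,
          geometry = geom
        )
        out$intensities$theta[v, ] <- res$theta
        out$intensities$r[v, ] <- res$r
        out$registry <- rbind(out$registry, data.frame(
          variant_id = variant_ids[v], mode = assign_mode[j],
          samples = paste(sample_ids[res$affected], collapse = ","),
          stringsAsFactors = FALSE))
      }
      out
    })
    intensities <- err$intensities
    registry <- err$registry
    registry <- registry[order(registry$variant_id), , drop = FALSE]
    rownames(registry) <- NULL
  }

  truth_gm <- new_genotype_matrix(truth)
  bundle <- list(intensities = intensities, truth = truth_gm,
                 sample_meta = sample_meta, variant_meta = variant_meta,
                 error_registry = registry, config = config)
  class(bundle) <- "sim_bundle"
  bundle
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle:", nrow(x$variant_meta), "variants x",
      nrow(x$sample_meta), "samples\n")
  cat("  X variants:", sum(x$variant_meta$chrom == "X"),
      " monomorphic:", sum(x$variant_meta$true_maf == 0), "\n")
  if (nrow(x$error_registry)) {
    cat("  planted errors:",
        paste(sprintf("%s=%d", names(table(x$error_registry$mode)),
                      table(x$error_registry$mode)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Inject one misclassification mode into a single variant's intensities
#'
#' Three planted pathologies mimic patterns seen on real arrays:
#' \describe{
#'   \item{ab_misassign}{a fraction `ab_frac` of the majority-homozygote
#'     samples (or a fixed count `ab_k`) drifts to a pseudo-cluster
#'     offset from their homozygote anchor toward the heterozygote position
#'     (theta about anchor + `ab_offset`), where the caller mistakes them for
#'     heterozygotes.}
#'   \item{low_r_wide_theta}{a fraction of samples lose signal: their R is
#'     multiplied by `lowr_factor` (< 0.4) and their theta spread is inflated
#'     by `theta_widen_sd`.}
#'   \item{short_boundary}{intensities are untouched, but the registry entry
#'     instructs the model builder to shrink the variant's cluster deviations
#'     by `dev_shrink`, producing an over-tight calling boundary and spurious
#'     no-calls.}
#' }
#'
#' The function consumes the current RNG stream; callers seed it.
#'
#' @param variant_intensities List with numeric vectors `theta` and `r`.
#' @param truth_column Integer dosage vector (0/1/2) for the variant.
#' @param mode One of `"ab_misassign"`, `"low_r_wide_theta"`,
#'   `"short_boundary"`.
#' @param params See [sim_config()] `error_params`.
#' @param geometry Cluster geometry (for anchor positions).
#' @return List with modified `theta`, `r`, and integer indices `affected`.
#' @export
inject_error_mode <- function(variant_intensities, truth_column, mode,
                              params = list(),
                              geometry = default_cluster_geometry()) {
  params <- utils::modifyList(list(
    ab_frac = 0.02, ab_offset = 0.18, ab_offset_sd = 0.02,
    lowr_fraction = 0.10, lowr_factor = 0.3, theta_widen_sd = 0.15,
    dev_shrink = 0.66
  ), params)
  theta <- variant_intensities$theta
  r <- variant_intensities$r
  n <- length(theta)
  affected <- integer(0)
  centers <- geometry$theta_centers

  if (mode == "ab_misassign") {
    hom <- which(truth_column %in% c(0L, 2L) & !is.na(theta))
    # drift samples from the majority homozygote cluster
    n0 <- sum(truth_column[hom] == 0L); n2 <- sum(truth_column[hom] == 2L)
    from <- if (n0 >= n2) 0L else 2L
    pool <- hom[truth_column[hom] == from]
    k <- if (is.null(params$ab_k)) {
      max(2L, round(params$ab_frac * length(pool)))
    } else params$ab_k
    if (k > length(pool)) {
      stop("ab_misassign: k exceeds available homozygote samples")
    }
    k <- min(k, length(pool))
    if (k > 0L) {
      affected <- sort(sample(pool, k))
      anchor <- if (from == 0L) centers["AA"] else centers["BB"]
      dir <- if (from == 0L) 1 else -1
      theta[affected] <- clip(stats::rnorm(
        k, anchor + dir * params$ab_offset, params$ab_offset_sd), 0, 1)
    }
  } else if (mode == "low_r_wide_theta") {
    pool <- which(!is.na(theta))
    k <- max(1L, round(params$lowr_fraction * length(pool)))
    affected <- sort(sample(pool, min(k, length(pool))))
    r[affected] <- r[affected] * params$lowr_factor
    theta[affected] <- clip(theta[affected] +
      stats::rnorm(length(affected), 0, params$theta_widen_sd), 0.001, 0.999)
  } else if (mode == "short_boundary") {
    # no intensity change; the registry drives model-deviation shrinking
    affected <- integer(0)
  } else {
    stop("unknown error mode: ", mode)
  }
  list(theta = theta, r = r, affected = affected)
}

#' Derive a sequencing-truth surrogate with flip errors and off-target sites
#'
#' Emulates sequencing-derived truth genotypes for concordance evaluation:
#' each genotype is independently replaced by one of the two other genotype
#' classes with probability `error_rate`, and a random fraction of sites is
#' marked off-target (to be removed before comparison, as off-target
#' sequencing calls are unreliable).
#'
#' @param truth A `genotype_matrix` (dosage coding) without no-calls.
#' @param error_rate Per-genotype flip probability in `[0, 1)`.
#' @param off_target_fraction Fraction of sites flagged off-target.
#' @param seed Integer seed.
#' @return List with `genotypes` (genotype_matrix) and `off_target`
#'   (character vector of variant ids).
#' @export
simulate_truth_seq <- function(truth, error_rate = 0,
                               off_target_fraction = 0, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate < 1,
            off_target_fraction >= 0, off_target_fraction <= 1)
  g <- unclass_geno(truth)
  out <- with_substream(seed, "truth_seq", {
    flip <- which(stats::runif(length(g)) < error_rate & !is.na(g))
    if (length(flip)) {
      # replace by one of the two other classes, uniformly
      shift <- sample(1:2, length(flip), replace = TRUE)
      g[flip] <- (g[flip] + shift) %% 3L
    }
    n_off <- round(off_target_fraction * nrow(g))
    off <- if (n_off > 0) sort(sample(rownames(g), n_off)) else character(0)
    list(genotypes = new_genotype_matrix(g), off_target = off)
  })
  out
}
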