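# Per-variant cluster-model fitting, genotype calling and reclustering.
#
# The fitter is a deterministic constrained three-component mixture on theta
# (components anchored at configurable prior centers, AA < AB < BB ordering
# enforced, points weighted by R), standing in for the proprietary automated
# clustering of array software. Calling assigns each sample the populated
# cluster with the highest posterior under a per-cluster bivariate normal on
# (theta, R), with Mahalanobis-distance and posterior no-call thresholds.

#' Caller configuration
#'
#' @param prior_centers Anchor theta positions for AA/AB/BB.
#' @param anchor_dev Theta deviation assumed for an empty (anchored)
#'   component during fitting, and for components with too few points.
#' @param min_theta_dev,min_r_dev Floors on estimated deviations.
#' @param min_points Components with fewer members are marked unpopulated.
#' @param d_max No-call rule: maximum Mahalanobis distance to the best
#'   cluster.
#' @param p_min No-call rule: minimum posterior of the best cluster.
#' @param max_iter Maximum classification-EM iterations.
#' @param r_frac Reclustering: points with R below `r_frac` times the
#'   variant's median R are dropped as no-call candidates before refitting.
#' @param trim_sd Reclustering: points more than `trim_sd` deviations from
#'   their fitted component centre are trimmed before the final refit.
#' @param dissolve_frac,anchor_offset_max,dissolve_ratio Reclustering: a
#'   populated component holding less than `dissolve_frac` of the calls,
#'   sitting more than `anchor_offset_max` from its anchor, next to a
#'   populated neighbour at least `dissolve_ratio` times its size, is treated
#'   as a drifted spur and merged into that neighbour (the neighbour's
#'   deviation is widened to cover the absorbed points).
#' @param boundary_widen,nc_widen_threshold Reclustering: if the refit model
#'   still no-calls more than `nc_widen_threshold` of the samples, deviations
#'   are inflated by `boundary_widen` (kept only if it reduces the no-call
#'   rate; at most two rounds).
#' @param cover_frac When absorbing a drifted spur, the receiving cluster's
#'   deviation is widened so absorbed points sit within
#'   `cover_frac * d_max` Mahalanobis units.
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(prior_centers = c(AA = 0.10, AB = 0.50, BB = 0.90),
                          anchor_dev = 0.06,
                          min_theta_dev = 0.01,
                          min_r_dev = 0.02,
                          min_points = 2L,
                          d_max = 4.0,
                          p_min = 0.7,
                          max_iter = 50L,
                          r_frac = 0.4,
                          trim_sd = 3.0,
                          dissolve_frac = 0.10,
                          anchor_offset_max = 0.10,
                          dissolve_ratio = 3,
                          boundary_widen = 1.5,
                          nc_widen_threshold = 0.05,
                          cover_frac = 0.9) {
  stopifnot(prior_centers[1] < prior_centers[2],
            prior_centers[2] < prior_centers[3],
            anchor_dev > 0, d_max > 0, p_min >= 0, p_min <= 1)
  cfg <- as.list(environment())
  names(cfg$prior_centers) <- GENO_CLASSES
  class(cfg) <- "caller_config"
  cfg
}

new_cluster_model <- function(theta_mean, theta_dev, r_mean, r_dev,
                              populated, n, config,
                              provenance = "built-from-data") {
  m <- list(theta_mean = stats::setNames(theta_mean, GENO_CLASSES),
            theta_dev = stats::setNames(theta_dev, GENO_CLASSES),
            r_mean = stats::setNames(r_mean, GENO_CLASSES),
            r_dev = stats::setNames(r_dev, GENO_CLASSES),
            populated = stats::setNames(populated, GENO_CLASSES),
            n = stats::setNames(as.integer(n), GENO_CLASSES),
            d_max = config$d_max, p_min = config$p_min,
            provenance = provenance)
  class(m) <- "cluster_model"
  validate_cluster_model(m)
  m
}

validate_cluster_model <- function(m) {
  pop <- which(m$populated)
  if (length(pop) > 1L) {
    mu <- m$theta_mean[pop]
    if (any(diff(mu) <= 0)) {
      stop("populated cluster theta means must be strictly increasing")
    }
  }
  if (any(m$theta_dev[pop] <= 0) || any(m$r_dev[pop] <= 0)) {
    stop("populated cluster deviations must be positive")
  }
  invisible(m)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model (", x$provenance, "), d_max=", x$d_max,
      ", p_min=", x$p_min, "\n", sep = "")
  df <- data.frame(populated = x$populated, n = x$n,
                   theta_mean = round(x$theta_mean, 4),
                   theta_dev = round(x$theta_dev, 4),
                   r_mean = round(x$r_mean, 4),
                   r_dev = round(x$r_dev, 4))
  print(df)
  invisible(x)
}

#' Fit a per-variant cluster model from intensities
#'
#' Deterministic classification EM on theta with three components anchored at
#' the configured prior centers (so no random initialization): points are
#' assigned to the component with the highest density under uniform class
#' priors (rare genotype classes must stay callable, so component size never
#' down-weights a class), component means are R-weighted, and ordering
#' AA < AB < BB is enforced at every step. Components with fewer than
#' `min_points` members are marked unpopulated. R statistics are computed per
#' assigned component.
#'
#' @param theta,r Numeric vectors of one variant's intensities (NA = missing).
#' @param config A [caller_config()].
#' @param dev_shrink Factor applied to the fitted deviations (used to emulate
#'   over-tight stored cluster boundaries; 1 = no change).
#' @param provenance Provenance tag stored on the model.
#' @return An object of class `cluster_model`.
#' @export
build_cluster_model <- function(theta, r, config = caller_config(),
                                dev_shrink = 1,
                                provenance = "built-from-data") {
  ok <- !is.na(theta) & !is.na(r)
  th <- theta[ok]; rr <- r[ok]
  empty <- new_cluster_model(
    theta_mean = config$prior_centers, theta_dev = rep(config$anchor_dev, 3),
    r_mean = rep(NA_real_, 3), r_dev = rep(NA_real_, 3),
    populated = rep(FALSE, 3), n = rep(0L, 3),
    config = config, provenance = provenance)
  if (length(th) == 0L) return(empty)

  mu <- as.numeric(config$prior_centers)
  sig <- rep(config$anchor_dev, 3)
  anchored <- rep(TRUE, 3)
  assign_prev <- rep(0L, length(th))
  for (iter in seq_len(config$max_iter)) {
    ll <- vapply(1:3, function(g) {
      stats::dnorm(th, mu[g], sig[g], log = TRUE)
    }, numeric(length(th)))
    if (length(th) == 1L) ll <- matrix(ll, nrow = 1L)
    assign <- max.col(ll, ties.method = "first")
    for (g in 1:3) {
      idx <- assign == g
      if (sum(idx) >= 1L) {
        mu[g] <- wmean(th[idx], rr[idx])
        sig[g] <- if (sum(idx) >= 2L) {
          wsd(th[idx], rr[idx], floor = config$min_theta_dev)
        } else config$anchor_dev
        anchored[g] <- FALSE
      } else {
        mu[g] <- as.numeric(config$prior_centers[g])
        sig[g] <- config$anchor_dev
        anchored[g] <- TRUE
      }
    }
    # enforce AA < AB < BB by theta order
    o <- order(mu)
    mu <- mu[o]; sig <- sig[o]; anchored <- anchored[o]
    relabel <- match(seq_len(3L), o)
    assign <- relabel[assign]
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
  }

  n_g <- tabulate(assign, 3L)
  populated <- n_g >= config$min_points & !anchored
  # resolve theta-mean ties so ordering is strict
  for (g in 2:3) if (mu[g] <= mu[g - 1]) mu[g] <- mu[g - 1] + 1e-6
  r_mean <- r_dev <- rep(NA_real_, 3)
  for (g in which(populated)) {
    idx <- assign == g
    r_mean[g] <- mean(rr[idx])
    r_dev[g] <- max(stats::sd(rr[idx]), config$min_r_dev)
    if (is.na(r_dev[g])) r_dev[g] <- config$min_r_dev
  }
  sig[populated] <- pmax(sig[populated] * dev_shrink, 1e-6)
  r_dev[populated] <- pmax(r_dev[populated] * dev_shrink, 1e-9)
  model <- new_cluster_model(mu, sig, r_mean, r_dev, populated, n_g,
                             config, provenance)
  attr(model, "assign") <- stats::setNames(assign, which(ok))
  model
}

#' Fit cluster models for every variant of an intensity matrix
#'
#' @param intensities An `intensity_matrix`.
#' @param config A [caller_config()].
#' @param shrink_variants Character vector of variant ids whose stored model
#'   deviations are shrunk by `dev_shrink` (emulating over-tight cluster
#'   boundaries in a stored cluster file).
#' @param dev_shrink Shrink factor for those variants.
#' @return An object of class `cluster_model_set` (named list of
#'   `cluster_model` plus the shared config).
#' @export
build_cluster_models <- function(intensities, config = caller_config(),
                                 shrink_variants = character(0),
                                 dev_shrink = 0.66) {
  vids <- rownames(intensities$theta)
  models <- lapply(seq_along(vids), function(v) {
    sh <- if (vids[v] %in% shrink_variants) dev_shrink else 1
    m <- build_cluster_model(intensities$theta[v, ], intensities$r[v, ],
                             config, dev_shrink = sh)
    attr(m, "assign") <- NULL
    m
  })
  names(models) <- vids
  structure(list(models = models, config = config),
            class = "cluster_model_set")
}

#' Cluster models for a simulated bundle, honouring its error registry
#'
#' Builds models from the bundle's own intensities; variants registered with
#' the `short_boundary` mode get their deviations shrunk, reproducing the
#' over-tight-boundary pathology.
#'
#' @param bundle A `sim_bundle`.
#' @param config A [caller_config()].
#' @return A `cluster_model_set`.
#' @export
bundle_models <- function(bundle, config = caller_config()) {
  reg <- bundle$error_registry
  sb <- reg$variant_id[reg$mode == "short_boundary"]
  build_cluster_models(bundle$intensities, config,
                       shrink_variants = sb,
                       dev_shrink = bundle$config$error_params$dev_shrink)
}

#' The generating cluster model of a simulation configuration
#'
#' The oracle model: cluster positions and deviations equal to the geometry
#' the intensities were generated from (R treated as normal with the
#' lognormal's median and sdlog as approximate mean and deviation).
#'
#' @param config A [sim_config()].
#' @param variant_ids Variant ids to cover.
#' @param caller_cfg A [caller_config()] supplying the no-call rule.
#' @return A `cluster_model_set` with provenance `"generating"`.
#' @export
generating_models <- function(config, variant_ids,
                              caller_cfg = caller_config()) {
  g <- config$cluster_geometry
  r_mu <- exp(g$r_meanlog)
  one <- new_cluster_model(
    theta_mean = as.numeric(g$theta_centers),
    theta_dev = rep(g$theta_dev, length.out = 3),
    r_mean = rep(r_mu, 3), r_dev = rep(r_mu * g$r_sdlog, 3),
    populated = rep(TRUE, 3), n = rep(NA_integer_, 3),
    config = caller_cfg, provenance = "generating")
  models <- rep(list(one), length(variant_ids))
  names(models) <- variant_ids
  structure(list(models = models, config = caller_cfg),
            class = "cluster_model_set")
}

#' @export
print.cluster_model_set <- function(x, ...) {
  pop <- vapply(x$models, function(m) sum(m$populated), integer(1))
  cat("cluster_model_set:", length(x$models), "variants;",
      "populated clusters:", paste(names(table(pop)), table(pop),
                                   sep = "x", collapse = ", "), "\n")
  invisible(x)
}

# Call one variant: returns list(dosage = integer with NA, score = numeric).
call_variant <- function(theta, r, model) {
  n <- length(theta)
  dosage <- rep(NA_integer_, n)
  score <- rep(NA_real_, n)
  pop <- which(model$populated)
  ok <- which(!is.na(theta) & !is.na(r))
  if (!length(pop) || !length(ok)) return(list(dosage = dosage, score = score))
  z2 <- vapply(pop, function(g) {
    ((theta[ok] - model$theta_mean[g]) / model$theta_dev[g])^2 +
      ((r[ok] - model$r_mean[g]) / model$r_dev[g])^2
  }, numeric(length(ok)))
  z2 <- matrix(z2, nrow = length(ok))
  logdens <- -z2 / 2 - matrix(rep(log(model$theta_dev[pop] *
                                        model$r_dev[pop]), each = length(ok)),
                              nrow = length(ok))
  best <- max.col(logdens, ties.method = "first")
  m <- logdens[cbind(seq_along(ok), best)]
  post <- 1 / rowSums(exp(logdens - m))
  d <- sqrt(z2[cbind(seq_along(ok), best)])
  called <- d <= model$d_max & post >= model$p_min
  dosage[ok[called]] <- pop[best[called]] - 1L
  score[ok] <- post
  list(dosage = dosage, score = score)
}

#' Call genotypes against a cluster-model set
#'
#' Each sample is assigned the populated cluster with the highest posterior
#' under a per-cluster bivariate normal on (theta, R) with uniform class
#' priors; the call is a no-call (NC) when the best cluster's Mahalanobis
#' distance exceeds `d_max`, its posterior falls below `p_min`, or the
#' intensity is missing. Calling is deterministic and idempotent.
#'
#' @param intensities An `intensity_matrix`.
#' @param models A `cluster_model_set` covering all its variants.
#' @return A `genotype_matrix` with per-call confidence scores.
#' @export
call_genotypes <- function(intensities, models) {
  vids <- rownames(intensities$theta)
  missing_models <- setdiff(vids, names(models$models))
  if (length(missing_models)) {
    stop("variants absent from the cluster model: ",
         paste(utils::head(missing_models, 5), collapse = ", "),
         if (length(missing_models) > 5) " ...")
  }
  dosage <- matrix(NA_integer_, nrow(intensities$theta),
                   ncol(intensities$theta),
                   dimnames = dimnames(intensities$theta))
  score <- dosage + NA_real_
  storage.mode(score) <- "double"
  for (v in seq_along(vids)) {
    res <- call_variant(intensities$theta[v, ], intensities$r[v, ],
                        models$models[[vids[v]]])
    dosage[v, ] <- res$dosage
    score[v, ] <- res$score
  }
  new_genotype_matrix(dosage, score)
}

#' @export
predict.cluster_model_set <- function(object, intensities, ...) {
  call_genotypes(intensities, object)
}

#' Deterministic repair of a flagged variant's cluster model
#'
#' A fixed repair pipeline stands in for manual reclustering (no claim of
#' parity with human decisions is made):
#' \enumerate{
#'   \item points with R below `r_frac` times the variant's median R become
#'     no-call candidates and are dropped from the fit (low-intensity
#'     contamination);
#'   \item the mixture is refit and points more than `trim_sd` deviations
#'     from their component centre are trimmed, then refit again (scattered
#'     outliers);
#'   \item small populated components drifted far off their anchor next to a
#'     much larger neighbour are dissolved into that neighbour, whose
#'     deviation is widened to cover the absorbed points (drifted
#'     pseudo-heterozygote spurs);
#'   \item if the refit model still no-calls more than `nc_widen_threshold`
#'     of samples, deviations are inflated by `boundary_widen` when that
#'     reduces the no-call rate (over-tight boundaries).
#' }
#' The repaired model is then re-called and its metrics re-evaluated: if any
#' irreparable-geometry rule (cluster separation, AB frequency, AB R mean,
#' heterozygote excess) still fires, the variant is zeroed; otherwise it is
#' reclustered. If the incoming flags were frequency-only and no geometry
#' rule fires on the current model, nothing is repaired (`unchanged`).
#'
#' @param theta,r One variant's intensity vectors.
#' @param model The variant's current `cluster_model`.
#' @param flags Character vector of rule ids that flagged the variant.
#' @param ruleset The `ruleset` the flags came from (see
#'   [builtin_ruleset()]).
#' @param config A [caller_config()].
#' @return List with `model` (revised `cluster_model`), `status` (one of
#'   `"reclustered"`, `"zeroed"`, `"unchanged"`), `calls`, `score`,
#'   `metrics` (for the revised model).
#' @export
recluster_variant <- function(theta, r, model, flags,
                              ruleset = builtin_ruleset("adjusted"),
                              config = caller_config()) {
  stopifnot(length(flags) >= 1L)
  rule_geom <- vapply(ruleset$rules, function(rl) isTRUE(rl$geometry),
                      logical(1))
  names(rule_geom) <- vapply(ruleset$rules, `[[`, character(1), "id")
  eval_rules <- function(mod, calls) {
    mt <- compute_variant_metrics(calls, theta, r, mod)
    rep <- apply_ruleset(as.data.frame(c(list(variant_id = "v"), mt),
                                       stringsAsFactors = FALSE), ruleset)
    list(metrics = mt, hits = rep$hits$rule_id)
  }

  cur_calls <- call_variant(theta, r, model)
  cur <- eval_rules(model, cur_calls$dosage)
  geom_hits <- intersect(cur$hits, names(rule_geom)[rule_geom])
  flags_geom <- intersect(flags, names(rule_geom)[rule_geom])
  if (!length(flags_geom) && !length(geom_hits)) {
    return(list(model = model, status = "unchanged",
                calls = cur_calls$dosage, score = cur_calls$score,
                metrics = cur$metrics))
  }

  ok <- !is.na(theta) & !is.na(r)
  med_r <- stats::median(r[ok])
  keep <- ok & r >= config$r_frac * med_r

  fit <- build_cluster_model(theta[keep], r[keep], config)
  assign <- attr(fit, "assign")
  # trim theta outliers within their assigned component, then refit
  kept_idx <- which(keep)
  trim_ok <- rep(TRUE, length(kept_idx))
  for (g in which(fit$populated)) {
    members <- which(assign == g)
    z <- abs(theta[kept_idx][members] - fit$theta_mean[g]) / fit$theta_dev[g]
    trim_ok[members[z > config$trim_sd]] <- FALSE
  }
  if (!all(trim_ok)) {
    keep2 <- rep(FALSE, length(theta)); keep2[kept_idx[trim_ok]] <- TRUE
    fit <- build_cluster_model(theta[keep2], r[keep2], config)
    kept_idx <- which(keep2)
    assign <- attr(fit, "assign")
  }

  # dissolve drifted low-mass spurs into their large neighbour
  pop <- which(fit$populated)
  if (length(pop) >= 2L) {
    n_tot <- sum(fit$n[pop])
    for (g in pop) {
      frac <- fit$n[g] / n_tot
      off <- abs(fit$theta_mean[g] - config$prior_centers[g])
      others <- setdiff(which(fit$populated), g)
      if (!length(others)) next
      nb <- others[which.min(abs(fit$theta_mean[others] - fit$theta_mean[g]))]
      if (frac < config$dissolve_frac && off > config$anchor_offset_max &&
          fit$n[nb] >= config$dissolve_ratio * fit$n[g]) {
        members <- c(which(assign == nb), which(assign == g))
        th_m <- theta[kept_idx][members]; r_m <- r[kept_idx][members]
        new_mu <- wmean(th_m, r_m)
        spread <- max(abs(th_m - new_mu)) / (config$cover_frac * config$d_max)
        new_sig <- max(wsd(th_m, r_m, floor = config$min_theta_dev), spread)
        fit$theta_mean[nb] <- new_mu
        fit$theta_dev[nb] <- new_sig
        fit$r_mean[nb] <- mean(r_m)
        fit$r_dev[nb] <- max(stats::sd(r_m), config$min_r_dev)
        fit$n[nb] <- fit$n[nb] + fit$n[g]
        fit$populated[g] <- FALSE
        fit$n[g] <- 0L
        assign[assign == g] <- nb
      }
    }
    # dissolution can only merge, never reorder, but re-check strictness
    validate_cluster_model(fit)
  }
  attr(fit, "assign") <- NULL

  # widen over-tight boundaries while it reduces an excessive no-call rate;
  # the rate is judged on points that passed the low-R mask, since masked
  # points are intended no-calls, not evidence of a tight boundary
  recall <- call_variant(theta, r, fit)
  nc_rate <- mean(is.na(recall$dosage[keep]))
  for (i in 1:2) {
    if (nc_rate <= config$nc_widen_threshold) break
    widened <- fit
    widened$theta_dev[widened$populated] <-
      widened$theta_dev[widened$populated] * config$boundary_widen
    widened$r_dev[widened$populated] <-
      widened$r_dev[widened$populated] * config$boundary_widen
    recall_w <- call_variant(theta, r, widened)
    nc_w <- mean(is.na(recall_w$dosage[keep]))
    if (nc_w < nc_rate) {
      fit <- widened; recall <- recall_w; nc_rate <- nc_w
    } else break
  }

  fin <- eval_rules(fit, recall$dosage)
  zero_hit <- any(vapply(ruleset$rules, function(rl) {
    isTRUE(rl$zeroing) && rl$id %in% fin$hits
  }, logical(1)))
  status <- if (zero_hit) "zeroed" else "reclustered"
  list(model = fit, status = status, calls = recall$dosage,
       score = recall$score, metrics = fin$metrics)
}

#' Plot a variant's intensities and cluster model
#'
#' Scatter of (theta, R) coloured by genotype call, with cluster centres and
#' two-deviation ellipses for populated clusters.
#'
#' @param x A `cluster_model`.
#' @param theta,r The variant's intensities.
#' @param calls Optional dosage vector to colour points by.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cluster_model <- function(x, theta, r, calls = NULL, ...) {
  col <- if (is.null(calls)) rep(1L, length(theta)) else {
    ifelse(is.na(calls), 8L, calls + 2L)
  }
  graphics::plot(theta, r, col = col, pch = 16, xlim = c(0, 1),
                 xlab = "Norm Theta", ylab = "Norm R", ...)
  for (g in which(x$populated)) {
    graphics::points(x$theta_mean[g], x$r_mean[g], pch = 3, cex = 2,
                     col = g + 1L, lwd = 2)
    a <- seq(0, 2 * pi, length.out = 60)
    graphics::lines(x$theta_mean[g] + 2 * x$theta_dev[g] * cos(a),
                    x$r_mean[g] + 2 * x$r_dev[g] * sin(a), col = g + 1L)
  }
  invisible(x)
}
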