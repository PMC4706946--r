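# Concordance between array calls and sequencing-derived truth genotypes,
# plus variant-set comparison between cluster files.
#
# Conventions: genotype pairs where either side is missing/no-call are
# excluded from both numerator and denominator and tallied separately.
# Per-stratum values are mean +/- SD across variants (not pooled pairs).
# MAF strata come from the array cohort; MAC strata from the truth cohort.

#' Intersect array and truth site lists
#'
#' Sites are matched on chromosome and position. Sites whose alleles match in
#' swapped ref/alt orientation are retained with a `flip` flag (truth dosage
#' is mirrored downstream); sites flagged off-target, strand-ambiguous sites
#' (A/T or C/G allele pairs) and allele mismatches are excluded and counted.
#'
#' @param array_meta Data frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param truth_meta Data frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param off_target Character vector of truth variant ids to exclude.
#' @return Data frame with `array_id`, `truth_id`, `flip`; attribute
#'   `excluded` holds named counts (`off_target`, `ambiguous`,
#'   `allele_mismatch`).
#' @export
intersect_sites <- function(array_meta, truth_meta,
                            off_target = character(0)) {
  key_a <- paste(array_meta$chrom, array_meta$pos)
  key_t <- paste(truth_meta$chrom, truth_meta$pos)
  i <- match(key_a, key_t)
  hit <- !is.na(i)
  a <- array_meta[hit, , drop = FALSE]
  t_ <- truth_meta[i[hit], , drop = FALSE]

  ambiguous <- function(ref, alt) {
    (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
      (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
  }
  is_off <- t_$variant_id %in% off_target
  same <- a$ref == t_$ref & a$alt == t_$alt
  swap <- a$ref == t_$alt & a$alt == t_$ref
  amb <- ambiguous(a$ref, a$alt) | ambiguous(t_$ref, t_$alt)
  keep <- !is_off & !amb & (same | swap)
  n_amb <- sum(!is_off & amb)
  if (n_amb > 0) {
    warning(n_amb, " strand-ambiguous site(s) excluded from the intersection")
  }
  out <- data.frame(array_id = a$variant_id[keep],
                    truth_id = t_$variant_id[keep],
                    flip = swap[keep], stringsAsFactors = FALSE)
  attr(out, "excluded") <- c(off_target = sum(is_off),
                             ambiguous = n_amb,
                             allele_mismatch = sum(!is_off & !amb &
                                                     !(same | swap)))
  out
}

# Align array and truth dosage matrices on shared sites/samples; returns
# matrices with truth flipped where the site orientation is swapped.
align_pairs <- function(array_calls, truth_calls, sites) {
  ga <- unclass_geno(array_calls)
  gt <- unclass_geno(truth_calls)
  samples <- intersect(colnames(ga), colnames(gt))
  if (!length(samples)) stop("no shared samples between array and truth")
  ga <- ga[sites$array_id, samples, drop = FALSE]
  gt <- gt[sites$truth_id, samples, drop = FALSE]
  if (any(sites$flip)) gt[sites$flip, ] <- 2L - gt[sites$flip, , drop = FALSE]
  list(array = ga, truth = gt, samples = samples)
}

new_concordance_report <- function(metric, strata, skipped, n_pairs) {
  structure(list(metric = metric, strata = strata, skipped = skipped,
                 n_pairs = n_pairs), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("concordance_report (", x$metric, "), ", x$n_pairs,
      " genotype pairs, ", x$skipped, " variant(s) skipped\n", sep = "")
  s <- x$strata
  s$mean <- round(s$mean, 4); s$sd <- round(s$sd, 4)
  print(s, row.names = FALSE)
  invisible(x)
}

# shared stratified mean +/- SD machinery over per-variant values
stratify_report <- function(metric, values, strata_of, levels, skipped,
                            n_pairs) {
  rows <- lapply(c(levels, "all"), function(st) {
    v <- if (st == "all") values else values[strata_of == st]
    data.frame(stratum = st, n_variants = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else
                 if (length(v) == 1) 0 else NA_real_,
               stringsAsFactors = FALSE)
  })
  new_concordance_report(metric, do.call(rbind, rows), skipped, n_pairs)
}

#' Overall genotype concordance, stratified by array MAF class
#'
#' Per variant, concordance is the fraction of matching genotype pairs among
#' pairs where both sides are called. Variants are stratified by the array
#' cohort's MAF: common (>= 0.05), less common ([0.01, 0.05)), rare
#' (< 0.01), plus all variants.
#'
#' @param array_calls,truth_calls `genotype_matrix` objects (dosage coding),
#'   samples matched by id.
#' @param sites Intersection from [intersect_sites()]; defaults to matching
#'   row names directly with no flips.
#' @return A `concordance_report` (metric `"overall"`).
#' @export
concordance_overall <- function(array_calls, truth_calls, sites = NULL) {
  if (is.null(sites)) {
    shared <- intersect(rownames(unclass_geno(array_calls)),
                        rownames(unclass_geno(truth_calls)))
    sites <- data.frame(array_id = shared, truth_id = shared, flip = FALSE,
                        stringsAsFactors = FALSE)
  }
  al <- align_pairs(array_calls, truth_calls, sites)
  res <- per_variant_concordance(al, restrict = "none")
  # MAF class from the array calls
  maf <- apply(al$array, 1L, function(d) {
    cnt <- c(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
             sum(d == 2L, na.rm = TRUE))
    if (sum(cnt) == 0) return(NA_real_)
    maf_mac(cnt[1], cnt[2], cnt[3])$maf
  })
  cls <- ifelse(maf >= 0.05, "common",
          ifelse(maf >= 0.01, "less_common", "rare"))
  ok <- !is.na(res$conc)
  stratify_report("overall", res$conc[ok], cls[ok],
                  c("common", "less_common", "rare"),
                  skipped = sum(!ok), n_pairs = sum(res$n[ok]))
}

# per-variant agreement with optional restriction of evaluable truth pairs
per_variant_concordance <- function(al, restrict) {
  nv <- nrow(al$array)
  conc <- rep(NA_real_, nv); n <- integer(nv)
  for (v in seq_len(nv)) {
    a <- al$array[v, ]; t_ <- al$truth[v, ]
    ok <- !is.na(a) & !is.na(t_)
    if (restrict == "nonref") ok <- ok & t_ > 0L
    if (restrict == "het") ok <- ok & t_ == 1L
    if (!any(ok)) next
    n[v] <- sum(ok)
    conc[v] <- if (restrict == "het") mean(a[ok] == 1L) else
      mean(a[ok] == t_[ok])
  }
  list(conc = conc, n = n)
}

# truth-cohort MAC per aligned variant
truth_mac <- function(al) {
  apply(al$truth, 1L, function(d) {
    cnt <- c(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
             sum(d == 2L, na.rm = TRUE))
    if (sum(cnt) == 0) return(NA_integer_)
    maf_mac(cnt[1], cnt[2], cnt[3])$mac
  })
}

#' Non-reference concordance on rare variants, stratified by truth MAC
#'
#' Per variant, genotype pairs are restricted to samples whose truth genotype
#' carries at least one non-reference allele; concordance is the fraction of
#' those pairs the array matches. Variants are stratified by the truth
#' cohort's minor allele count within `mac_range` (variants outside the
#' range, or with no evaluable pair, are skipped).
#'
#' @param array_calls,truth_calls `genotype_matrix` objects.
#' @param sites Intersection from [intersect_sites()] (optional, as in
#'   [concordance_overall()]).
#' @param mac_range Inclusive truth-MAC bounds, default `c(2, 5)`.
#' @return A `concordance_report` (metric `"nonref"`).
#' @export
nonref_concordance <- function(array_calls, truth_calls, sites = NULL,
                               mac_range = c(2L, 5L)) {
  mac_stratified(array_calls, truth_calls, sites, mac_range, "nonref")
}

#' Heteroallele accuracy on rare variants, stratified by truth MAC
#'
#' Per variant, among samples whose truth genotype is heterozygous (and whose
#' array call is not a no-call), the fraction called heterozygous by the
#' array. Stratification as in [nonref_concordance()].
#'
#' @inheritParams nonref_concordance
#' @return A `concordance_report` (metric `"het_accuracy"`).
#' @export
het_accuracy <- function(array_calls, truth_calls, sites = NULL,
                         mac_range = c(2L, 5L)) {
  mac_stratified(array_calls, truth_calls, sites, mac_range, "het")
}

mac_stratified <- function(array_calls, truth_calls, sites, mac_range,
                           restrict) {
  if (is.null(sites)) {
    shared <- intersect(rownames(unclass_geno(array_calls)),
                        rownames(unclass_geno(truth_calls)))
    sites <- data.frame(array_id = shared, truth_id = shared, flip = FALSE,
                        stringsAsFactors = FALSE)
  }
  al <- align_pairs(array_calls, truth_calls, sites)
  mac <- truth_mac(al)
  res <- per_variant_concordance(al, restrict = restrict)
  in_range <- !is.na(mac) & mac >= mac_range[1] & mac <= mac_range[2]
  ok <- in_range & !is.na(res$conc)
  levels <- as.character(seq(mac_range[1], mac_range[2]))
  metric <- if (restrict == "het") "het_accuracy" else "nonref"
  stratify_report(metric, res$conc[ok], as.character(mac[ok]), levels,
                  skipped = sum(!ok), n_pairs = sum(res$n[ok]))
}

#' Compare two variant sets (custom vs default cluster file survivors)
#'
#' @param set_a,set_b Character vectors of unique variant ids.
#' @return List with `shared`, `unique_a`, `unique_b` (id vectors) and
#'   `counts` (named integer vector `shared`, `unique_a`, `unique_b`).
#' @export
compare_variant_sets <- function(set_a, set_b) {
  stopifnot(!anyDuplicated(set_a), !anyDuplicated(set_b))
  shared <- intersect(set_a, set_b)
  ua <- setdiff(set_a, set_b)
  ub <- setdiff(set_b, set_a)
  list(shared = shared, unique_a = ua, unique_b = ub,
       counts = c(shared = length(shared), unique_a = length(ua),
                  unique_b = length(ub)))
}
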