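# The flagging engine: clustering-error criteria encoded as data.
#
# Two built-in rulesets implement the published criterion tables: the CHARGE
# consortium guidelines and the adjusted variant tuned for a cohort where
# two-thirds of array variants are monomorphic. The two differ only in the
# four combined frequency/call-rate rows (call-frequency cutoffs relaxed from
# "not 1" to "< 0.99", and the MAF bound of the missing-heterozygote rule
# raised from 0 to 0.0002), so every adjusted flag set is contained in its
# CHARGE counterpart.
#
# Interval rules: the call-frequency band 0.95~0.99 is half-open [lo, hi) so
# that a call frequency of exactly 0.99 falls through to the combined rules;
# T Mean bands are closed [lo, hi]. Equality-against-constant predicates
# (AB Freq = 0, AA Freq = 1, MAF > 0, Call Freq != 1) are evaluated on the
# integer counts.

new_rule <- function(id, label, category, clauses,
                     geometry = TRUE, zeroing = FALSE) {
  list(id = id, label = label, category = category, clauses = clauses,
       geometry = geometry, zeroing = zeroing)
}

cl <- function(field, op, value, value2 = NULL) {
  list(field = field, op = op, value = value, value2 = value2)
}

#' Built-in clustering-error rulesets
#'
#' Returns the 17 rules of the named criterion column. `"charge"` is the
#' CHARGE-consortium guideline set; `"adjusted"` relaxes the four combined
#' frequency rows for cohorts rich in monomorphic variants. Both share the
#' thirteen geometry rows (call-frequency band, cluster separation,
#' AB frequency, AB R mean, heterozygote excess, T Mean / T Dev bands).
#'
#' The AB R Mean row's published table prints no cutoff; the default
#' predicate is `ab_r_mean < ab_r_mean_min` (0.3), configurable.
#'
#' @param name `"charge"` or `"adjusted"`.
#' @param ab_r_mean_min Cutoff for the AB R Mean rule.
#' @return An object of class `ruleset`: list with `name` and `rules`.
#' @export
builtin_ruleset <- function(name = c("charge", "adjusted"),
                            ab_r_mean_min = 0.3) {
  if (!is.character(name) || !name[1] %in% c("charge", "adjusted")) {
    stop("unknown ruleset '", name[1], "'; valid names: charge, adjusted")
  }
  name <- name[1]
  adj <- name == "adjusted"
  ce <- "clustering_error"
  rules <- list(
    new_rule("call_freq_band", "Call Freq 0.95~0.99", ce,
             list(cl("call_freq", "in_co", 0.95, 0.99))),
    new_rule("cluster_sep_low", "Cluster Sep < 0.4", ce,
             list(cl("cluster_sep", "lt", 0.4)), zeroing = TRUE),
    new_rule("ab_freq_high", "AB Freq > 0.6", ce,
             list(cl("freq_AB", "gt", 0.6)), zeroing = TRUE),
    new_rule("ab_r_mean_low", "AB R Mean", ce,
             list(cl("ab_r_mean", "lt", ab_r_mean_min)), zeroing = TRUE),
    new_rule("het_excess_high", "Het Excess > 0.1", ce,
             list(cl("het_excess", "gt", 0.1)), zeroing = TRUE),
    new_rule("het_excess_low", "Het Excess < -0.9", ce,
             list(cl("het_excess", "lt", -0.9)), zeroing = TRUE),
    if (adj) {
      new_rule("maf_low_callfreq", "MAF < 0.0001 & Call Freq < 0.99", ce,
               list(cl("maf", "lt", 1e-4), cl("call_freq", "lt", 0.99)),
               geometry = FALSE)
    } else {
      new_rule("maf_low_callfreq", "MAF < 0.0001 & Call Freq != 1", ce,
               list(cl("maf", "lt", 1e-4), cl("n_NC", "ge", 1L)),
               geometry = FALSE)
    },
    new_rule("aa_t_mean_band", "AA T Mean 0.2~0.3", "aa_cluster_error",
             list(cl("t_mean_AA", "in_cc", 0.2, 0.3))),
    new_rule("aa_t_dev_high", "AA T Dev > 0.025", "aa_cluster_error",
             list(cl("t_dev_AA", "gt", 0.025))),
    if (adj) {
      new_rule("aa_only_callfreq", "AA Freq = 1 & Call Freq < 0.99",
               "aa_cluster_error",
               list(cl("n_AB", "eq", 0L), cl("n_BB", "eq", 0L),
                    cl("n_called", "ge", 1L), cl("call_freq", "lt", 0.99)),
               geometry = FALSE)
    } else {
      new_rule("aa_only_callfreq", "AA Freq = 1 & Call Freq < 1",
               "aa_cluster_error",
               list(cl("n_AB", "eq", 0L), cl("n_BB", "eq", 0L),
                    cl("n_called", "ge", 1L), cl("n_NC", "ge", 1L)),
               geometry = FALSE)
    },
    new_rule("ab_t_mean_low_band", "AB T Mean 0.2~0.3", "ab_cluster_error",
             list(cl("t_mean_AB", "in_cc", 0.2, 0.3))),
    new_rule("ab_t_mean_high_band", "AB T Mean 0.7~0.8", "ab_cluster_error",
             list(cl("t_mean_AB", "in_cc", 0.7, 0.8))),
    new_rule("ab_t_dev_high", "AB T Dev >= 0.07", "ab_cluster_error",
             list(cl("t_dev_AB", "ge", 0.07))),
    if (adj) {
      new_rule("no_het_maf", "AB Freq = 0 & MAF > 0.0002",
               "ab_cluster_error",
               list(cl("n_AB", "eq", 0L), cl("n_called", "ge", 1L),
                    cl("maf", "gt", 2e-4)),
               geometry = FALSE)
    } else {
      new_rule("no_het_maf", "AB Freq = 0 & MAF > 0", "ab_cluster_error",
               list(cl("n_AB", "eq", 0L), cl("n_called", "ge", 1L),
                    cl("mac", "ge", 1L)),
               geometry = FALSE)
    },
    new_rule("bb_t_mean_band", "BB T Mean 0.7~0.8", "bb_cluster_error",
             list(cl("t_mean_BB", "in_cc", 0.7, 0.8))),
    new_rule("bb_t_dev_high", "BB T Dev > 0.025", "bb_cluster_error",
             list(cl("t_dev_BB", "gt", 0.025))),
    if (adj) {
      new_rule("bb_only_callfreq", "BB Freq = 1 & Call Freq < 0.99",
               "bb_cluster_error",
               list(cl("n_AB", "eq", 0L), cl("n_AA", "eq", 0L),
                    cl("n_called", "ge", 1L), cl("call_freq", "lt", 0.99)),
               geometry = FALSE)
    } else {
      new_rule("bb_only_callfreq", "BB Freq = 1 & Call Freq < 1",
               "bb_cluster_error",
               list(cl("n_AB", "eq", 0L), cl("n_AA", "eq", 0L),
                    cl("n_called", "ge", 1L), cl("n_NC", "ge", 1L)),
               geometry = FALSE)
    }
  )
  structure(list(name = name, rules = rules), class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat("ruleset '", x$name, "' with ", length(x$rules), " rules\n", sep = "")
  for (rl in x$rules) {
    cat(sprintf("  %-20s [%s] %s\n", rl$id, rl$category, rl$label))
  }
  invisible(x)
}

eval_clause <- function(x, clause) {
  v <- clause$value
  res <- switch(clause$op,
    lt = x < v, le = x <= v, gt = x > v, ge = x >= v,
    eq = x == v, ne = x != v,
    in_co = x >= v & x < clause$value2,
    in_cc = x >= v & x <= clause$value2,
    stop("unknown comparator: ", clause$op))
  res & !is.na(res)  # absent metric fields never satisfy a predicate
}

#' Apply a ruleset to a metrics table
#'
#' Every rule is evaluated independently on every variant; a variant can be
#' flagged by several rules (counted with redundancy). Absent (`NA`) metric
#' fields make any predicate referencing them false. The result does not
#' depend on rule order.
#'
#' @param metrics Data frame from [variant_metrics_table()] (must contain
#'   `variant_id` and every field a rule references).
#' @param ruleset A `ruleset` from [builtin_ruleset()] or [read_ruleset()].
#' @return An object of class `flag_report`: list with `hits`
#'   (data frame `variant_id`, `rule_id`, `category`), per-rule counts,
#'   per-category counts, `total_redundant`, `n_unique`, `ruleset_name`.
#' @export
apply_ruleset <- function(metrics, ruleset) {
  stopifnot(is.data.frame(metrics), "variant_id" %in% names(metrics))
  hits <- lapply(ruleset$rules, function(rl) {
    flag <- rep(TRUE, nrow(metrics))
    for (clause in rl$clauses) {
      if (!clause$field %in% names(metrics)) {
        stop("metrics table lacks field '", clause$field,
             "' referenced by rule ", rl$id)
      }
      flag <- flag & eval_clause(metrics[[clause$field]], clause)
    }
    if (!any(flag)) return(NULL)
    data.frame(variant_id = metrics$variant_id[flag], rule_id = rl$id,
               category = rl$category, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(variant_id = character(0), rule_id = character(0),
                       category = character(0), stringsAsFactors = FALSE)
  }
  rule_ids <- vapply(ruleset$rules, `[[`, character(1), "id")
  cats <- vapply(ruleset$rules, `[[`, character(1), "category")
  rule_counts <- stats::setNames(
    as.integer(table(factor(hits$rule_id, levels = rule_ids))), rule_ids)
  attr(rule_counts, "category") <- stats::setNames(cats, rule_ids)
  cat_counts <- tapply(rule_counts, cats, sum)
  structure(list(hits = hits, rule_counts = rule_counts,
                 category_counts = cat_counts,
                 total_redundant = sum(rule_counts),
                 n_unique = length(unique(hits$variant_id)),
                 ruleset_name = ruleset$name),
            class = "flag_report")
}

#' @export
print.flag_report <- function(x, ...) {
  cat("flag_report (ruleset '", x$ruleset_name, "'): ",
      x$total_redundant, " flags with redundancy on ",
      x$n_unique, " unique variants\n", sep = "")
  invisible(x)
}

#' Summarize a flag report in the layout of a criterion table
#'
#' Per-rule counts, per-category subtotals, the redundancy-counted grand
#' total (the sum of the per-rule counts, i.e. a variant hit by three rules
#' contributes three) and the unique-variant count.
#'
#' `report` may be a `flag_report`, or a data frame of per-rule counts with
#' columns `rule_id`, `category` and `n` (e.g. counts transcribed from a
#' published criterion table), in which case the same redundancy-sum
#' semantics are applied to the given counts and the unique count is `NA`.
#'
#' @param report A `flag_report` or a per-rule count data frame.
#' @return Data frame with one row per rule plus category-subtotal and total
#'   rows; attributes `total_redundant` and `n_unique`.
#' @export
summarize_flags <- function(report) {
  if (inherits(report, "flag_report")) {
    cats <- names(report$category_counts)
    rc <- report$rule_counts
    per_rule <- data.frame(rule_id = names(rc),
                           category = rep(NA_character_, length(rc)),
                           n = as.integer(rc), stringsAsFactors = FALSE)
    per_rule$category <- as.character(attr(report$rule_counts, "category"))
    n_unique <- report$n_unique
  } else {
    stopifnot(is.data.frame(report),
              all(c("rule_id", "category", "n") %in% names(report)))
    per_rule <- report[, c("rule_id", "category", "n")]
    n_unique <- NA_integer_
  }
  sub <- stats::aggregate(n ~ category, data = per_rule, FUN = sum)
  out <- rbind(
    per_rule,
    data.frame(rule_id = paste0("subtotal_", sub$category),
               category = sub$category, n = sub$n),
    data.frame(rule_id = "total_redundant", category = "all",
               n = sum(per_rule$n)))
  attr(out, "total_redundant") <- sum(per_rule$n)
  attr(out, "n_unique") <- n_unique
  out
}

#' Write / read a ruleset as YAML or JSON
#'
#' Rulesets are data, not code: users can define new criterion columns. The
#' on-disk form mirrors the in-memory structure (`name`, `rules` with `id`,
#' `label`, `category`, `geometry`, `zeroing` and `clauses` of
#' field/op/value).
#'
#' @param ruleset A `ruleset`.
#' @param path Output path; extension `.yaml`/`.yml` or `.json`.
#' @return `read_ruleset` returns a `ruleset`; `write_ruleset` the path,
#'   invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  obj <- list(name = ruleset$name, rules = lapply(ruleset$rules, function(rl) {
    rl$clauses <- lapply(rl$clauses, function(clause) {
      clause[!vapply(clause, is.null, logical(1))]
    })
    rl
  }))
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  rules <- lapply(obj$rules, function(rl) {
    clauses <- lapply(rl$clauses, function(clause) {
      cl(clause$field, clause$op, clause$value, clause$value2)
    })
    new_rule(rl$id, rl$label, rl$category, clauses,
             geometry = isTRUE(rl$geometry), zeroing = isTRUE(rl$zeroing))
  })
  structure(list(name = obj$name, rules = rules), class = "ruleset")
}
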