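# Core containers: intensity and genotype matrices.
#
# Genotypes are stored as B-allele dosage: 0 = AA, 1 = AB, 2 = BB, NA = NC
# (no-call). An optional per-call confidence score matrix rides along as an
# attribute.

#' Construct an intensity matrix
#'
#' Per-variant x per-sample normalized polar intensities: `theta` in `[0, 1]`
#' and `R >= 0`. Missing intensities are `NA` in both layers.
#'
#' @param theta,r Numeric matrices (variants x samples) with matching
#'   dimnames.
#' @return An object of class `intensity_matrix` (a list of the two layers).
#' @export
new_intensity_matrix <- function(theta, r) {
  stopifnot(is.matrix(theta), is.matrix(r), all(dim(theta) == dim(r)))
  ok <- !is.na(theta)
  if (any(theta[ok] < 0 | theta[ok] > 1)) stop("theta must lie in [0, 1]")
  if (any(r[!is.na(r)] < 0)) stop("R must be non-negative")
  structure(list(theta = theta, r = r), class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat("intensity_matrix:", nrow(x$theta), "variants x", ncol(x$theta),
      "samples;", sum(is.na(x$theta)), "missing\n")
  invisible(x)
}

#' @export
dim.intensity_matrix <- function(x) dim(x$theta)

#' Construct a genotype matrix
#'
#' @param dosage Integer matrix (variants x samples) of B-allele dosages in
#'   `{0, 1, 2}` with `NA` for no-calls.
#' @param score Optional numeric matrix of per-call confidence in `[0, 1]`;
#'   no-call entries carry the score that failed the threshold.
#' @return An object of class `genotype_matrix`.
#' @export
new_genotype_matrix <- function(dosage, score = NULL) {
  stopifnot(is.matrix(dosage))
  storage.mode(dosage) <- "integer"
  ok <- !is.na(dosage)
  if (any(!dosage[ok] %in% 0:2)) stop("dosage values must be 0, 1, 2 or NA")
  if (!is.null(score)) {
    stopifnot(all(dim(score) == dim(dosage)))
    attr(dosage, "score") <- score
  }
  class(dosage) <- c("genotype_matrix", class(dosage))
  dosage
}

# strip class/attributes down to the raw dosage matrix
unclass_geno <- function(g) {
  attr(g, "score") <- NULL
  unclass(g)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  g <- unclass_geno(x)
  tab <- table(factor(g, levels = 0:2, labels = GENO_CLASSES),
               useNA = "always")
  cat("genotype_matrix:", nrow(g), "variants x", ncol(g), "samples\n  ")
  cat(paste(sprintf("%s=%d", c(GENO_CLASSES, "NC"), as.integer(tab)),
            collapse = "  "), "\n")
  invisible(x)
}

#' Genotype labels from a dosage matrix
#'
#' @param g A `genotype_matrix` or dosage matrix.
#' @return Character matrix with entries in `{"AA","AB","BB","NC"}`.
#' @export
genotype_labels <- function(g) {
  g <- unclass_geno(g)
  lab <- matrix(GENO_CLASSES[g + 1L], nrow(g), ncol(g),
                dimnames = dimnames(g))
  lab[is.na(g)] <- "NC"
  lab
}

# per-variant genotype counts (n_AA, n_AB, n_BB, n_NC)
geno_counts <- function(g) {
  g <- unclass_geno(g)
  cbind(n_AA = rowSums(g == 0L, na.rm = TRUE),
        n_AB = rowSums(g == 1L, na.rm = TRUE),
        n_BB = rowSums(g == 2L, na.rm = TRUE),
        n_NC = rowSums(is.na(g)))
}
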