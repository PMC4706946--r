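# Readers/writers for the external interchange formats. Text formats only:
# long-format intensity TSV (GenomeStudio final-report style), PED/MAP,
# minimal VCF 4.2 with GT, and a JSON cluster-file dialect. Binary .egt and
# .bed are deliberately unsupported. Coordinates are 1-based throughout.

#' Final-report dialect description
#'
#' Column mapping for a GenomeStudio-final-report-style long TSV. The
#' default dialect expects a header row with columns `variant_id`,
#' `sample_id`, `theta`, `r` and optionally `call` (labels AA/AB/BB/NC).
#'
#' @param variant_id,sample_id,theta,r,call Column names in the file.
#' @param sep Field delimiter.
#' @param skip Header lines to skip before the column header.
#' @return A list of class `final_report_dialect`.
#' @export
final_report_dialect <- function(variant_id = "variant_id",
                                 sample_id = "sample_id",
                                 theta = "theta", r = "r",
                                 call = "call", sep = "\t", skip = 0L) {
  structure(list(variant_id = variant_id, sample_id = sample_id,
                 theta = theta, r = r, call = call, sep = sep,
                 skip = as.integer(skip)),
            class = "final_report_dialect")
}

#' Read a final-report-style intensity TSV
#'
#' Long-format rows are pivoted to variant x sample matrices; variants and
#' samples appear in file order. Duplicate (variant, sample) rows and
#' unparseable theta/R values are errors.
#'
#' @param path File path.
#' @param dialect A [final_report_dialect()].
#' @return List with `intensities` (`intensity_matrix`) and `genotypes`
#'   (`genotype_matrix`, or NULL when the file carries no call column).
#' @export
read_final_report <- function(path, dialect = final_report_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                          skip = dialect$skip, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c(dialect$variant_id, dialect$sample_id, dialect$theta, dialect$r)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing required column(s): ",
                         paste(miss, collapse = ", "))
  vid <- as.character(df[[dialect$variant_id]])
  sid <- as.character(df[[dialect$sample_id]])
  if (anyDuplicated(paste(vid, sid))) {
    d <- paste(vid, sid)[duplicated(paste(vid, sid))][1]
    stop("duplicated (variant, sample) row: ", d)
  }
  th <- suppressWarnings(as.numeric(df[[dialect$theta]]))
  rr <- suppressWarnings(as.numeric(df[[dialect$r]]))
  bad <- sum((is.na(th) & !is.na(df[[dialect$theta]])) |
               (is.na(rr) & !is.na(df[[dialect$r]])))
  if (bad > 0) stop(bad, " row(s) with unparseable theta/R values")
  vids <- unique(vid); sids <- unique(sid)
  theta <- matrix(NA_real_, length(vids), length(sids),
                  dimnames = list(vids, sids))
  r <- theta
  idx <- cbind(match(vid, vids), match(sid, sids))
  theta[idx] <- th
  r[idx] <- rr
  genotypes <- NULL
  if (!is.null(dialect$call) && dialect$call %in% names(df)) {
    dm <- matrix(NA_integer_, length(vids), length(sids),
                 dimnames = list(vids, sids))
    dm[idx] <- match(df[[dialect$call]], GENO_CLASSES) - 1L
    genotypes <- new_genotype_matrix(dm)
  }
  list(intensities = new_intensity_matrix(theta, r), genotypes = genotypes)
}

#' Write intensities (and optional calls) as a final-report-style TSV
#'
#' @param intensities An `intensity_matrix`.
#' @param path Output path.
#' @param genotypes Optional `genotype_matrix` adding a `call` column.
#' @return The path, invisibly.
#' @export
write_final_report <- function(intensities, path, genotypes = NULL) {
  vids <- rownames(intensities$theta); sids <- colnames(intensities$theta)
  df <- data.frame(
    variant_id = rep(vids, times = length(sids)),
    sample_id = rep(sids, each = length(vids)),
    theta = as.vector(intensities$theta),
    r = as.vector(intensities$r), stringsAsFactors = FALSE)
  if (!is.null(genotypes)) {
    df$call <- as.vector(genotype_labels(genotypes))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a cluster-model set as a JSON cluster file
#'
#' The JSON dialect stores, per variant and per genotype class, the theta
#' mean/deviation, R mean/deviation and populated flag, plus the no-call
#' parameters and provenance. Binary .egt cluster files are not supported:
#' reading one raises an error pointing to this schema.
#'
#' @param models A `cluster_model_set`.
#' @param path Output path (`.json`).
#' @return `read_cluster_json` returns a `cluster_model_set`;
#'   `write_cluster_json` the path, invisibly.
#' @export
write_cluster_json <- function(models, path) {
  obj <- list(
    format = "exocall-cluster-file",
    version = 1L,
    config = models$config[c("d_max", "p_min")],
    variants = lapply(models$models, function(m) {
      list(theta_mean = as.list(m$theta_mean),
           theta_dev = as.list(m$theta_dev),
           r_mean = as.list(m$r_mean),
           r_dev = as.list(m$r_dev),
           populated = as.list(m$populated),
           n = as.list(m$n),
           d_max = m$d_max, p_min = m$p_min,
           provenance = m$provenance)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_cluster_json
#' @param caller_cfg A [caller_config()] completing fitting parameters not
#'   stored in the file.
#' @export
read_cluster_json <- function(path, caller_cfg = caller_config()) {
  if (grepl("\\.egt$", path, ignore.case = TRUE)) {
    stop("binary .egt cluster files are an unsupported format; ",
         "use the JSON cluster-file dialect (see ?write_cluster_json)")
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "exocall-cluster-file")) {
    stop("not an exocall JSON cluster file: ", path)
  }
  num3 <- function(x) {
    vapply(GENO_CLASSES, function(g) {
      v <- x[[g]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  }
  models <- lapply(obj$variants, function(v) {
    cfg <- caller_cfg
    cfg$d_max <- v$d_max; cfg$p_min <- v$p_min
    n <- vapply(GENO_CLASSES, function(g) {
      x <- v$n[[g]]
      if (is.null(x)) NA_integer_ else as.integer(x)
    }, integer(1))
    new_cluster_model(num3(v$theta_mean), num3(v$theta_dev),
                      num3(v$r_mean), num3(v$r_dev),
                      vapply(GENO_CLASSES, function(g)
                        isTRUE(v$populated[[g]]), logical(1)),
                      n, cfg, provenance = v$provenance %||% "supplied-file")
  })
  names(models) <- names(obj$variants)
  cfg <- caller_cfg
  cfg$d_max <- obj$config$d_max %||% caller_cfg$d_max
  cfg$p_min <- obj$config$p_min %||% caller_cfg$p_min
  structure(list(models = models, config = cfg),
            class = "cluster_model_set")
}

#' Write genotypes as PED/MAP
#'
#' PED columns: family id (= sample id), sample id, father 0, mother 0, sex
#' (1 = male, 2 = female, 0 = unknown), phenotype -9, then two allele letters
#' per variant (`0 0` for a no-call). MAP columns: chromosome, variant id,
#' genetic distance 0, 1-based position.
#'
#' @param genotypes A `genotype_matrix` (dosage of the alt/B allele).
#' @param variant_meta Data frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt` aligned to the rows.
#' @param prefix Output path prefix (`<prefix>.ped`, `<prefix>.map`).
#' @param declared_sex Optional `"M"`/`"F"` per sample.
#' @return The prefix, invisibly.
#' @export
write_ped_map <- function(genotypes, variant_meta, prefix,
                          declared_sex = NULL) {
  g <- unclass_geno(genotypes)
  sids <- colnames(g)
  sex <- if (is.null(declared_sex)) rep(0L, ncol(g)) else
    ifelse(is.na(declared_sex), 0L, ifelse(declared_sex == "M", 1L, 2L))
  alle <- matrix("0", 2L * nrow(g), ncol(g))
  for (v in seq_len(nrow(g))) {
    a1 <- c("0", variant_meta$ref[v], variant_meta$ref[v],
            variant_meta$alt[v])[ifelse(is.na(g[v, ]), 0L, g[v, ]) + 2L]
    a2 <- c("0", variant_meta$ref[v], variant_meta$alt[v],
            variant_meta$alt[v])[ifelse(is.na(g[v, ]), 0L, g[v, ]) + 2L]
    a1[is.na(g[v, ])] <- "0"; a2[is.na(g[v, ])] <- "0"
    alle[2L * v - 1L, ] <- a1
    alle[2L * v, ] <- a2
  }
  ped <- cbind(sids, sids, 0L, 0L, sex, -9L, t(alle))
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- variant_meta[, c("chrom", "variant_id", "pos")]
  map <- cbind(map[, 1:2], 0L, map[, 3])
  utils::write.table(map, paste0(prefix, ".map"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PED/MAP genotypes
#'
#' Genotypes are returned as alt-allele dosage. When `alleles` (a data frame
#' with `variant_id`, `ref`, `alt`) is supplied, dosage counts the given alt
#' allele; otherwise the alphabetically later of the two observed alleles is
#' taken as alt. `0 0` is a missing call.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair.
#' @param alleles Optional ref/alt assignment.
#' @return List with `genotypes` (`genotype_matrix`), `variant_meta`
#'   (chrom, variant_id, pos, and ref/alt when resolvable), `sample_meta`
#'   (sample_id, sex).
#' @export
read_ped_map <- function(prefix, alleles = NULL) {
  map <- utils::read.table(paste0(prefix, ".map"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "variant_id", "cm", "pos"))
  ped <- utils::read.table(paste0(prefix, ".ped"), header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  nv <- nrow(map)
  if (ncol(ped) != 6L + 2L * nv) {
    stop("PED has ", ncol(ped), " columns; expected ", 6L + 2L * nv)
  }
  sids <- ped[[2]]
  sex <- ifelse(ped[[5]] == "1", "M", ifelse(ped[[5]] == "2", "F",
                                             NA_character_))
  a1 <- t(as.matrix(ped[, 6L + 2L * seq_len(nv) - 1L]))
  a2 <- t(as.matrix(ped[, 6L + 2L * seq_len(nv)]))
  ref <- alt <- rep(NA_character_, nv)
  if (!is.null(alleles)) {
    i <- match(map$variant_id, alleles$variant_id)
    ref <- alleles$ref[i]; alt <- alleles$alt[i]
  }
  g <- matrix(NA_integer_, nv, length(sids),
              dimnames = list(map$variant_id, sids))
  for (v in seq_len(nv)) {
    x1 <- a1[v, ]; x2 <- a2[v, ]
    obs <- setdiff(sort(unique(c(x1, x2))), "0")
    if (is.na(alt[v])) {
      if (length(obs) == 0L) next
      alt[v] <- obs[length(obs)]
      ref[v] <- if (length(obs) > 1L) obs[1] else NA_character_
    }
    miss <- x1 == "0" | x2 == "0"
    d <- (x1 == alt[v]) + (x2 == alt[v])
    d[miss] <- NA_integer_
    g[v, ] <- as.integer(d)
  }
  meta <- data.frame(variant_id = map$variant_id, chrom = map$chrom,
                     pos = map$pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  list(genotypes = new_genotype_matrix(g), variant_meta = meta,
       sample_meta = data.frame(sample_id = sids, sex = sex,
                                stringsAsFactors = FALSE))
}

#' Write genotypes as a minimal VCF 4.2 (GT only)
#'
#' @param genotypes A `genotype_matrix` (alt dosage).
#' @param variant_meta Data frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param path Output path (plain text).
#' @return The path, invisibly.
#' @export
write_vcf <- function(genotypes, variant_meta, path) {
  g <- unclass_geno(genotypes)
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  head_lines <- c("##fileformat=VCFv4.2",
                  "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                  paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO", "FORMAT", colnames(g)),
                        collapse = "\t"))
  body <- apply(cbind(variant_meta$chrom, variant_meta$pos,
                      variant_meta$variant_id, variant_meta$ref,
                      variant_meta$alt, ".", "PASS", ".", "GT", gt),
                1L, paste, collapse = "\t")
  writeLines(c(head_lines, body), path)
  invisible(path)
}

#' Read genotypes from a VCF with GT fields
#'
#' Uses the vcfR parser. Genotypes map to alt-allele dosage: hom-ref 0, het
#' 1, hom-alt 2, `./.` missing. Only biallelic SNV records are returned.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return List with `genotypes` (`genotype_matrix`) and `variant_meta`.
#' @export
read_vcf_genotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  to_dosage <- function(x) {
    x <- gsub("\\|", "/", x)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1", "1")] <- 2L
    out
  }
  d <- matrix(to_dosage(gt), nrow(gt), ncol(gt),
              dimnames = list(fix$ID, colnames(gt)))
  meta <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF,
                     alt = fix$ALT, stringsAsFactors = FALSE)
  list(genotypes = new_genotype_matrix(d), variant_meta = meta)
}

#' Serialize a simulated bundle to a directory of text artifacts
#'
#' Writes the intensity TSV (with truth calls), truth genotypes as minimal
#' VCF and PED/MAP, sample metadata TSV, error-registry TSV and the
#' configuration as YAML.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_final_report(bundle$intensities, file.path(dir, "intensities.tsv"),
                     genotypes = bundle$truth)
  write_vcf(bundle$truth, bundle$variant_meta, file.path(dir, "truth.vcf"))
  write_ped_map(bundle$truth, bundle$variant_meta, file.path(dir, "truth"),
                declared_sex = bundle$sample_meta$sex)
  utils::write.table(bundle$sample_meta, file.path(dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$variant_meta, file.path(dir, "variant_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$error_registry,
                     file.path(dir, "error_registry.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- bundle$config
  cfg$maf_spectrum <- as.list(as.data.frame(cfg$maf_spectrum))
  cfg$cluster_geometry <- lapply(cfg$cluster_geometry, as.list)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
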