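#' Write a cohort to plain-text files
#'
#' Writes the genotypes both as a minimal VCF v4.2 (CHROM/POS/ID/REF/ALT,
#' GT field only) and as a TSV dosage matrix (rows = individuals, columns =
#' variants, entries 0/1/2 effect-allele counts), the individual table as
#' CSV, and the couple truth table and variant metadata as TSV.
#' [read_cohort()] reverses the operation; the round trip reproduces every
#' analysed field exactly (numeric columns are serialized at 17 significant
#' digits).
#'
#' @param cohort a [simulate_cohort()] cohort.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    dosage = file.path(dir, "dosages.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    truth = file.path(dir, "truth.tsv"),
    variants = file.path(dir, "variants.tsv")
  )
  write_minimal_vcf(cohort$genotypes, cohort$variant_meta, paths["vcf"])
  write_dosage_tsv(cohort$genotypes, paths["dosage"])
  write_table_exact(cohort$individuals, paths["phenotypes"], sep = ",")
  write_table_exact(cohort$truth, paths["truth"], sep = "\t")
  write_table_exact(cohort$variant_meta, paths["variants"], sep = "\t")
  invisible(paths)
}

# Serialize a data frame so numeric columns survive a read round trip
# bit-exactly (17 significant digits).
write_table_exact <- function(df, path, sep = ",") {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = sep, quote = TRUE, row.names = FALSE,
                     na = "NA")
}

write_minimal_vcf <- function(G, meta, path) {
  stopifnot(ncol(G) == nrow(meta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t")
  ), con)
  gt_code <- c("0" = "0/0", "1" = "0/1", "2" = "1/1")
  for (j in seq_len(ncol(G))) {
    g <- G[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[as.character(g)])
    writeLines(paste(c(meta$chrom[j], meta$pos[j], meta$id[j], meta$ref[j],
                       meta$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a minimal VCF
#'
#' Parses a VCF with GT fields into an individuals x variants dosage matrix
#' of ALT-allele counts; `./.` genotypes become `NA` (individuals with
#' missing dosage are dropped from single-variant analyses downstream).
#'
#' @param path VCF file path.
#' @return A list with `genotypes` (dosage matrix, rownames = sample IDs)
#'   and `variant_meta` (id, chrom, pos, ref, alt).
#' @export
read_vcf_dosage <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("malformed VCF (no GT field): ", path)
  dose <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), rownames(gt)))
  clean <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
  bad <- !(clean %in% names(map)) & !is.na(clean)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed VCF genotype '%s' at variant row %d, sample %d",
                 gt[bad][1], idx[1], idx[2]))
  }
  dose[] <- t(matrix(map[clean], nrow = nrow(gt)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  list(
    genotypes = dose,
    variant_meta = data.frame(
      id = fix$ID, chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
    )
  )
}

write_dosage_tsv <- function(G, path) {
  df <- data.frame(id = rownames(G), G, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV dosage matrix
#'
#' Expects one `id` column plus one column per variant with entries in
#' 0/1/2 (or NA for missing). Any other value is rejected with the
#' offending line number.
#'
#' @param path TSV file path.
#' @return Integer dosage matrix with sample IDs as rownames.
#' @export
read_dosage_tsv <- function(path) {
  if (!file.exists(path)) stop("dosage TSV not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("dosage TSV lacks an 'id' column: ", path)
  G <- as.matrix(df[setdiff(names(df), "id")])
  rownames(G) <- df$id
  bad <- matrix(!(as.vector(G) %in% c(0L, 1L, 2L)) & !is.na(as.vector(G)),
                nrow = nrow(G))
  if (any(bad)) {
    row <- which(apply(bad, 1, any))[1]
    stop(sprintf(
      "invalid dosage '%s' at line %d of %s (must be 0, 1, 2 or NA)",
      G[bad][1], row + 1L, path
    ))
  }
  storage.mode(G) <- "integer"
  G
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the files written by [write_cohort()].
#' @param config optionally, the [sim_config()] that generated the cohort
#'   (restored onto the object when supplied).
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir, config = NULL) {
  p_pheno <- file.path(dir, "phenotypes.csv")
  p_dose <- file.path(dir, "dosages.tsv")
  p_truth <- file.path(dir, "truth.tsv")
  p_var <- file.path(dir, "variants.tsv")
  for (p in c(p_pheno, p_dose, p_truth, p_var)) {
    if (!file.exists(p)) stop("missing cohort file: ", p)
  }
  individuals <- utils::read.csv(p_pheno, stringsAsFactors = FALSE)
  if ("decoy" %in% names(individuals)) {
    individuals$decoy <- as.character(individuals$decoy)
    individuals$decoy[is.na(individuals$decoy)] <- ""
  }
  G <- read_dosage_tsv(p_dose)
  truth <- utils::read.table(p_truth, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  meta <- utils::read.table(p_var, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
  if (!identical(rownames(G), individuals$id)) {
    stop("dosage TSV sample IDs do not match the phenotype table")
  }
  structure(
    list(individuals = individuals, genotypes = G, truth = truth,
         variant_meta = meta, config = config, log = character()),
    class = "cohort"
  )
}
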