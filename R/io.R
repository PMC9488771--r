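# Readers and writers for the package's file dialects: long-format grid CSV,
# 012 genotype TSV (missing = -1), a minimal GT-only VCF v4.2 subset, FASTA
# via ape, plain CSV tables, and a YAML pipeline configuration. Every writer
# round-trips through its reader.

#' Write abundance grids as long-format CSV
#'
#' Columns `cell_x`, `cell_y`, `species`, `abundance`; every cell of every
#' species is written so the grid dimensions round-trip.
#'
#' @param grids Named list of abundance matrices.
#' @param path Output CSV path.
#' @export
write_grids_csv <- function(grids, path) {
  stopifnot(is.list(grids), !is.null(names(grids)))
  rows <- lapply(names(grids), function(s) {
    g <- grids[[s]]
    data.frame(cell_x = rep(seq_len(nrow(g)), ncol(g)),
               cell_y = rep(seq_len(ncol(g)), each = nrow(g)),
               species = s, abundance = as.vector(g),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read abundance grids from long-format CSV
#'
#' @param path CSV written by [write_grids_csv()].
#' @return Named list of abundance matrices.
#' @export
read_grids_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_x", "cell_y", "species", "abundance")
  if (!all(need %in% names(df))) {
    dh_stop(paste("grid CSV must have columns:", paste(need, collapse = ", ")),
            "dh_input_error")
  }
  lapply(split(df, df$species), function(d) {
    g <- matrix(0, max(d$cell_x), max(d$cell_y))
    g[cbind(d$cell_x, d$cell_y)] <- d$abundance
    g
  })
}

#' Write a genotype matrix as 012 TSV
#'
#' Tab-separated with an `individual_id` column followed by one column per
#' locus; dosages 0/1/2 and -1 for missing.
#'
#' @param gm Integer dosage matrix (individuals x loci, `NA` missing).
#' @param path Output TSV path.
#' @export
write_012 <- function(gm, path) {
  out <- gm
  out[is.na(out)] <- -1L
  df <- data.frame(individual_id = rownames(gm), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 012 TSV genotype matrix
#'
#' @param path TSV written by [write_012()].
#' @return Integer dosage matrix with `NA` for missing.
#' @export
read_012 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "individual_id") {
    dh_stop("012 TSV must start with an individual_id column", "dh_input_error")
  }
  gm <- as.matrix(df[, -1, drop = FALSE])
  bad <- !(gm %in% c(-1, 0, 1, 2))
  if (any(bad)) {
    lines <- which(rowSums(matrix(bad, nrow(gm))) > 0)[1] + 1L
    dh_stop(sprintf("invalid 012 value at line %d (allowed: -1, 0, 1, 2)", lines),
            "dh_input_error")
  }
  storage.mode(gm) <- "integer"
  gm[gm == -1L] <- NA_integer_
  rownames(gm) <- df$individual_id
  gm
}

#' Write a minimal GT-only VCF
#'
#' Plain-text VCF v4.2 subset: `CHROM POS ID REF ALT QUAL FILTER INFO FORMAT`
#' plus one diploid GT column per individual (`0/0`, `0/1`, `1/1`, `./.`).
#' The dosage convention counts ALT alleles. Chromosome label `"Z"` marks
#' Z-linked sites for the filtering rules.
#'
#' @param gm Integer dosage matrix (individuals x loci).
#' @param loci Data frame with `locus_id`, `chrom`, `pos`, `ref`, `alt`
#'   matching `colnames(gm)`.
#' @param path Output VCF path.
#' @export
write_vcf_minimal <- function(gm, loci, path) {
  stopifnot(is.matrix(gm), all(colnames(gm) %in% loci$locus_id))
  loci <- loci[match(colnames(gm), loci$locus_id), , drop = FALSE]
  gt <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(ncol(gm)), function(j) {
    calls <- ifelse(is.na(gm[, j]), "./.", gt[gm[, j] + 1L])
    paste(c(loci$chrom[j], loci$pos[j], loci$locus_id[j], loci$ref[j],
            loci$alt[j], ".", "PASS", ".", "GT", calls), collapse = "\t")
  }, character(1))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm)), collapse = "\t")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a VCF
#'
#' Parses GT fields into ALT-allele dosages via vcfR; any half-missing or
#' missing call becomes `NA`.
#'
#' @param path VCF path.
#' @return List with `genotypes` (individuals x loci dosage matrix) and
#'   `loci` (data frame with `locus_id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  rownames(dosage) <- loci$locus_id
  list(genotypes = t(dosage), loci = loci)
}

#' Write haplotypes to FASTA
#'
#' Reference haplotypes are labelled `id|species`; queries by their bare id.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output FASTA path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  bin <- ape::as.DNAbin(lapply(seqs, function(s) strsplit(tolower(s), "")[[1]]))
  ape::write.FASTA(bin, path)
  invisible(path)
}

#' Read haplotypes from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  vapply(as.character(bin), function(ch) toupper(paste(ch, collapse = "")),
         character(1))
}

#' Split `id|species` reference FASTA labels
#'
#' @param labels Character vector of FASTA labels.
#' @return Data frame with `id` and `species` (`NA` species for bare query
#'   ids).
#' @export
parse_reference_labels <- function(labels) {
  parts <- strsplit(labels, "|", fixed = TRUE)
  data.frame(
    id = vapply(parts, `[`, character(1), 1L),
    species = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                     character(1)),
    stringsAsFactors = FALSE)
}

#' Read a YAML pipeline configuration
#'
#' Validates that every referenced input path exists at run start.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    dh_stop(sprintf("configuration file not found: %s", path), "dh_input_error")
  }
  cfg <- yaml::read_yaml(path)
  for (field in grep("_path$", names(cfg), value = TRUE)) {
    if (!file.exists(cfg[[field]])) {
      dh_stop(sprintf("input file referenced by %s not found: %s",
                      field, cfg[[field]]), "dh_input_error")
    }
  }
  cfg
}
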