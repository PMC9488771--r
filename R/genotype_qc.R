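# Read-count genotype scoring and locus/individual filtering for ddRAD
# panels. Two filtering presets mirror the two labs that produced the data
# this package is designed for: "wsu" (per-locus missingness and flag-rate
# caps, then a per-individual genotyping floor) and "cornell" (one SNP per
# RAD locus, locus presence floor, individual missingness cap with a second
# presence pass, then removal of Z-linked sites).

#' Score a genotype from per-haplotype read counts
#'
#' An individual is scored homozygous when more than 93% of its reads are
#' consistent with a single haplotype, and heterozygous when more than 29%
#' are consistent with a second haplotype -- or when at least 20% are
#' consistent with a second allele that is represented in other individuals.
#' Genotypes meeting neither criterion, showing more than two credible
#' haplotypes, or represented by fewer than 5 reads are flagged: the majority
#' allele is retained and the second allele is scored missing.
#'
#' @param counts Named non-negative integer vector of reads per candidate
#'   haplotype.
#' @param population_haplotypes Character vector of haplotypes observed in
#'   other individuals at this locus.
#' @param thresholds List with elements `hom` (default 0.93, strict), `het`
#'   (0.29, strict), `het_pop` (0.20, inclusive), `min_reads` (5).
#' @return Object of class `genotype_call`: list with `genotype` (`"hom"`,
#'   `"het"` or `"hemizygous"`), `alleles` (length-2 character, `NA` for a
#'   missing second allele), `flagged`, `reason`, `total_reads`.
#' @export
call_genotype <- function(counts, population_haplotypes = character(),
                          thresholds = list(hom = 0.93, het = 0.29,
                                            het_pop = 0.20, min_reads = 5)) {
  if (length(counts) == 0) dh_stop("empty read counts", "dh_input_error")
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    dh_stop("read counts must be named by haplotype", "dh_input_error")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    dh_stop("read counts must be non-negative integers", "dh_input_error")
  }
  th <- utils::modifyList(list(hom = 0.93, het = 0.29, het_pop = 0.20,
                               min_reads = 5), as.list(thresholds))
  total <- sum(counts)
  ord <- order(-counts, names(counts))   # deterministic tie-break by name
  haps <- names(counts)[ord]
  shares <- if (total > 0) counts[ord] / total else counts[ord] * 0

  call <- function(genotype, alleles, flagged = FALSE, reason = "") {
    structure(list(genotype = genotype, alleles = alleles, flagged = flagged,
                   reason = reason, total_reads = total),
              class = "genotype_call")
  }
  flagged_call <- function(reason) {
    call("hemizygous", c(haps[1], NA_character_), flagged = TRUE,
         reason = reason)
  }

  if (total < th$min_reads) return(flagged_call("fewer than min_reads reads"))
  n_credible <- sum(shares >= th$het_pop)
  if (n_credible > 2) return(flagged_call("more than two credible haplotypes"))
  if (shares[1] > th$hom) return(call("hom", c(haps[1], haps[1])))
  second <- if (length(haps) >= 2) shares[2] else 0
  if (second > th$het) return(call("het", haps[1:2]))
  if (second >= th$het_pop && haps[2] %in% population_haplotypes) {
    return(call("het", haps[1:2]))
  }
  flagged_call("second haplotype below heterozygote thresholds")
}

#' @export
print.genotype_call <- function(x, ...) {
  al <- paste(ifelse(is.na(x$alleles), ".", x$alleles), collapse = "/")
  cat(sprintf("genotype call: %s (%s)%s, %d reads\n", x$genotype, al,
              if (x$flagged) paste0(" FLAGGED [", x$reason, "]") else "",
              x$total_reads))
  invisible(x)
}

#' Locus/individual filtering configuration
#'
#' @param preset `"wsu"` or `"cornell"`. The wsu preset retains loci with at
#'   most 20% missing and at most 5% flagged genotypes, then drops individuals
#'   genotyped at fewer than 75% of the retained loci. The cornell preset
#'   keeps one SNP per RAD locus, retains loci present in at least 80% of
#'   individuals, removes individuals with more than 25% missing loci,
#'   re-applies the presence filter to the surviving individuals, and finally
#'   drops Z-linked sites.
#' @param ... Named overrides of any preset field (`locus_max_missing`,
#'   `locus_max_flagged`, `individual_min_genotyped`, `locus_min_presence`,
#'   `individual_max_missing`, `drop_z`, `one_snp_per_locus`).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(preset = c("wsu", "cornell"), ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "wsu") {
    list(preset = "wsu", locus_max_missing = 0.20, locus_max_flagged = 0.05,
         individual_min_genotyped = 0.75, drop_z = FALSE,
         one_snp_per_locus = FALSE)
  } else {
    list(preset = "cornell", locus_min_presence = 0.80,
         individual_max_missing = 0.25, drop_z = TRUE,
         one_snp_per_locus = TRUE)
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), c(names(cfg), "locus_min_presence",
                                    "individual_max_missing",
                                    "locus_max_missing", "locus_max_flagged",
                                    "individual_min_genotyped"))
  if (length(unknown)) {
    dh_stop(paste("unknown filter_config fields:", paste(unknown, collapse = ", ")),
            "dh_config_error")
  }
  cfg <- utils::modifyList(cfg, dots)
  fracs <- cfg[names(cfg) %in% c("locus_max_missing", "locus_max_flagged",
                                 "individual_min_genotyped",
                                 "locus_min_presence", "individual_max_missing")]
  if (!all(vapply(fracs, is_prob, logical(1)))) {
    dh_stop("filter fractions must lie in [0, 1]", "dh_config_error")
  }
  structure(cfg, class = "filter_config")
}

report_row <- function(stage, type, id, reason, value = NA_real_) {
  data.frame(stage = stage, type = type, id = id, reason = reason,
             value = value, stringsAsFactors = FALSE)
}

#' Filter a genotype matrix by locus and individual quality rules
#'
#' Applies the preset's rules in its documented order (the two presets are
#' order-sensitive and can disagree on crafted inputs). Flagged genotypes
#' count as genotyped with one allele: missingness is the fraction of fully
#' missing (`NA`) slots.
#'
#' @param gm Integer matrix individuals x loci with dosages 0/1/2 and `NA`
#'   for missing; dimnames required.
#' @param flags Optional logical matrix of the same shape marking flagged
#'   genotypes (default: none flagged).
#' @param cfg A [filter_config()].
#' @param loci Optional data frame of locus metadata with columns `locus_id`
#'   (matching `colnames(gm)`), and optionally `rad_locus`, `pos`, `chrom`.
#'   Needed for the one-SNP-per-locus and Z-chromosome rules.
#' @return Object of class `qc_result`: list with the filtered `genotypes`,
#'   `flags`, `loci`, and a `report` data frame listing every removed locus
#'   and individual with its reason.
#' @export
filter_matrix <- function(gm, flags = NULL, cfg = filter_config("wsu"),
                          loci = NULL) {
  if (!is.matrix(gm) || nrow(gm) == 0 || ncol(gm) == 0) {
    dh_stop("genotype matrix must be a non-empty matrix", "dh_input_error")
  }
  if (is.null(rownames(gm)) || is.null(colnames(gm))) {
    dh_stop("genotype matrix requires dimnames", "dh_input_error")
  }
  stopifnot(inherits(cfg, "filter_config"))
  if (is.null(flags)) {
    flags <- matrix(FALSE, nrow(gm), ncol(gm), dimnames = dimnames(gm))
  }
  stopifnot(identical(dim(flags), dim(gm)))
  if (is.null(loci)) {
    loci <- data.frame(locus_id = colnames(gm),
                       rad_locus = colnames(gm),
                       chrom = NA_character_,
                       pos = seq_len(ncol(gm)),
                       stringsAsFactors = FALSE)
  }
  loci <- loci[match(colnames(gm), loci$locus_id), , drop = FALSE]
  report <- list()
  keep_l <- colnames(gm)
  keep_i <- rownames(gm)

  drop_loci <- function(ids, stage, reason, values = NA_real_) {
    if (length(ids)) {
      report[[length(report) + 1]] <<- report_row(stage, "locus", ids, reason, values)
      keep_l <<- setdiff(keep_l, ids)
    }
  }
  drop_inds <- function(ids, stage, reason, values = NA_real_) {
    if (length(ids)) {
      report[[length(report) + 1]] <<- report_row(stage, "individual", ids, reason, values)
      keep_i <<- setdiff(keep_i, ids)
    }
  }

  if (cfg$preset == "wsu") {
    miss <- colMeans(is.na(gm))
    flg <- colMeans(flags)
    bad_m <- keep_l[miss[keep_l] > cfg$locus_max_missing]
    drop_loci(bad_m, "locus_missing", "missing genotype fraction above cap",
              miss[bad_m])
    bad_f <- keep_l[flg[keep_l] > cfg$locus_max_flagged]
    drop_loci(bad_f, "locus_flagged", "flagged genotype fraction above cap",
              flg[bad_f])
    if (isTRUE(cfg$drop_z)) {
      z <- keep_l[!is.na(loci$chrom[match(keep_l, loci$locus_id)]) &
                    loci$chrom[match(keep_l, loci$locus_id)] == "Z"]
      drop_loci(z, "z_chromosome", "Z-linked site")
    }
    if (length(keep_l) == 0) {
      dh_stop("all loci removed by filtering: empty result", "dh_empty_result")
    }
    genod <- rowMeans(!is.na(gm[, keep_l, drop = FALSE]))
    bad_i <- keep_i[genod[keep_i] < cfg$individual_min_genotyped]
    drop_inds(bad_i, "individual_genotyped",
              "genotyped at fewer than the required fraction of retained loci",
              genod[bad_i])
  } else {
    if (isTRUE(cfg$one_snp_per_locus)) {
      ord <- order(loci$rad_locus, loci$pos)
      first <- !duplicated(loci$rad_locus[ord])
      keep_first <- loci$locus_id[ord][first]
      drop_loci(setdiff(keep_l, keep_first), "one_snp_per_locus",
                "additional SNP on an already-represented RAD locus")
    }
    pres <- colMeans(!is.na(gm))
    bad_p <- keep_l[pres[keep_l] < cfg$locus_min_presence]
    drop_loci(bad_p, "locus_presence", "present in too few individuals",
              pres[bad_p])
    if (length(keep_l) == 0) {
      dh_stop("all loci removed by filtering: empty result", "dh_empty_result")
    }
    miss_i <- rowMeans(is.na(gm[, keep_l, drop = FALSE]))
    bad_i <- keep_i[miss_i[keep_i] > cfg$individual_max_missing]
    drop_inds(bad_i, "individual_missing",
              "more than the allowed fraction of loci missing", miss_i[bad_i])
    # second presence pass after re-export for the surviving individuals
    pres2 <- colMeans(!is.na(gm[keep_i, keep_l, drop = FALSE]))
    bad_p2 <- keep_l[pres2 < cfg$locus_min_presence]
    drop_loci(bad_p2, "locus_presence_reexport",
              "present in too few surviving individuals", pres2[bad_p2])
    if (isTRUE(cfg$drop_z)) {
      z <- keep_l[!is.na(loci$chrom[match(keep_l, loci$locus_id)]) &
                    loci$chrom[match(keep_l, loci$locus_id)] == "Z"]
      drop_loci(z, "z_chromosome", "Z-linked site")
    }
  }

  if (length(keep_l) == 0) {
    dh_stop("all loci removed by filtering: empty result", "dh_empty_result")
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(stage = character(), type = character(), id = character(),
               reason = character(), value = numeric(),
               stringsAsFactors = FALSE)
  structure(list(
    genotypes = gm[keep_i, keep_l, drop = FALSE],
    flags = flags[keep_i, keep_l, drop = FALSE],
    loci = loci[match(keep_l, loci$locus_id), , drop = FALSE],
    report = report,
    config = cfg
  ), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("qc_result [%s]: %d individuals x %d loci retained; %d removals\n",
              x$config$preset, nrow(x$genotypes), ncol(x$genotypes),
              nrow(x$report)))
  invisible(x)
}
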