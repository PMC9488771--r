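# End-to-end orchestration on synthetic data: simulate inputs, filter
# genotypes, estimate ancestry and hybrid classes, assign dams from mtDNA,
# infer sires, build siring and complementarity tables, and run the
# abundance-overlap null model. Every specimen is accounted for exactly once
# (assigned or flagged), all randomness flows from the single configured
# seed, and a rerun with the same seed reproduces the report exactly.

#' Synthetic morphology table
#'
#' Species-level winter and summer phallus means and sex-specific masses
#' with the structure the behavioural tests consume: winter means lognormal
#' across species (roughly 10--130 mm, the observed range in dabbling and
#' diving ducks), summer means back-computed from the seasonal log-log
#' relation with noise, and male mass exceeding female mass within species.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with `species`, `winter_phallus_mm`,
#'   `summer_phallus_mm`, `n_phallus`, `male_mass_g`, `female_mass_g`.
#' @export
gen_morphology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(substream_seed(cfg$seed, "morphology"), {
    K <- cfg$n_species
    winter <- stats::rlnorm(K, meanlog = log(40), sdlog = 0.6)
    log10_summer <- (log10(winter) - 0.3195) / 0.7836 +
      stats::rnorm(K, 0, 0.05)
    male <- stats::rlnorm(K, meanlog = log(900), sdlog = 0.3)
    data.frame(
      species = cfg$species,
      winter_phallus_mm = winter,
      summer_phallus_mm = 10^log10_summer,
      n_phallus = stats::rpois(K, 12) + 2L,
      male_mass_g = male,
      female_mass_g = male * stats::runif(K, 0.80, 0.95),
      stringsAsFactors = FALSE)
  })
}

#' Run the full hybrid-attribution pipeline on synthetic data
#'
#' Composes the stages in analysis order: abundance grids and pair weights;
#' parental reference genotypes and allele-frequency panel; mtDNA
#' references; an abundance-weighted sample of hybrid specimens with truth
#' labels; genotype filtering; supervised ancestry with parent-pair and
#' hybrid-class calls; maternal assignment and sire inference; siring and
#' complementarity tables; and the abundance-overlap null model on the
#' sampled combinations.
#'
#' @param cfg A [sim_config()]; its seed drives every stage.
#' @param n_hybrids Number of hybrid specimens to simulate (default 127).
#' @param class_probs Named probabilities of the simulated hybrid classes
#'   (default 80% F1, 15% F2 backcross, 5% later backcross, matching the
#'   F1 fraction observed among fully genotyped hybrids).
#' @param ncfg A [null_config()] for the encounter null model; its `n_draws`
#'   is set to `n_hybrids` and its seed is derived from `cfg$seed`.
#' @param filter_preset `"wsu"` or `"cornell"`.
#' @param out_dir Optional directory; when given, stage outputs are written
#'   (grids CSV, reference VCF, 012 TSV, FASTA, truth labels, ancestry and
#'   maternal CSVs, null-model CSV).
#' @return Object of class `duckhybrids_report`: list of stage outputs,
#'   per-stage counts, and recovery metrics against the truth labels
#'   (`f1_recall`, `pair_accuracy`, `dam_accuracy`, `sire_accuracy`).
#' @export
run_pipeline <- function(cfg = sim_config(), n_hybrids = 127L,
                         class_probs = c(F1 = 0.80, F2_backcross = 0.15,
                                         later_backcross = 0.05),
                         ncfg = NULL, filter_preset = "wsu", out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(ncfg)) ncfg <- null_config()
  ncfg$n_draws <- as.integer(n_hybrids)
  ncfg$seed <- substream_seed(cfg$seed, "null_model")

  # --- simulate inputs -------------------------------------------------
  grids <- gen_abundance_grids(cfg)
  weights <- compute_pair_weights(grids, ncfg)
  par <- gen_parental_genotypes(cfg)
  mt <- gen_mtdna(cfg)
  morph <- gen_morphology(cfg)

  sampled_pairs <- gen_hybrid_sample(weights, n_hybrids,
                                     seed = substream_seed(cfg$seed, "sample"))
  classes <- withr::with_seed(substream_seed(cfg$seed, "classes"), {
    sample(names(class_probs), n_hybrids, replace = TRUE, prob = class_probs)
  })
  hybrids <- vector("list", n_hybrids)
  for (i in seq_len(n_hybrids)) {
    sp <- strsplit(sampled_pairs[i], " x ", fixed = TRUE)[[1]]
    orient <- withr::with_seed(substream_seed(cfg$seed, paste0("orient", i)),
                               sample(2L, 1L))
    sire <- sp[orient]; dam <- sp[3L - orient]
    hybrids[[i]] <- gen_hybrid_genotypes(
      classes[i], species_a = sire, species_b = dam, freqs = par$true_freqs,
      seed = substream_seed(cfg$seed, paste0("hybrid", i)),
      id = sprintf("hyb%03d", i), sire = sire, dam = dam)
  }
  truth <- do.call(rbind, lapply(hybrids, `[[`, "label"))
  hyb_gm <- do.call(rbind, lapply(hybrids, `[[`, "genotype"))
  rownames(hyb_gm) <- truth$specimen_id
  hyb_mt <- vapply(seq_len(n_hybrids), function(i) {
    gen_hybrid_mtdna(mt, truth$true_dam[i],
                     substream_seed(cfg$seed, paste0("mt", i)))
  }, character(1))
  names(hyb_mt) <- truth$specimen_id

  # --- genotype QC -----------------------------------------------------
  qc_refs <- filter_matrix(par$genotypes, cfg = filter_config(filter_preset),
                           loci = par$loci)
  ref_species <- par$species[match(rownames(qc_refs$genotypes),
                                   rownames(par$genotypes))]
  qc_hyb <- filter_matrix(hyb_gm[, colnames(qc_refs$genotypes), drop = FALSE],
                          cfg = filter_config(filter_preset),
                          loci = par$loci)

  # --- ancestry --------------------------------------------------------
  panel <- estimate_allele_freqs(qc_refs$genotypes, ref_species)
  # Non-convergence surfaces per-individual in the `converged` column; the
  # per-call warnings are tallied rather than repeated.
  n_nonconverged <- 0L
  anc <- withCallingHandlers(
    run_ancestry(qc_hyb$genotypes, panel),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        n_nonconverged <<- n_nonconverged + 1L
        invokeRestart("muffleWarning")
      }
    })

  # --- maternal assignment and sire inference --------------------------
  maternal <- lapply(rownames(qc_hyb$genotypes), function(id) {
    tryCatch(assign_maternal(hyb_mt[[id]], mt, hybrid_id = id),
             dh_ambiguous = function(e) {
               data.frame(hybrid_id = id, mother_species = NA_character_,
                          best_distance = NA_real_, margin = NA_real_,
                          stringsAsFactors = FALSE)
             })
  })
  maternal <- do.call(rbind, maternal)
  anc <- merge(anc, maternal, by.x = "individual_id", by.y = "hybrid_id",
               sort = FALSE)
  anc$sire_species <- NA_character_
  anc$status <- "assigned"
  for (i in seq_len(nrow(anc))) {
    if (is.na(anc$mother_species[i])) {
      anc$status[i] <- "flagged_ambiguous_mtdna"
      next
    }
    sire <- tryCatch(infer_sire(anc$parent_pair[i], anc$mother_species[i]),
                     dh_inconsistent_parents = function(e) NA_character_)
    if (is.na(sire)) {
      anc$status[i] <- "flagged_parent_mismatch"
    } else {
      anc$sire_species[i] <- sire
    }
  }

  # --- behavioural tables ---------------------------------------------
  f1 <- anc[anc$hybrid_class == "F1" & anc$status == "assigned", , drop = FALSE]
  f1_tab <- NULL; comp <- NULL
  if (nrow(f1) > 0) {
    sp_mat <- do.call(rbind, strsplit(f1$parent_pair, " x ", fixed = TRUE))
    f1_df <- data.frame(specimen_id = f1$individual_id,
                        species_a = sp_mat[, 1], species_b = sp_mat[, 2],
                        sire = f1$sire_species, dam = f1$mother_species,
                        stringsAsFactors = FALSE)
    f1_tab <- group_by_asymmetry(f1_df, morph)
    comp <- build_complementarity(f1_df, morph)
  }

  # --- encounter null model -------------------------------------------
  obs <- table(sampled_pairs)
  sims <- simulate_expected(weights, ncfg)
  devs <- deviation_report(
    standardized_effects(stats::setNames(as.integer(obs), names(obs)), sims, ncfg))

  # --- recovery metrics ------------------------------------------------
  kept <- truth$specimen_id %in% anc$individual_id
  truth$accounted <- ifelse(kept, "analysed", "filtered")
  m <- match(anc$individual_id, truth$specimen_id)
  true_f1 <- truth$true_class[m] == "F1"
  metrics <- list(
    f1_recall = mean(anc$hybrid_class[true_f1] == "F1"),
    pair_accuracy = mean(anc$parent_pair ==
                           pair_key(truth$species_a[m], truth$species_b[m])),
    dam_accuracy = mean(anc$mother_species == truth$true_dam[m], na.rm = TRUE),
    sire_accuracy = mean(anc$sire_species[true_f1] ==
                           truth$true_sire[m][true_f1], na.rm = TRUE)
  )

  report <- structure(list(
    config = cfg, null_config = ncfg,
    counts = list(
      n_hybrids = n_hybrids,
      n_reference = nrow(par$genotypes),
      n_loci = cfg$n_loci,
      n_loci_retained = ncol(qc_hyb$genotypes),
      n_hybrids_analysed = nrow(anc),
      n_flagged = sum(anc$status != "assigned"),
      n_em_nonconverged = n_nonconverged,
      n_f1_called = sum(anc$hybrid_class == "F1")
    ),
    weights = weights, truth = truth, ancestry = anc,
    assignment_histogram = assignment_histogram(anc),
    siring = f1_tab, complementarity = comp, null_model = devs,
    qc_report = rbind(qc_refs$report, qc_hyb$report),
    morphology = morph,
    metrics = metrics
  ), class = "duckhybrids_report")

  if (!is.null(out_dir)) write_report_files(report, grids, par, mt, hyb_gm,
                                            hyb_mt, out_dir)
  report
}

write_report_files <- function(report, grids, par, mt, hyb_gm, hyb_mt,
                               out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_grids_csv(grids, p("abundance_grids.csv"))
  write_vcf_minimal(par$genotypes, par$loci, p("reference_genotypes.vcf"))
  write_012(hyb_gm, p("hybrid_genotypes.012.tsv"))
  refs <- stats::setNames(mt$refs$sequence,
                          paste(mt$refs$id, mt$refs$species, sep = "|"))
  write_fasta(c(refs, hyb_mt), p("mtdna.fasta"))
  utils::write.csv(report$truth, p("truth_labels.csv"), row.names = FALSE)
  utils::write.csv(report$ancestry, p("ancestry_results.csv"), row.names = FALSE)
  utils::write.csv(report$null_model, p("null_model_results.csv"),
                   row.names = FALSE)
  utils::write.csv(report$qc_report, p("qc_removals.csv"), row.names = FALSE)
  utils::write.csv(report$morphology, p("morphology.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.duckhybrids_report <- function(x, ...) {
  cat("duckhybrids pipeline report\n")
  cat(sprintf("  species: %d | loci simulated: %d | retained: %d\n",
              x$config$n_species, x$counts$n_loci, x$counts$n_loci_retained))
  cat(sprintf("  hybrids: %d simulated, %d analysed, %d flagged, %d called F1\n",
              x$counts$n_hybrids, x$counts$n_hybrids_analysed,
              x$counts$n_flagged, x$counts$n_f1_called))
  cat(sprintf("  recovery: F1 recall %.3f | pair accuracy %.3f | dam accuracy %.3f\n",
              x$metrics$f1_recall, x$metrics$pair_accuracy,
              x$metrics$dam_accuracy))
  over <- sum(x$null_model$classification == "over")
  under <- sum(x$null_model$classification == "under")
  cat(sprintf("  null model: %d pairs over, %d under, %d combinations\n",
              over, under, nrow(x$null_model)))
  invisible(x)
}
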