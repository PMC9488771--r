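# Synthetic-data generator: breeding-season abundance grids, parental and
# hybrid ddRAD-style genotypes, species-diagnostic mtDNA haplotypes, and
# abundance-weighted hybrid samples. Every downstream stage of the package is
# exercisable on these simulants, with truth labels for parameter recovery.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study conditions the analysis assumes: eight parental species genotyped at
#' 2,000 biallelic loci with ten reference individuals each, moderate
#' population divergence (Balding--Nichols F = 0.3), broadly overlapping
#' circular breeding ranges with lognormal cell abundances, and
#' species-diagnostic mtDNA at 5% inter-species divergence.
#'
#' @param n_species Number of parental species (>= 2).
#' @param grid_side Cells per axis of the square abundance grid.
#' @param range_centers Optional `n_species` x 2 matrix of range centres in
#'   cell coordinates. Default places species evenly on a circle around the
#'   grid centre so that all ranges overlap pairwise.
#' @param range_radius Radius (cells) of each species' hard circular
#'   breeding-range footprint.
#' @param abundance_meanlog,abundance_sdlog Lognormal parameters for cell
#'   abundance inside a footprint.
#' @param fst Balding--Nichols divergence parameter in (0, 1): species allele
#'   frequencies are Beta-distributed around a shared ancestral frequency with
#'   variance `fst * p * (1 - p)`.
#' @param n_loci Number of biallelic loci.
#' @param n_ref_per_species Reference individuals genotyped per species.
#' @param mtdna_length Haplotype length in bp.
#' @param mtdna_divergence Expected substitutions/site between any two species'
#'   mtDNA haplotypes.
#' @param species Optional character vector of species names; defaults to a
#'   panel of North American duck species.
#' @param seed Integer master seed. Each generator derives its own
#'   deterministic substream via [substream_seed()], so a fixed seed implies
#'   byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_species = 8L, grid_side = 30L, range_centers = NULL,
                       range_radius = 10, abundance_meanlog = 1,
                       abundance_sdlog = 1, fst = 0.3, n_loci = 2000L,
                       n_ref_per_species = 10L, mtdna_length = 650L,
                       mtdna_divergence = 0.05, species = NULL, seed = 1L) {
  if (!is_count(n_species, 2L)) dh_stop("n_species must be an integer >= 2", "dh_config_error")
  if (!is_count(grid_side)) dh_stop("grid_side must be an integer >= 1", "dh_config_error")
  if (!is_count(n_loci)) dh_stop("n_loci must be an integer >= 1", "dh_config_error")
  if (!is_count(n_ref_per_species)) dh_stop("n_ref_per_species must be >= 1", "dh_config_error")
  if (!is_count(mtdna_length)) dh_stop("mtdna_length must be >= 1", "dh_config_error")
  if (!(is.numeric(fst) && length(fst) == 1L && fst > 0 && fst < 1)) {
    dh_stop("fst must lie strictly in (0, 1)", "dh_config_error")
  }
  if (!(is.numeric(mtdna_divergence) && mtdna_divergence >= 0)) {
    dh_stop("mtdna_divergence must be >= 0", "dh_config_error")
  }
  if (!(is.numeric(range_radius) && range_radius > 0)) {
    dh_stop("range_radius must be > 0", "dh_config_error")
  }
  if (is.null(species)) {
    species <- if (n_species <= length(duck_species_panel)) {
      duck_species_panel[seq_len(n_species)]
    } else {
      c(duck_species_panel,
        sprintf("species_%02d", seq_len(n_species - length(duck_species_panel))))
    }
  }
  if (length(species) != n_species || anyDuplicated(species) > 0) {
    dh_stop("species must be n_species unique names", "dh_config_error")
  }
  if (is.null(range_centers)) {
    centre <- (grid_side + 1) / 2
    ring <- min(range_radius * 0.6, grid_side / 5)
    ang <- 2 * pi * (seq_len(n_species) - 1) / n_species
    range_centers <- cbind(centre + ring * cos(ang), centre + ring * sin(ang))
  }
  range_centers <- as.matrix(range_centers)
  if (nrow(range_centers) != n_species || ncol(range_centers) != 2L) {
    dh_stop("range_centers must be an n_species x 2 matrix", "dh_config_error")
  }
  structure(list(
    n_species = as.integer(n_species), grid_side = as.integer(grid_side),
    range_centers = range_centers, range_radius = range_radius,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    fst = fst, n_loci = as.integer(n_loci),
    n_ref_per_species = as.integer(n_ref_per_species),
    mtdna_length = as.integer(mtdna_length),
    mtdna_divergence = mtdna_divergence,
    species = species, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate per-species breeding-season abundance grids
#'
#' Each species occupies a hard circular footprint around its range centre;
#' inside the footprint, cell abundance is lognormal, outside it is zero. The
#' hard footprint makes areas of sympatry (cells where both species'
#' abundances exceed zero) unambiguous.
#'
#' @param cfg A [sim_config()].
#' @return Named list of `grid_side` x `grid_side` abundance matrices, one per
#'   species; entry `[x, y]` is the abundance in cell (x, y).
#' @export
gen_abundance_grids <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gs <- cfg$grid_side
  xs <- matrix(seq_len(gs), gs, gs)          # [x, y] = x
  ys <- matrix(seq_len(gs), gs, gs, byrow = TRUE)
  withr::with_seed(substream_seed(cfg$seed, "abundance"), {
    grids <- lapply(seq_len(cfg$n_species), function(k) {
      d2 <- (xs - cfg$range_centers[k, 1])^2 + (ys - cfg$range_centers[k, 2])^2
      inside <- d2 <= cfg$range_radius^2
      a <- matrix(0, gs, gs)
      a[inside] <- stats::rlnorm(sum(inside), cfg$abundance_meanlog,
                                 cfg$abundance_sdlog)
      a
    })
    names(grids) <- cfg$species
    grids
  })
}

#' Generate parental reference genotypes under a Balding--Nichols model
#'
#' Per locus, an ancestral reference-allele frequency is drawn from
#' Uniform(0.05, 0.95); each species' frequency is Beta-distributed with mean
#' equal to the ancestral frequency and variance `fst * p * (1 - p)`; reference
#' individuals carry Binomial(2, species frequency) allele counts.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (individuals x loci integer matrix of allele
#'   dosages 0/1/2), `species` (species of each row), `true_freqs`
#'   (`n_species` x `n_loci` matrix of simulated species allele frequencies),
#'   and `loci` (data frame of locus metadata: locus_id, rad_locus, chrom,
#'   pos, ref, alt).
#' @export
gen_parental_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$n_species; L <- cfg$n_loci; nr <- cfg$n_ref_per_species
  withr::with_seed(substream_seed(cfg$seed, "genotypes"), {
    p <- stats::runif(L, 0.05, 0.95)
    ratio <- (1 - cfg$fst) / cfg$fst
    f <- matrix(stats::rbeta(K * L, rep(p * ratio, each = K),
                             rep((1 - p) * ratio, each = K)), K, L)
    rownames(f) <- cfg$species
    geno <- do.call(rbind, lapply(seq_len(K), function(k) {
      matrix(stats::rbinom(nr * L, 2L, rep(f[k, ], each = nr)), nr, L)
    }))
    species <- rep(cfg$species, each = nr)
    rownames(geno) <- paste0(species, "_ref", rep(sprintf("%02d", seq_len(nr)), K))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    loci <- data.frame(
      locus_id = sprintf("loc%05d", seq_len(L)),
      rad_locus = sprintf("rad%05d", seq_len(L)),
      chrom = paste0("chr", 1L + (seq_len(L) - 1L) %% 33L),
      pos = 100L * seq_len(L),
      ref = ref, alt = alt, stringsAsFactors = FALSE
    )
    colnames(geno) <- loci$locus_id
    colnames(f) <- loci$locus_id
    list(genotypes = geno, species = species, true_freqs = f,
         ancestral_freqs = p, loci = loci)
  })
}

hybrid_classes <- c("F1", "F2_backcross", "later_backcross", "parental")

#' Generate one hybrid (or parental) genotype with its truth label
#'
#' Allele-dosage rows are drawn per locus from the two parental species'
#' allele frequencies according to the pedigree: an F1 takes one allele from
#' each species; an F2 backcross takes one allele from the recurrent
#' (backcross) parent `species_a` and one from an F1 gamete; a later backcross
#' backcrosses an F2 backcross to `species_a` again. Expected ancestry of
#' `species_a` is 0.5, 0.75 and 0.875 respectively. Loci are unlinked, so
#' gametes mix the two lineages independently per locus.
#'
#' @param class One of `"F1"`, `"F2_backcross"`, `"later_backcross"`,
#'   `"parental"`.
#' @param species_a,species_b Parental species (rownames of `freqs`). For
#'   backcross classes `species_a` is the recurrent parent; for `"parental"`
#'   both must be the same species.
#' @param freqs Species x loci allele-frequency matrix (e.g.
#'   `gen_parental_genotypes()$true_freqs`).
#' @param seed Integer seed.
#' @param id Specimen id; generated if `NULL`.
#' @param sire,dam Which of the two species is father/mother (truth label
#'   only; defaults `species_a`/`species_b`).
#' @return List with `genotype` (integer dosage vector) and `label` (one-row
#'   data frame: specimen_id, species_a, species_b, true_class, true_sire,
#'   true_dam).
#' @export
gen_hybrid_genotypes <- function(class, species_a, species_b, freqs, seed,
                                 id = NULL, sire = species_a, dam = species_b) {
  if (!class %in% hybrid_classes) {
    dh_stop(sprintf("unknown hybrid class '%s'", class), "dh_config_error")
  }
  if (!all(c(species_a, species_b) %in% rownames(freqs))) {
    dh_stop("species_a/species_b must be rownames of freqs", "dh_config_error")
  }
  if (class == "parental" && species_a != species_b) {
    dh_stop("parental simulants require species_a == species_b", "dh_config_error")
  }
  if (!all(c(sire, dam) %in% c(species_a, species_b))) {
    dh_stop("sire and dam must be among {species_a, species_b}", "dh_config_error")
  }
  fa <- freqs[species_a, ]; fb <- freqs[species_b, ]
  probs <- switch(class,
    parental        = list(fa, fa),
    F1              = list(fa, fb),
    F2_backcross    = list(fa, (fa + fb) / 2),
    later_backcross = list(fa, (3 * fa + fb) / 4)
  )
  L <- length(fa)
  g <- withr::with_seed(seed, {
    stats::rbinom(L, 1L, probs[[1]]) + stats::rbinom(L, 1L, probs[[2]])
  })
  names(g) <- colnames(freqs)
  if (is.null(id)) id <- sprintf("hyb_%s_%d", class, seed %% 100000L)
  label <- data.frame(
    specimen_id = id, species_a = species_a, species_b = species_b,
    true_class = class, true_sire = sire, true_dam = dam,
    stringsAsFactors = FALSE
  )
  list(genotype = g, label = label)
}

mutate_sites <- function(chars, sites) {
  bases <- c("A", "C", "G", "T")
  for (s in sites) chars[s] <- sample(setdiff(bases, chars[s]), 1L)
  chars
}

#' Generate species-diagnostic mtDNA haplotypes
#'
#' One ancestral sequence is mutated independently per species at
#' `mtdna_divergence * mtdna_length / 2` uniformly placed sites, so any two
#' species differ at about `mtdna_divergence * mtdna_length` sites.
#' Within-species reference haplotypes carry at most one private mutation
#' each (pairwise within-species difference <= 2 sites).
#'
#' @param cfg A [sim_config()]. A warning is emitted when the expected number
#'   of between-species differences falls below 5, where distance-based
#'   maternal assignment becomes unreliable; `mtdna_divergence = 0` is allowed
#'   as a degenerate case (assignment must then report ambiguity).
#' @return Object of class `mtdna_set`: list with `species_seq` (named
#'   character vector of species base haplotypes), `refs` (data frame: id,
#'   species, sequence), and the generating parameters.
#' @export
gen_mtdna <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$mtdna_length
  div <- cfg$mtdna_divergence
  if (div > 0 && div * L < 5) {
    warning("expected between-species mtDNA differences < 5; ",
            "maternal assignment may be ambiguous")
  }
  withr::with_seed(substream_seed(cfg$seed, "mtdna"), {
    anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    n_mut <- round(div * L / 2)
    species_chars <- lapply(cfg$species, function(s) {
      if (n_mut == 0) anc else mutate_sites(anc, sample.int(L, n_mut))
    })
    names(species_chars) <- cfg$species
    refs <- do.call(rbind, lapply(cfg$species, function(s) {
      seqs <- vapply(seq_len(cfg$n_ref_per_species), function(i) {
        ch <- species_chars[[s]]
        if (stats::rbinom(1L, 1L, 0.5) == 1L) ch <- mutate_sites(ch, sample.int(L, 1L))
        paste(ch, collapse = "")
      }, character(1))
      data.frame(id = paste0(s, "_mt", sprintf("%02d", seq_len(cfg$n_ref_per_species))),
                 species = s, sequence = seqs, stringsAsFactors = FALSE)
    }))
    structure(list(
      species_seq = vapply(species_chars, paste, character(1), collapse = ""),
      refs = refs, length = L, divergence = div
    ), class = "mtdna_set")
  })
}

#' Generate the mtDNA haplotype a hybrid inherits from its dam
#'
#' The hybrid carries its true dam's species haplotype, plus at most one
#' private mutation.
#'
#' @param mt An `mtdna_set` from [gen_mtdna()].
#' @param dam Dam species name.
#' @param seed Integer seed.
#' @return A single haplotype string.
#' @export
gen_hybrid_mtdna <- function(mt, dam, seed) {
  stopifnot(inherits(mt, "mtdna_set"))
  if (!dam %in% names(mt$species_seq)) {
    dh_stop(sprintf("unknown dam species '%s'", dam), "dh_config_error")
  }
  withr::with_seed(seed, {
    ch <- strsplit(mt$species_seq[[dam]], "")[[1]]
    if (stats::rbinom(1L, 1L, 0.5) == 1L) ch <- mutate_sites(ch, sample.int(length(ch), 1L))
    paste(ch, collapse = "")
  })
}

#' Sample hybrid parental pairs from abundance-overlap weights
#'
#' Draws `n` hybrid combinations i.i.d. from the categorical distribution
#' proportional to `weight * enrichment`, emulating an observed sample of
#' hunter-shot hybrids whose frequencies track breeding-range abundance
#' overlap, with optional per-pair enrichment.
#'
#' @param weights Either the data frame returned by [compute_pair_weights()]
#'   or a named non-negative numeric vector of pair weights.
#' @param n Number of hybrids to draw (>= 1).
#' @param enrichment Optional named numeric multipliers (default 1 for every
#'   pair).
#' @param seed Integer seed.
#' @return Character vector of `n` sampled pair keys.
#' @export
gen_hybrid_sample <- function(weights, n, enrichment = NULL, seed = 1L) {
  if (is.data.frame(weights)) {
    w <- stats::setNames(weights$w, weights$pair)
  } else {
    w <- weights
  }
  if (is.null(names(w))) dh_stop("weights must be named", "dh_config_error")
  if (any(w < 0)) dh_stop("weights must be non-negative", "dh_config_error")
  if (!is_count(n)) dh_stop("n must be an integer >= 1", "dh_config_error")
  mult <- rep(1, length(w)); names(mult) <- names(w)
  if (!is.null(enrichment)) {
    unknown <- setdiff(names(enrichment), names(w))
    if (length(unknown)) {
      dh_stop(paste("enrichment names not in weights:",
                    paste(unknown, collapse = ", ")), "dh_config_error")
    }
    mult[names(enrichment)] <- enrichment
  }
  prob <- w * mult
  if (sum(prob) <= 0) dh_stop("all pair weights are zero", "dh_config_error")
  withr::with_seed(seed, sample(names(w), n, replace = TRUE, prob = prob))
}
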