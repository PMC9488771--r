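# Independent brute-force oracles and fixture builders used across tests.
# Each oracle re-derives the expected result by direct enumeration or
# explicit loops, independently of the package's implementation path.

# Random genotype matrix with controllable missingness and flag rate.
random_genotype_matrix <- function(n_ind, n_loci, p_missing = 0.15,
                                   p_flag = 0.05, seed = 1) {
  withr::with_seed(seed, {
    gm <- matrix(sample(0:2, n_ind * n_loci, replace = TRUE), n_ind, n_loci)
    gm[matrix(runif(n_ind * n_loci) < p_missing, n_ind)] <- NA
    flags <- matrix(runif(n_ind * n_loci) < p_flag, n_ind, n_loci) & !is.na(gm)
    dimnames(gm) <- dimnames(flags) <-
      list(sprintf("ind%02d", seq_len(n_ind)), sprintf("L%03d", seq_len(n_loci)))
    list(gm = gm, flags = flags)
  })
}

# Explicit-loop re-implementation of the wsu filtering rules.
naive_filter_wsu <- function(gm, flags, max_missing = 0.20, max_flagged = 0.05,
                             min_genotyped = 0.75) {
  keep_l <- character()
  for (l in colnames(gm)) {
    n_miss <- 0; n_flag <- 0
    for (i in rownames(gm)) {
      if (is.na(gm[i, l])) n_miss <- n_miss + 1
      if (flags[i, l]) n_flag <- n_flag + 1
    }
    if (n_miss / nrow(gm) <= max_missing && n_flag / nrow(gm) <= max_flagged) {
      keep_l <- c(keep_l, l)
    }
  }
  keep_i <- character()
  for (i in rownames(gm)) {
    n_geno <- 0
    for (l in keep_l) if (!is.na(gm[i, l])) n_geno <- n_geno + 1
    if (length(keep_l) > 0 && n_geno / length(keep_l) >= min_genotyped) {
      keep_i <- c(keep_i, i)
    }
  }
  list(loci = keep_l, individuals = keep_i)
}

# Explicit-loop re-implementation of the cornell filtering rules.
naive_filter_cornell <- function(gm, loci, min_presence = 0.80,
                                 max_missing = 0.25, drop_z = TRUE,
                                 one_snp = TRUE) {
  keep_l <- colnames(gm)
  if (one_snp) {
    seen <- character(); first <- character()
    ord <- order(loci$rad_locus, loci$pos)
    for (j in ord) {
      if (!loci$rad_locus[j] %in% seen) {
        seen <- c(seen, loci$rad_locus[j])
        first <- c(first, loci$locus_id[j])
      }
    }
    keep_l <- intersect(keep_l, first)
  }
  pres <- function(l, inds) {
    n <- 0
    for (i in inds) if (!is.na(gm[i, l])) n <- n + 1
    n / length(inds)
  }
  keep_l <- keep_l[vapply(keep_l, pres, numeric(1), inds = rownames(gm)) >= min_presence]
  keep_i <- character()
  for (i in rownames(gm)) {
    n_miss <- 0
    for (l in keep_l) if (is.na(gm[i, l])) n_miss <- n_miss + 1
    if (length(keep_l) > 0 && n_miss / length(keep_l) <= max_missing) {
      keep_i <- c(keep_i, i)
    }
  }
  keep_l <- keep_l[vapply(keep_l, pres, numeric(1), inds = keep_i) >= min_presence]
  if (drop_z) {
    z <- loci$locus_id[!is.na(loci$chrom) & loci$chrom == "Z"]
    keep_l <- setdiff(keep_l, z)
  }
  list(loci = keep_l, individuals = keep_i)
}

# Fisher 2x2 oracle: enumerate every table with the observed margins and sum
# the probabilities (via products of binomial coefficients) of tables no more
# probable than the observed one.
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2]); n <- sum(tab)
  p_table <- function(a) {
    exp(lchoose(c1, a) + lchoose(c2, r1 - a) - lchoose(n, r1))
  }
  as <- max(0, r1 - c2):min(r1, c1)
  probs <- vapply(as, p_table, numeric(1))
  p_obs <- p_table(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Dense grid-search oracle for the two-species supervised-admixture MLE.
grid_search_q <- function(g, f2, step = 0.001) {
  use <- !is.na(g)
  g <- g[use]; f2 <- f2[, use, drop = FALSE]
  qa <- seq(0, 1, by = step)
  ll <- vapply(qa, function(q) {
    p <- q * f2[1, ] + (1 - q) * f2[2, ]
    sum(g * log(p) + (2 - g) * log(1 - p))
  }, numeric(1))
  qa[which.max(ll)]
}

# Exhaustive multinomial enumeration: exact per-category mean and population
# standard deviation of counts for up to 3 categories.
enum_multinomial_musd <- function(p, n) {
  k <- length(p)
  stopifnot(k <= 3)
  grid <- expand.grid(rep(list(0:n), k - 1))
  grid <- grid[rowSums(grid) <= n, , drop = FALSE]
  counts <- cbind(as.matrix(grid), n - rowSums(grid))
  logp <- apply(counts, 1, function(x) {
    lgamma(n + 1) - sum(lgamma(x + 1)) + sum(x * log(p))
  })
  w <- exp(logp)
  stopifnot(abs(sum(w) - 1) < 1e-12)
  mu <- colSums(counts * w)
  ex2 <- colSums(counts^2 * w)
  list(mu = mu, sigma = sqrt(ex2 - mu^2))
}

# Small allele-frequency panel with near-fixed differences between species.
diagnostic_panel <- function(n_loci = 100, f_hi = 0.99) {
  f <- rbind(rep(f_hi, n_loci), rep(1 - f_hi, n_loci))
  rownames(f) <- c("spA", "spB")
  colnames(f) <- sprintf("L%03d", seq_len(n_loci))
  f
}

random_sequence <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}
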