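# Supervised ancestry estimation. Parental reference panels fix the
# per-species allele frequencies; only the ancestry fractions q of each
# putative hybrid are estimated, by an EM algorithm maximising the binomial
# genotype likelihood on the K-simplex. The largest fraction ("maximum
# assignment probability") drives hybrid-class calling: up to 64% is an F1,
# the bands above correspond to pedigree expectations for F2 (0.75) and
# later (0.875) backcrosses.

#' Estimate per-species allele frequencies from reference individuals
#'
#' Frequencies are simple allele-count tallies, `f = count / (2 * genotyped
#' individuals)`, with missing genotypes excluded from the denominator, then
#' clamped to `[eps, 1 - eps]` so that no locus contributes an infinite
#' log-likelihood. Loci lacking a genotyped reference individual for any
#' species are dropped and recorded.
#'
#' @param gm Integer matrix (individuals x loci) of allele dosages 0/1/2,
#'   `NA` missing.
#' @param species Character vector, species of each row of `gm`.
#' @param eps Frequency clamp (default 1e-4).
#' @return Object of class `allele_freq_panel`: list with `f` (K x L
#'   frequency matrix), `species`, `loci` (retained locus names) and
#'   `dropped_loci`.
#' @export
estimate_allele_freqs <- function(gm, species, eps = 1e-4) {
  stopifnot(is.matrix(gm), length(species) == nrow(gm))
  sp <- sort(unique(species))
  if (length(sp) < 2) dh_stop("need references for at least 2 species", "dh_input_error")
  counts <- rowsum((!is.na(gm)) * 1, species)     # genotyped individuals per species x locus
  if (any(rowSums(counts) == 0)) {
    bad <- rownames(counts)[rowSums(counts) == 0]
    dh_stop(paste("species with zero genotyped reference individuals:",
                  paste(bad, collapse = ", ")), "dh_input_error")
  }
  gm0 <- gm; gm0[is.na(gm0)] <- 0L
  tall <- rowsum(gm0, species)
  keep <- colSums(counts == 0) == 0
  f <- tall[, keep, drop = FALSE] / (2 * counts[, keep, drop = FALSE])
  f <- pmin(pmax(f, eps), 1 - eps)
  structure(list(f = f[sp, , drop = FALSE], species = sp,
                 loci = colnames(gm)[keep],
                 dropped_loci = colnames(gm)[!keep], eps = eps),
            class = "allele_freq_panel")
}

#' @export
print.allele_freq_panel <- function(x, ...) {
  cat(sprintf("allele_freq_panel: %d species x %d loci (%d dropped)\n",
              length(x$species), length(x$loci), length(x$dropped_loci)))
  invisible(x)
}

#' Supervised admixture: estimate ancestry fractions for one individual
#'
#' Maximises the log-likelihood
#' `sum_l [ g_l log(p_l) + (2 - g_l) log(1 - p_l) ]` with
#' `p_l = sum_k q_k f_kl` over the K-simplex, by the EM update
#' `q_k <- (1 / 2L') sum_l [ g_l q_k f_kl / p_l + (2 - g_l) q_k (1 - f_kl) / (1 - p_l) ]`
#' across the L' non-missing loci. The likelihood is concave in q for fixed
#' reference frequencies, so a single deterministic run from the uniform
#' start suffices; the log-likelihood is asserted non-decreasing at every
#' iteration.
#'
#' @param g Integer dosage vector (0/1/2, `NA` missing), named by locus.
#' @param panel An [estimate_allele_freqs()] panel (or a bare K x L frequency
#'   matrix with species rownames).
#' @param tol Convergence tolerance on the log-likelihood improvement
#'   (default 1e-6).
#' @param max_iter Maximum EM iterations (default 2000); non-convergence
#'   yields a warning and the best iterate.
#' @return Object of class `ancestry_fit`: list with `q` (named simplex
#'   vector), `loglik`, `n_iter`, `converged`, `n_loci_used`.
#' @export
supervised_admixture <- function(g, panel, tol = 1e-6, max_iter = 2000L) {
  f <- if (inherits(panel, "allele_freq_panel")) panel$f else panel
  stopifnot(is.matrix(f), !is.null(rownames(f)))
  if (!is.null(names(g)) && !is.null(colnames(f))) {
    common <- intersect(names(g), colnames(f))
    g <- g[common]; f <- f[, common, drop = FALSE]
  }
  use <- !is.na(g)
  if (!any(use)) dh_stop("all genotypes missing for this individual", "dh_input_error")
  g <- as.numeric(g[use])
  f <- f[, use, drop = FALSE]
  K <- nrow(f); L <- ncol(f)
  one_f <- 1 - f
  g2 <- 2 - g
  q <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    p <- as.vector(q %*% f)
    ll <- sum(g * log(p) + g2 * log1p(-p))
    stopifnot(ll >= ll_old - 1e-8)      # EM monotonicity
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
    # q_k <- q_k/(2L) * [ sum_l f_kl g_l/p_l + sum_l (1-f_kl)(2-g_l)/(1-p_l) ]
    q <- q * as.vector(f %*% (g / p) + one_f %*% (g2 / (1 - p))) / (2 * L)
    q <- q / sum(q)                     # guard numerical drift off the simplex
  }
  if (!converged) {
    warning(sprintf("supervised_admixture did not converge in %d iterations", max_iter))
  }
  names(q) <- rownames(f)
  structure(list(q = q, loglik = ll_old, n_iter = iter, converged = converged,
                 n_loci_used = L), class = "ancestry_fit")
}

#' @export
print.ancestry_fit <- function(x, ...) {
  top <- sort(x$q, decreasing = TRUE)[1:2]
  cat(sprintf("ancestry_fit: max q = %.3f (%s), loglik = %.2f, %d loci, %d EM iterations%s\n",
              top[1], names(top)[1], x$loglik, x$n_loci_used, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Assign the parental pair of a hybrid from its ancestry fractions
#'
#' The two species with the largest ancestry fractions, ordered by fraction
#' (descending) with ties broken lexicographically by species name.
#'
#' @param q Named ancestry vector (length K >= 2).
#' @return List with `species_hi`, `species_lo`, `pair` (canonical key) and
#'   `q_pair` (combined ancestry of the pair).
#' @export
assign_parent_pair <- function(q) {
  stopifnot(!is.null(names(q)), length(q) >= 2)
  ord <- order(-q, names(q))
  hi <- names(q)[ord[1]]; lo <- names(q)[ord[2]]
  list(species_hi = hi, species_lo = lo, pair = pair_key(hi, lo),
       q_pair = unname(q[ord[1]] + q[ord[2]]))
}

#' Call the hybrid class from the maximum assignment probability
#'
#' A maximum single-species ancestry fraction of up to 64% is called F1
#' (an F1 with 51%/49% loci is "51%"); up to 0.875 is an F2 backcross (the
#' pedigree expectation for an F2 backcross is 75%); below `parental_min` a
#' later backcross (pedigree expectation 87.5%); at or above `parental_min`,
#' parental.
#'
#' @param q Named ancestry vector, or a single maximum-assignment value.
#' @param f1_max F1 upper bound, inclusive (default 0.64).
#' @param f2_max F2-backcross upper bound, inclusive (default 0.875).
#' @param parental_min Parental lower bound, inclusive (default 0.95).
#' @return One of `"F1"`, `"F2_backcross"`, `"later_backcross"`,
#'   `"parental"`.
#' @export
call_hybrid_class <- function(q, f1_max = 0.64, f2_max = 0.875,
                              parental_min = 0.95) {
  m <- max(q)
  if (m <= f1_max) "F1"
  else if (m <= f2_max) "F2_backcross"
  else if (m < parental_min) "later_backcross"
  else "parental"
}

#' Run supervised ancestry over a matrix of putative hybrids
#'
#' Convenience wrapper producing one row per individual with its ancestry
#' fractions, maximum assignment probability, parental pair and hybrid
#' class.
#'
#' @param gm Integer dosage matrix (individuals x loci).
#' @param panel An [estimate_allele_freqs()] panel.
#' @inheritParams supervised_admixture
#' @inheritParams call_hybrid_class
#' @return Data frame with columns `individual_id`, one `q_<species>` per
#'   panel species, `max_assignment`, `parent_pair`, `q_pair`,
#'   `hybrid_class`, `loglik`, `converged`.
#' @export
run_ancestry <- function(gm, panel, tol = 1e-6, max_iter = 2000L,
                         f1_max = 0.64, f2_max = 0.875, parental_min = 0.95) {
  stopifnot(is.matrix(gm), !is.null(rownames(gm)))
  rows <- lapply(rownames(gm), function(id) {
    fit <- supervised_admixture(gm[id, ], panel, tol = tol, max_iter = max_iter)
    pp <- assign_parent_pair(fit$q)
    out <- data.frame(individual_id = id, stringsAsFactors = FALSE)
    for (s in names(fit$q)) out[[paste0("q_", s)]] <- unname(fit$q[s])
    out$max_assignment <- max(fit$q)
    out$parent_pair <- pp$pair
    out$q_pair <- pp$q_pair
    out$hybrid_class <- call_hybrid_class(fit$q, f1_max, f2_max, parental_min)
    out$loglik <- fit$loglik
    out$converged <- fit$converged
    out
  })
  do.call(rbind, rows)
}

#' Histogram of maximum assignment probabilities
#'
#' Bins the maximum single-species ancestry fractions of a set of hybrids
#' over [0.5, 1]; on mixed F1/backcross samples the distribution is bimodal
#' with modes near 0.5 and 0.75.
#'
#' @param max_assignment Numeric vector of maximum assignment probabilities
#'   (or a data frame from [run_ancestry()] with a `max_assignment` column).
#' @param binwidth Bin width over [0.5, 1] (default 0.05).
#' @return Data frame with `bin_lo`, `bin_hi`, `count`; counts sum to the
#'   number of individuals.
#' @export
assignment_histogram <- function(max_assignment, binwidth = 0.05) {
  if (is.data.frame(max_assignment)) max_assignment <- max_assignment$max_assignment
  if (length(max_assignment) == 0) dh_stop("no results to bin", "dh_input_error")
  breaks <- seq(0.5, 1, by = binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  x <- pmin(pmax(max_assignment, 0.5), 1)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, left.open = FALSE)
  idx <- pmin(idx, length(breaks) - 1L)
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
             count = tabulate(idx, nbins = length(breaks) - 1L))
}
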