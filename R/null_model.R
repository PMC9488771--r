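# Abundance-overlap null model for hybrid-pair frequencies. Pair weights
# combine log-transformed breeding-season abundances over cells of sympatry;
# the observed number of hybrids is resampled from the weight vector (127
# draws, 1000 replicates by default) to give an expected mean and standard
# deviation per pair, and standardized effect sizes (O - mu) / sigma outside
# +/-1.645 mark combinations more or less frequent than the 90% interval of
# the null expects.

#' Null-model configuration
#'
#' @param n_draws Hybrids drawn per replicate (default 127, the size of the
#'   observed sample the model is calibrated to).
#' @param n_reps Resampling replicates (default 1000).
#' @param threshold Standardized-effect-size cut marking deviation from the
#'   null (default 1.645, the two-sided 90% interval).
#' @param combiner How per-cell log abundances of the two species combine
#'   into a pair weight: `"product_log"` (default; both species must be
#'   present and the product rewards joint abundance), `"sum_log"`, or
#'   `"min_log"`.
#' @param log_offset Offset inside the log, `log(offset + abundance)`
#'   (default 1, so zero-abundance cells are well-defined).
#' @param seed Integer seed for the resampling.
#' @return Object of class `null_config`.
#' @export
null_config <- function(n_draws = 127L, n_reps = 1000L, threshold = 1.645,
                        combiner = c("product_log", "sum_log", "min_log"),
                        log_offset = 1, seed = 1L) {
  combiner <- match.arg(combiner)
  if (!is_count(n_draws)) dh_stop("n_draws must be an integer >= 1", "dh_config_error")
  if (!is_count(n_reps, 2L)) dh_stop("n_reps must be an integer >= 2", "dh_config_error")
  if (!(is.numeric(threshold) && threshold > 0)) {
    dh_stop("threshold must be > 0", "dh_config_error")
  }
  structure(list(n_draws = as.integer(n_draws), n_reps = as.integer(n_reps),
                 threshold = threshold, combiner = combiner,
                 log_offset = log_offset, seed = as.integer(seed)),
            class = "null_config")
}

#' Abundance-overlap weights for all species pairs
#'
#' For every unordered species pair, sympatric cells are those where both
#' abundances exceed zero; the weight sums a per-cell combination of the
#' log-transformed abundances over those cells. All pairs are enumerated,
#' including pairs with zero overlap (weight 0).
#'
#' @param grids Named list of equal-dimension abundance matrices, one per
#'   species (e.g. from [gen_abundance_grids()]).
#' @param cfg A [null_config()] (supplies `combiner` and `log_offset`).
#' @return Data frame with `species_i`, `species_j`, `pair`, `w`,
#'   `n_sympatric_cells`; one row per unordered pair, `K (K - 1) / 2` rows
#'   in total.
#' @export
compute_pair_weights <- function(grids, cfg = null_config()) {
  stopifnot(is.list(grids), !is.null(names(grids)))
  if (length(grids) < 2) dh_stop("need at least 2 species", "dh_input_error")
  dims <- vapply(grids, dim, integer(2))
  if (any(dims != dims[, 1])) dh_stop("grids must share dimensions", "dh_input_error")
  empty <- vapply(grids, function(g) all(g <= 0), logical(1))
  if (any(empty)) {
    dh_stop(paste("species with empty abundance grid:",
                  paste(names(grids)[empty], collapse = ", ")), "dh_input_error")
  }
  if (any(vapply(grids, function(g) any(g < 0), logical(1)))) {
    dh_stop("abundances must be non-negative", "dh_input_error")
  }
  pairs <- utils::combn(names(grids), 2)
  rows <- apply(pairs, 2, function(pr) {
    ai <- grids[[pr[1]]]; aj <- grids[[pr[2]]]
    sym <- ai > 0 & aj > 0
    li <- log(cfg$log_offset + ai[sym]); lj <- log(cfg$log_offset + aj[sym])
    w <- switch(cfg$combiner,
                product_log = sum(li * lj),
                sum_log = sum(li + lj),
                min_log = sum(pmin(li, lj)))
    data.frame(species_i = pr[1], species_j = pr[2],
               pair = pair_key(pr[1], pr[2]), w = w,
               n_sympatric_cells = sum(sym), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

weights_vector <- function(weights) {
  if (is.data.frame(weights)) stats::setNames(weights$w, weights$pair) else weights
}

#' Expected per-pair hybrid counts under the abundance-overlap null
#'
#' The default `"resample"` method draws `n_draws` hybrids i.i.d. from the
#' categorical distribution proportional to the weights, `n_reps` times, and
#' reports the per-pair mean and sample standard deviation (denominator
#' `n_reps - 1`) of the counts. `method = "exact"` returns the multinomial
#' closed form (`mu = n p`, `sigma = sqrt(n p (1 - p))`, population form),
#' which the resampling converges to.
#'
#' @param weights Pair weights ([compute_pair_weights()] data frame or named
#'   vector); must not be all zero.
#' @param cfg A [null_config()].
#' @param method `"resample"` or `"exact"`.
#' @return Data frame with `pair`, `w`, `mu`, `sigma`.
#' @export
simulate_expected <- function(weights, cfg = null_config(),
                              method = c("resample", "exact")) {
  method <- match.arg(method)
  w <- weights_vector(weights)
  if (any(w < 0)) dh_stop("weights must be non-negative", "dh_input_error")
  if (sum(w) <= 0) dh_stop("all pair weights are zero", "dh_input_error")
  p <- w / sum(w)
  if (method == "exact") {
    mu <- cfg$n_draws * p
    sigma <- sqrt(cfg$n_draws * p * (1 - p))
  } else {
    counts <- withr::with_seed(cfg$seed, {
      stats::rmultinom(cfg$n_reps, cfg$n_draws, p)
    })
    mu <- rowMeans(counts)
    sigma <- apply(counts, 1, stats::sd)
  }
  data.frame(pair = names(w), w = unname(w), mu = unname(mu),
             sigma = unname(sigma), stringsAsFactors = FALSE)
}

#' Standardized effect sizes and deviation classification
#'
#' `SES = (O - mu) / sigma` per pair; pairs with `SES` beyond the threshold
#' are classified `"over"`/`"under"`, otherwise `"within"`. Pairs with zero
#' simulated spread have no defined SES: they are `"within"` when the
#' observation equals the expectation, `"over"` (flagged) when hybrids were
#' observed despite zero weight, and `"no_expectation"` otherwise.
#'
#' @param observed Named integer vector of observed hybrid counts per pair
#'   key (pairs absent from the vector count 0), or a data frame with
#'   columns `pair` and `count`.
#' @param sims Data frame from [simulate_expected()].
#' @param cfg A [null_config()]; a warning is issued when the observed total
#'   differs from `cfg$n_draws`.
#' @return Data frame with `pair`, `observed`, `mu`, `sigma`, `ses`,
#'   `classification`, `zero_weight_flag`.
#' @export
standardized_effects <- function(observed, sims, cfg = null_config()) {
  if (is.data.frame(observed)) {
    observed <- stats::setNames(observed$count, observed$pair)
  }
  unknown <- setdiff(names(observed), sims$pair)
  if (length(unknown)) {
    dh_stop(paste("observed pairs missing from the simulated set:",
                  paste(unknown, collapse = ", ")), "dh_input_error")
  }
  O <- stats::setNames(rep(0, nrow(sims)), sims$pair)
  O[names(observed)] <- observed
  if (sum(O) != cfg$n_draws) {
    warning(sprintf("observed total (%d) differs from configured n_draws (%d)",
                    sum(O), cfg$n_draws))
  }
  ses <- ifelse(sims$sigma > 0, (O - sims$mu) / sims$sigma, NA_real_)
  cls <- ifelse(is.na(ses),
                ifelse(O == sims$mu, "within",
                       ifelse(O > sims$mu, "over", "no_expectation")),
                ifelse(ses > cfg$threshold, "over",
                       ifelse(ses < -cfg$threshold, "under", "within")))
  data.frame(pair = sims$pair, observed = unname(O), mu = sims$mu,
             sigma = sims$sigma, ses = ses, classification = cls,
             zero_weight_flag = sims$w == 0 & O > 0,
             stringsAsFactors = FALSE)
}

#' Deviation report for all hybrid combinations
#'
#' Rows sorted by absolute standardized effect size (undefined SES last),
#' ready for mirrored-phylogeny style plotting; an optional Newick tree is
#' passed through untouched for external renderers.
#'
#' @param results Data frame from [standardized_effects()].
#' @param tree Optional Newick string attached as the `"newick"` attribute.
#' @return The sorted data frame.
#' @export
deviation_report <- function(results, tree = NULL) {
  stopifnot(is.data.frame(results),
            all(c("pair", "ses", "classification") %in% names(results)))
  ord <- order(!is.finite(results$ses), -abs(results$ses), results$pair)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(tree)) attr(out, "newick") <- tree
  out
}
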