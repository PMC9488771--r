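# Maternal species assignment from mtDNA. A hybrid's dam is the species
# whose reference haplotypes are nearest in (uncorrected) p-distance; the
# sire is then the other member of the nuclear parental pair. A margin rule
# (gap between best and second-best species) operationalises "unambiguous"
# assignment: too small a margin is an error, never a guess.

to_chars <- function(s) {
  if (length(s) == 1L && is.character(s) && nchar(s) > 1L) {
    s <- strsplit(s, "")[[1]]
  }
  ch <- toupper(as.character(s))
  bad <- setdiff(unique(ch), c("A", "C", "G", "T", "N", "-"))
  if (length(bad)) {
    dh_stop(paste("sequence contains characters outside {A,C,G,T,N,-}:",
                  paste(bad, collapse = ", ")), "dh_input_error")
  }
  ch
}

#' Uncorrected pairwise distance between two aligned sequences
#'
#' Mismatches divided by compared sites; any site with `N` or a gap in
#' either sequence is excluded from the comparison.
#'
#' @param s1,s2 Aligned sequences of equal length (strings or character
#'   vectors over A, C, G, T, N, -).
#' @return Numeric p-distance in [0, 1] with attributes `sites_compared` and
#'   `sites_excluded`. Zero comparable sites is an error.
#' @export
p_distance <- function(s1, s2) {
  c1 <- to_chars(s1); c2 <- to_chars(s2)
  if (length(c1) != length(c2)) {
    dh_stop("sequences must be aligned to equal length", "dh_input_error")
  }
  ok <- !(c1 %in% c("N", "-")) & !(c2 %in% c("N", "-"))
  if (!any(ok)) dh_stop("zero comparable sites between sequences", "dh_input_error")
  structure(mean(c1[ok] != c2[ok]),
            sites_compared = sum(ok), sites_excluded = sum(!ok))
}

ref_frame <- function(refs) {
  if (inherits(refs, "mtdna_set")) return(refs$refs)
  stopifnot(is.data.frame(refs), all(c("id", "species", "sequence") %in% names(refs)))
  refs
}

#' Assign the maternal species of a hybrid from its mtDNA haplotype
#'
#' Computes the mean p-distance from the query to each species' reference
#' haplotypes and assigns the nearest species. The margin (second-best minus
#' best mean distance) must reach `min_margin`, otherwise an ambiguity error
#' of class `dh_ambiguous` is raised. For species-diagnostic markers this
#' nearest-mean decision boundary coincides with tree-based clade embedding;
#' a substitution-corrected distance (via [ape::dist.dna()]) is available as
#' an option.
#'
#' @param query Query haplotype (string), or named character vector of one.
#' @param refs Reference haplotypes: a data frame with columns `id`,
#'   `species`, `sequence`, or an `mtdna_set` from [gen_mtdna()].
#' @param min_margin Minimum distance gap between best and second-best
#'   species (default 0.01 substitutions/site, an order of magnitude above
#'   typical within-species diversity).
#' @param hybrid_id Identifier recorded in the result.
#' @param model `"p"` for the uncorrected distance (default), or an
#'   evolutionary-model correction accepted by [ape::dist.dna()] (e.g.
#'   `"K80"`, `"TN93"`).
#' @return One-row data frame: `hybrid_id`, `mother_species`,
#'   `best_distance`, `margin`.
#' @export
assign_maternal <- function(query, refs, min_margin = 0.01,
                            hybrid_id = "query", model = "p") {
  rf <- ref_frame(refs)
  sp <- unique(rf$species)
  if (length(sp) < 2) dh_stop("references must span at least 2 species", "dh_input_error")
  if (any(nchar(rf$sequence) != nchar(rf$sequence[1])) ||
      nchar(query) != nchar(rf$sequence[1])) {
    dh_stop("query and references must be aligned to equal length", "dh_input_error")
  }
  if (model == "p") {
    d <- vapply(rf$sequence, function(s) as.numeric(p_distance(query, s)),
                numeric(1), USE.NAMES = FALSE)
  } else {
    seqs <- c(list(query = strsplit(tolower(query), "")[[1]]),
              stats::setNames(strsplit(tolower(rf$sequence), ""), rf$id))
    dm <- as.matrix(ape::dist.dna(ape::as.DNAbin(seqs), model = model,
                                  pairwise.deletion = TRUE))
    d <- dm["query", rf$id]
  }
  mean_d <- tapply(d, rf$species, mean)
  ord <- order(mean_d, names(mean_d))
  best <- names(mean_d)[ord[1]]
  margin <- unname(mean_d[ord[2]] - mean_d[ord[1]])
  if (margin < min_margin) {
    dh_stop(sprintf(
      "ambiguous maternal assignment for %s: margin %.4f below %.4f (best %s, next %s)",
      hybrid_id, margin, min_margin, best, names(mean_d)[ord[2]]),
      "dh_ambiguous")
  }
  data.frame(hybrid_id = hybrid_id, mother_species = best,
             best_distance = unname(mean_d[ord[1]]), margin = margin,
             stringsAsFactors = FALSE)
}

#' Maternal assignment across several mtDNA markers
#'
#' Markers sequenced from different mtDNA regions (e.g. control region and
#' COI) are aligned separately; the hybrid is assigned per marker and the
#' markers must agree, otherwise the assignment is ambiguous.
#'
#' @param queries List of query haplotypes, one per marker.
#' @param refs_list List of reference sets (as in [assign_maternal()]), one
#'   per marker, in the same order.
#' @inheritParams assign_maternal
#' @return One-row data frame as [assign_maternal()], with the smallest
#'   per-marker margin reported.
#' @export
assign_maternal_markers <- function(queries, refs_list, min_margin = 0.01,
                                    hybrid_id = "query", model = "p") {
  stopifnot(length(queries) == length(refs_list), length(queries) >= 1)
  per <- Map(function(q, r) assign_maternal(q, r, min_margin, hybrid_id, model),
             queries, refs_list)
  mothers <- vapply(per, function(x) x$mother_species, character(1))
  if (length(unique(mothers)) > 1) {
    dh_stop(sprintf("markers disagree on the maternal species of %s: %s",
                    hybrid_id, paste(unique(mothers), collapse = " vs ")),
            "dh_ambiguous")
  }
  out <- per[[which.min(vapply(per, function(x) x$margin, numeric(1)))]]
  out
}

#' Infer the sire as the non-maternal member of the parental pair
#'
#' @param parent_pair Character vector of the two parental species (or a
#'   canonical pair key from [pair_key()]).
#' @param maternal Maternal species; must be one of the pair, otherwise an
#'   inconsistency error of class `dh_inconsistent_parents` is raised and
#'   the specimen should be flagged for manual resolution (exclusion-based
#'   inference).
#' @return The sire species.
#' @export
infer_sire <- function(parent_pair, maternal) {
  if (length(parent_pair) == 1L && grepl(" x ", parent_pair, fixed = TRUE)) {
    parent_pair <- strsplit(parent_pair, " x ", fixed = TRUE)[[1]]
  }
  stopifnot(length(parent_pair) == 2L)
  if (!maternal %in% parent_pair) {
    dh_stop(sprintf(
      "maternal species '%s' is not a member of the parental pair (%s); specimen must be flagged",
      maternal, paste(parent_pair, collapse = ", ")),
      "dh_inconsistent_parents")
  }
  setdiff(parent_pair, maternal)[1]
}
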