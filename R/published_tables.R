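# Accessors for the published summary data bundled with the package: the
# pair-level siring tallies for 80 genetically resolved F1 hybrid ducks
# organised by winter phallus-length asymmetry, the 2x2 phallus/mass
# complementarity tables, the multi-season harvest-survey totals, and the
# flock associations reported for F1 males. These counts are inputs to the
# exact-test layer, bundled as plain CSV.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "duckhybrids")
  if (!nzchar(path)) dh_stop(sprintf("bundled data file missing: %s", file))
  path
}

#' Published pair-level siring counts for F1 hybrid ducks
#'
#' One row per parental combination: number of F1s, winter phallus
#' asymmetry in mm (some estimated by the log-log seasonal regression, see
#' `asymmetry_estimated`), counts of F1s sired by the longer- and
#' shorter-phallus species, and the published `section` grouping
#' (`"large"` asymmetries, about 40 mm or more, versus `"small"`).
#'
#' @return Data frame with columns `pair`, `section`, `n_f1`,
#'   `asymmetry_mm`, `asymmetry_estimated`, `sire_longer`, `sire_shorter`.
#' @export
siring_asymmetry_table <- function() {
  utils::read.csv(extdata("f1_siring_counts.csv"), stringsAsFactors = FALSE)
}

#' Published phallus/mass complementarity tables
#'
#' 2x2 counts of F1 hybrids with large phallus asymmetries, cross-classified
#' by whether the sire species is heavier than the dam species and whether
#' the sire species has the longer phallus. The `"all"` variant covers all
#' 59 such F1s; the `"reduced"` variant removes the American Wigeon
#' combinations with Mallard and Northern Pintail, which contradicted the
#' phallus-asymmetry assumption.
#'
#' @return Named list of two 2x2 integer matrices (`all`, `reduced`) with
#'   rows sire_heavier/dam_heavier and columns sire_longer/sire_shorter.
#' @export
complementarity_tables <- function() {
  df <- utils::read.csv(extdata("complementarity_counts.csv"),
                        stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    matrix(as.integer(df[i, 2:5]), 2, 2, byrow = TRUE, dimnames = list(
      c("sire_heavier", "dam_heavier"), c("sire_longer", "sire_shorter")))
  })
  names(out) <- df$variant
  out
}

#' Published multi-season harvest totals
#'
#' Hybrid and parental counts from 14 North American waterfowl harvest
#' seasons, used to compute the hybrid harvest rate.
#'
#' @return List with `hybrids`, `parentals`, `seasons`.
#' @export
harvest_survey_totals <- function() {
  df <- utils::read.csv(extdata("harvest_totals.csv"), stringsAsFactors = FALSE)
  list(hybrids = df$hybrids[1], parentals = df$parentals[1],
       seasons = df$seasons[1])
}

#' Published flock associations of male F1 hybrids
#'
#' Per-combination counts of F1 males reported flying in flocks of their
#' father versus mother species.
#'
#' @return Data frame with columns `pair`, `father_flock`, `mother_flock`.
#' @export
flock_association_table <- function() {
  utils::read.csv(extdata("flock_associations.csv"), stringsAsFactors = FALSE)
}
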