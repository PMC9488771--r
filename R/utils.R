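# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

dh_stop <- function(msg, class = "dh_error") {
  stop(structure(
    class = unique(c(class, "dh_error", "error", "condition")),
    list(message = msg, call = sys.call(-1))
  ))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

#' Derive a deterministic per-component sub-seed
#'
#' All stochastic stages draw their seed from the single configured seed plus
#' a component label, so any stage can be regenerated independently of the
#' others while a fixed global seed still implies byte-identical output.
#'
#' @param seed Integer master seed.
#' @param label Character component label.
#' @return A single integer below 2^31.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  ints <- utf8ToInt(label)
  h <- sum(ints * seq_along(ints)) %% 1000003
  as.integer(((abs(seed) %% 2147480000) * 1009 + h * 9176 + 1) %% 2147483629)
}

#' Canonical unordered species-pair key
#'
#' Hybrid combinations are unordered: `pair_key("B", "A")` and
#' `pair_key("A", "B")` both give `"A x B"`.
#'
#' @param a,b Character species names (vectorised).
#' @return Character vector of canonical pair labels.
#' @export
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = " x "), paste(b, a, sep = " x "))
}

# Species used by default in the simulator: the eight-species reference panel
# first, then the seven additional parentals of the larger panel.
duck_species_panel <- c(
  "Aix_sponsa", "Anas_platyrhynchos", "Anas_crecca_carolinensis",
  "Anas_acuta", "Spatula_clypeata", "Spatula_discors", "Mareca_strepera",
  "Mareca_americana",
  "Aythya_valisineria", "Lophodytes_cucullatus", "Bucephala_clangula",
  "Aythya_americana", "Anas_crecca_crecca", "Spatula_cyanoptera",
  "Mareca_penelope"
)
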