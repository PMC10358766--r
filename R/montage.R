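#' The 32-channel 10-20 montage used throughout the package
#'
#' Electrode labels, in canonical order, of the 32-channel international
#' 10-20 montage the models in this package expect. The label `"FC"` is kept
#' verbatim from the acquisition montage even though the standard 10-20 name
#' for that position is `"FC2"`; [match_montage()] accepts `"FC2"` (and any
#' case variant such as `"CP6"` for `"Cp6"`) as an alias.
#'
#' @return Character vector of 32 electrode labels.
#' @export
#' @examples
#' canonical_montage()
canonical_montage <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC", "Cz",
    "C4", "T8", "Cp6", "Cp2", "P4", "P8", "PO4", "O2")
}

# Case-insensitive canonical key for an electrode label, folding the
# documented alias FC2 -> FC.
montage_key <- function(x) {
  key <- toupper(trimws(x))
  key[key == "FC2"] <- "FC"
  key
}

#' Match channel names against a montage
#'
#' Resolves a set of channel names (e.g. a file header) against an expected
#' montage, tolerating case differences and the `FC`/`FC2` alias, and returns
#' the permutation that reorders the data columns into montage order.
#'
#' @param names Character vector of channel names as found in the input.
#' @param montage Expected electrode labels (default [canonical_montage()]).
#' @return Integer vector `idx` such that `names[idx]` matches `montage`
#'   position by position.
#' @export
match_montage <- function(names, montage = canonical_montage()) {
  key_have <- montage_key(names)
  key_want <- montage_key(montage)
  if (anyDuplicated(key_have)) {
    stop_stteeg(
      paste0("Duplicate channel names: ",
             paste(unique(names[duplicated(key_have)]), collapse = ", ")),
      "stteeg_montage_error")
  }
  idx <- match(key_want, key_have)
  if (anyNA(idx)) {
    stop_stteeg(
      paste0("Missing channels: ",
             paste(montage[is.na(idx)], collapse = ", ")),
      "stteeg_montage_error")
  }
  extra <- setdiff(key_have, key_want)
  if (length(extra)) {
    stop_stteeg(
      paste0("Unknown channels not in montage: ",
             paste(names[key_have %in% extra], collapse = ", ")),
      "stteeg_montage_error")
  }
  idx
}
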