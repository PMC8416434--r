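#' The 19-channel 10-20 montage
#'
#' Channel set used throughout the package: the 19 electrode sites of the
#' international 10-20 system, in the fixed order adopted for all feature
#' naming and pair enumeration.
#'
#' @param labels Character vector of channel labels. Defaults to the
#'   standard 19-site set.
#' @param reference Free-text descriptor of the reference scheme.
#' @return An object of class `qeeg_montage`: a character vector of unique
#'   channel labels with a `reference` attribute.
#' @examples
#' m <- default_montage()
#' length(m)            # 19
#' nrow(channel_pairs(m))  # 171
#' @export
qeeg_montage <- function(labels, reference = "linked mastoid") {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    qeeg_abort("montage labels must be unique", "qeeg_error_validation")
  }
  structure(labels, reference = reference, class = "qeeg_montage")
}

#' @rdname qeeg_montage
#' @export
default_montage <- function() {
  qeeg_montage(c(
    "FP1", "FP2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
    "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"
  ))
}

#' @export
print.qeeg_montage <- function(x, ...) {
  cat("<qeeg_montage> ", length(x), " channels (ref: ",
      attr(x, "reference"), ")\n", sep = "")
  cat(" ", paste(unclass(x), collapse = " "), "\n")
  invisible(x)
}

# Legacy 10-20 temporal/posterior-temporal names mapped to their modern
# equivalents, so datasets labelled either way ingest identically.
legacy_channel_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

#' Normalise channel labels onto a montage
#'
#' Case-insensitive matching with the legacy T3/T4/T5/T6 aliases mapped to
#' T7/T8/P7/P8.
#'
#' @param labels Character vector of raw labels.
#' @param montage A [qeeg_montage()].
#' @return Character vector of canonical montage labels (NA where unmapped).
#' @export
normalize_channel_labels <- function(labels, montage = default_montage()) {
  up <- toupper(trimws(labels))
  alias_idx <- match(up, toupper(names(legacy_channel_aliases)))
  up[!is.na(alias_idx)] <- toupper(legacy_channel_aliases[alias_idx[!is.na(alias_idx)]])
  as.character(montage)[match(up, toupper(as.character(montage)))]
}

#' Enumerate unordered channel pairs
#'
#' All C(C-1)/2 unordered channel pairs of a montage, stable-ordered
#' lexicographically by montage index (the order used for coherence feature
#' naming).
#'
#' @param montage A [qeeg_montage()].
#' @return A tibble with columns `i`, `j` (montage indices, `i < j`),
#'   `chan_i`, `chan_j`.
#' @export
channel_pairs <- function(montage = default_montage()) {
  C <- length(montage)
  idx <- which(upper.tri(matrix(TRUE, C, C)), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  tibble::tibble(
    i = idx[ord, "row"],
    j = idx[ord, "col"],
    chan_i = as.character(montage)[idx[ord, "row"]],
    chan_j = as.character(montage)[idx[ord, "col"]]
  )
}
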