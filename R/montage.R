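# Scalp montage: 61-channel 10-10 layout with lobar region assignment.

# Default 61-name subset of the International 10-10 system. The exact
# electrode set of a given 64-channel amplifier varies by vendor; this is a
# standard symmetric 61-scalp-channel selection and is overridable everywhere
# a montage is accepted.
.montage_labels_61 <- c(
  "Fp1", "Fpz", "Fp2",
  "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8",
  "O1", "Oz", "O2"
)

# Old 10-20 dialect -> modern 10-10 names.
.label_aliases <- c(T3 = "T7", T4 = "T8", T5 = "P7", T6 = "P8")

.region_levels <- c("frontal", "temporal", "central", "parietal", "occipital")

#' Normalize EEG channel labels
#'
#' Trims whitespace, canonicalizes case (`FP1` -> `Fp1`, `CZ` -> `Cz`), and
#' maps legacy 10-20 names to their modern 10-10 equivalents
#' (`T3`/`T4` -> `T7`/`T8`, `T5`/`T6` -> `P7`/`P8`).
#'
#' @param labels Character vector of raw channel labels.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_channel_labels(c(" FP1 ", "T3", "cz"))
#' @export
normalize_channel_labels <- function(labels) {
  x <- trimws(labels)
  # canonical case: letters as in 10-10 convention -- initial capital, "p" in
  # Fp lowercase, terminal z lowercase, everything else upper
  x <- toupper(x)
  x <- sub("Z$", "z", sub("^FP", "Fp", x))
  x <- ifelse(x %in% names(.label_aliases), unname(.label_aliases[x]), x)
  x
}

#' Assign a scalp region to 10-10 channel labels
#'
#' Prefix rule: `Fp`/`AF`/`F` are frontal; `FT`/`T`/`TP` temporal; `FC`/`C`
#' central; `CP`/`P` parietal; `PO`/`O`/`I` occipital. Two-letter prefixes are
#' matched before one-letter ones, and midline `z` electrodes follow their
#' letter prefix.
#'
#' @param labels Character vector of (normalized) channel labels.
#' @return Character vector of regions, `NA` for unrecognized labels.
#' @export
region_of_label <- function(labels) {
  two <- substr(labels, 1L, 2L)
  one <- substr(labels, 1L, 1L)
  out <- rep(NA_character_, length(labels))
  out[two %in% c("FT", "TP")] <- "temporal"
  out[two == "FC"] <- "central"
  out[two == "CP"] <- "parietal"
  out[two == "Fp"] <- "frontal"
  out[two == "AF"] <- "frontal"
  out[two == "PO"] <- "occipital"
  miss <- is.na(out)
  out[miss & one == "F"] <- "frontal"
  miss <- is.na(out)
  out[miss & one == "T"] <- "temporal"
  miss <- is.na(out)
  out[miss & one == "C"] <- "central"
  miss <- is.na(out)
  out[miss & one == "P"] <- "parietal"
  miss <- is.na(out)
  out[miss & one %in% c("O", "I")] <- "occipital"
  out
}

#' Construct a scalp montage
#'
#' A montage is the ordered set of scalp channel labels together with the map
#' from each label to one of the five lobar regions (frontal, temporal,
#' central, parietal, occipital) used by regional aggregation.
#'
#' @param labels Character vector of 10-10 channel labels.
#' @param regions Optional named character vector overriding the prefix-based
#'   region rule (names are labels, values regions).
#' @return An object of class `eeg_montage`: list with `labels` and
#'   `region` (named character vector).
#' @seealso [default_montage()], [region_channel_pairs()]
#' @export
montage <- function(labels, regions = NULL) {
  labels <- normalize_channel_labels(labels)
  if (anyDuplicated(labels))
    stopf("duplicate channel labels after normalization: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  region <- region_of_label(labels)
  names(region) <- labels
  if (!is.null(regions)) {
    nm <- normalize_channel_labels(names(regions))
    bad <- setdiff(regions, .region_levels)
    if (length(bad)) stopf("unknown region(s): %s", paste(bad, collapse = ", "))
    region[nm] <- unname(regions)
  }
  if (anyNA(region))
    stopf("label(s) with no region assignment: %s",
          paste(labels[is.na(region)], collapse = ", "))
  structure(list(labels = labels, region = region), class = "eeg_montage")
}

#' Default 61-channel 10-10 montage
#'
#' @return An `eeg_montage` with 61 scalp labels, each assigned to exactly one
#'   of the five regions.
#' @examples
#' m <- default_montage()
#' table(m$region)
#' @export
default_montage <- function() montage(.montage_labels_61)

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels\n", length(x$labels)))
  print(table(factor(x$region, levels = .region_levels)))
  invisible(x)
}

#' Unordered channel pairs within a scalp region
#'
#' @param montage An `eeg_montage`.
#' @param region One of `"frontal"`, `"temporal"`, `"central"`, `"parietal"`,
#'   `"occipital"`.
#' @return Two-column character matrix of pairs (i < j in montage order);
#'   zero rows for a region with fewer than two channels.
#' @export
region_channel_pairs <- function(montage, region) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (!region %in% .region_levels)
    stopf("unknown region '%s'", region)
  members <- montage$labels[montage$region[montage$labels] == region]
  if (length(members) < 2L)
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("a", "b"))))
  idx <- utils::combn(length(members), 2L)
  cbind(a = members[idx[1L, ]], b = members[idx[2L, ]])
}
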