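#' Montage specification
#'
#' Describes an EEG montage: ordered channel labels, the (external) reference
#' electrode, and a neighbor map used by the small-Laplacian spatial filter.
#'
#' @param channel_names character vector of unique channel labels.
#' @param reference_name label of the reference electrode; must not be one of
#'   `channel_names`.
#' @param neighbor_map named list mapping a channel label to the character
#'   vector of its neighbor labels. Keys and values must all be members of
#'   `channel_names`.
#' @return An object of class `montage_spec`.
#' @seealso [default_montage()] for the six-electrode motor-strip layout.
#' @export
montage_spec <- function(channel_names, reference_name, neighbor_map = list()) {
  if (anyDuplicated(channel_names)) {
    stop("channel_names must be unique", call. = FALSE)
  }
  if (reference_name %in% channel_names) {
    stop("reference_name must not be one of channel_names", call. = FALSE)
  }
  bad_keys <- setdiff(names(neighbor_map), channel_names)
  if (length(bad_keys)) {
    stop("neighbor_map keys not in channel_names: ",
         paste(bad_keys, collapse = ", "), call. = FALSE)
  }
  bad_vals <- setdiff(unlist(neighbor_map, use.names = FALSE), channel_names)
  if (length(bad_vals)) {
    stop("neighbor_map values not in channel_names: ",
         paste(bad_vals, collapse = ", "), call. = FALSE)
  }
  structure(
    list(channel_names = as.character(channel_names),
         reference_name = as.character(reference_name),
         neighbor_map = neighbor_map),
    class = "montage_spec"
  )
}

#' Default motor-strip montage
#'
#' Six electrodes over the central motor areas of both hemispheres
#' (C5, C3, C1, CZ, C2, C4), referenced against CZA (3 cm anterior to CZ).
#' The Laplacian neighbor map is the linear small-Laplacian this strip
#' supports: each channel's neighbors are its immediate left/right channels
#' in strip order; the end channels C5 and C4 have a single inner neighbor.
#'
#' @return A [montage_spec()] object.
#' @export
default_montage <- function() {
  ch <- c("C5", "C3", "C1", "CZ", "C2", "C4")
  nb <- list()
  for (i in seq_along(ch)) {
    nb[[ch[i]]] <- ch[c(i - 1L, i + 1L)[c(i - 1L, i + 1L) %in% seq_along(ch)]]
  }
  montage_spec(ch, "CZA", nb)
}
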