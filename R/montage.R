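#' Standard 32-channel montage with mastoids
#'
#' Loads the 10-20-style 32-channel scalp layout (BioSemi-like labels,
#' including F3/Fz/F4 and the temporal sites T7/T8) plus left and right
#' mastoid electrodes M1/M2, with unit-sphere 3-D positions.
#'
#' @return an object of class `mmn_montage`: a list with `labels` (character)
#'   and `positions` (n x 3 matrix of unit vectors, rows named by label).
#' @export
#' @examples
#' m <- default_montage()
#' nrow(m$positions)
default_montage <- function() {
  path <- system.file("extdata", "biosemi32_montage.tsv", package = "oddballmmn")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pos <- as.matrix(tab[, c("x", "y", "z")])
  rownames(pos) <- tab$label
  montage(tab$label, pos)
}

#' Construct a montage object
#'
#' @param labels character vector of unique channel labels.
#' @param positions n x 3 numeric matrix of unit-norm channel positions.
#' @return `mmn_montage` object.
#' @export
montage <- function(labels, positions) {
  stopifnot(is.character(labels), !anyDuplicated(labels),
            is.matrix(positions), nrow(positions) == length(labels),
            ncol(positions) == 3)
  nrms <- sqrt(rowSums(positions^2))
  if (any(abs(nrms - 1) > 1e-9)) stop("montage positions must have unit norm")
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions), class = "mmn_montage")
}

#' Great-circle distances between montage channels
#'
#' @param montage an `mmn_montage`.
#' @return symmetric matrix of angular distances in radians.
#' @export
channel_distances <- function(montage) {
  p <- montage$positions
  d <- tcrossprod(p)
  d[d > 1] <- 1
  d[d < -1] <- -1
  acos(d)
}

#' Nearest montage neighbours of each channel
#'
#' @param montage an `mmn_montage`.
#' @param n_neighbors how many neighbours per channel.
#' @return named list of character vectors.
#' @keywords internal
nearest_neighbors <- function(montage, n_neighbors) {
  d <- channel_distances(montage)
  out <- lapply(seq_along(montage$labels), function(i) {
    ord <- order(d[i, ])
    montage$labels[setdiff(ord, i)][seq_len(n_neighbors)]
  })
  names(out) <- montage$labels
  out
}

#' Restrict a montage to a subset of channels
#'
#' @param montage an `mmn_montage`.
#' @param labels channels to keep, in the given order.
#' @return `mmn_montage`.
#' @export
subset_montage <- function(montage, labels) {
  miss <- setdiff(labels, montage$labels)
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  montage(labels, montage$positions[labels, , drop = FALSE])
}
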