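#' Histological cell-size index
#'
#' The intracellular DW signal is a volume-weighted sum of per-cell signals,
#' and in the wide-pulse limit each cell's attenuation grows like l^4; the
#' MRI-matched histological size index is therefore
#' Lhisto = (<l^7> / <l^3>)^(1/4), with plain arithmetic means over the cell
#' diameters l in a patch.
#'
#' @name histology
NULL

#' Compute the cell-size index for one patch
#'
#' @param l Positive cell diameters (um), non-empty.
#' @return Lhisto in um.
#' @examples
#' lhisto(c(10, 50))  # ((10^7 + 50^7) / (10^3 + 50^3))^(1/4)
#' @export
lhisto <- function(l) {
  if (length(l) == 0) stop("lhisto: empty diameter list")
  if (any(!is.finite(l)) || any(l <= 0)) stop("lhisto: diameters must be positive")
  (mean(l^7) / mean(l^3))^(1 / 4)
}

#' Per-patch cell-size index table
#'
#' @param diameters Data frame with columns `patch_id` and `diameter_um`
#'   (one row per cell), as read from CSV.
#' @return Data frame with `patch_id`, `lhisto_um`, `n_cells`.
#' @export
lhisto_table <- function(diameters) {
  stopifnot(all(c("patch_id", "diameter_um") %in% names(diameters)))
  ids <- unique(diameters$patch_id)
  do.call(rbind, lapply(ids, function(id) {
    l <- diameters$diameter_um[diameters$patch_id == id]
    data.frame(patch_id = id, lhisto_um = lhisto(l), n_cells = length(l))
  }))
}

#' Read per-patch diameters from CSV
#'
#' @param path CSV with columns `patch_id`, `diameter_um`.
#' @return Data frame.
#' @export
read_patch_diameters <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("patch_id", "diameter_um") %in% names(d)))
  d
}
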