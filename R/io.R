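#' Write an intensity profile to CSV (position_um, intensity)
#'
#' When the profile carries an attached ground-truth record a JSON sidecar
#' (`<path>.truth.json`) is written next to it.
#'
#' @param profile An [intensity_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  utils::write.csv(
    data.frame(position_um = profile$positions,
               intensity = profile$intensities),
    path, row.names = FALSE
  )
  truth <- attr(profile, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(
      c(unclass(truth), list(channel = profile$channel)),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' Read an intensity profile from CSV
#'
#' @param path CSV with columns `position_um`, `intensity`.
#' @param channel Channel tag.
#' @return An [intensity_profile()].
#' @export
read_profile_csv <- function(path, channel = "phalloidin") {
  d <- utils::read.csv(path)
  if (!all(c("position_um", "intensity") %in% names(d))) {
    stop("profile CSV needs columns position_um, intensity")
  }
  ps <- stats::median(diff(d$position_um))
  intensity_profile(d$position_um, d$intensity, ps, channel)
}

#' Write a synthetic image as TIFF (with a JSON truth sidecar)
#'
#' Intensities are rescaled to \[0, 1\] for storage; the scale and pixel size
#' are recorded in the sidecar.
#'
#' @param image Numeric matrix from [gen_striation_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  mx <- max(image)
  tiff::writeTIFF(image / max(mx, .Machine$double.eps), path,
                  bits.per.sample = 16L)
  truth <- attr(image, "truth")
  side <- list(pixel_size = attr(image, "pixel_size"), intensity_scale = mx)
  if (!is.null(truth)) side$truth <- unclass(truth)
  jsonlite::write_json(side, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a TIFF image written by [write_image_tiff()]
#'
#' @param path TIFF path; the sidecar (if present) restores the pixel size
#'   and intensity scale.
#' @return Numeric matrix with a `pixel_size` attribute.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  sidecar <- paste0(path, ".truth.json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    img <- img * (side$intensity_scale %||% 1)
    attr(img, "pixel_size") <- side$pixel_size
  }
  img
}

#' Write / read plain-text assay tables
#'
#' Thin CSV/TSV wrappers so every dataset the pipeline consumes has a
#' documented on-disk form: Ct tables and climbing datasets as CSV,
#' annotations (`gene<TAB>term`) and interaction edges
#' (`gene<TAB>gene<TAB>kind`) as TSV.
#'
#' @param x Data frame (or named list of term sets for annotations).
#' @param path File path.
#' @return `path` (writers, invisibly) or the parsed object (readers).
#' @name assay_io
NULL

#' @rdname assay_io
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname assay_io
#' @export
read_climbing_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("line", "vial", "day", "rep", "successes", "n_flies")
  if (!all(need %in% names(d))) {
    stop("climbing CSV needs columns ", paste(need, collapse = ", "))
  }
  class(d) <- c("climbing_dataset", "data.frame")
  d
}

#' @rdname assay_io
#' @export
read_ct_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("genotype", "day", "gene", "replicate", "ct")
  if (!all(need %in% names(d))) {
    stop("Ct CSV needs columns ", paste(need, collapse = ", "))
  }
  class(d) <- c("ct_table", "data.frame")
  d
}

#' @rdname assay_io
#' @export
write_annotations_tsv <- function(x, path) {
  rows <- do.call(rbind, lapply(names(x), function(g) {
    if (length(x[[g]]) == 0) return(NULL)
    data.frame(gene = g, term = x[[g]])
  }))
  if (is.null(rows)) rows <- data.frame(gene = character(0),
                                        term = character(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname assay_io
#' @export
read_annotations_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(d))) {
    stop("annotation TSV needs columns gene, term")
  }
  split(d$term, d$gene)
}

#' @rdname assay_io
#' @export
read_edges_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(d))) {
    stop("edge TSV needs columns from, to (and optionally kind)")
  }
  d
}
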