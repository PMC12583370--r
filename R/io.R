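# Field input/output: multi-page 32-bit float TIFF (one page per channel,
# order calcium/mito/er, then the per-stain negative controls) plus a JSON
# sidecar holding the intensity scale, channel order and condition labels.

#' Write a fluorescence field to a multi-page TIFF + JSON sidecar
#'
#' Channels are stored as 32-bit float pages scaled into \[0, 1\] by a
#' common factor recorded in the sidecar (`<path>.json`), so intensities
#' round-trip through [read_field()].
#'
#' @param field a `fluorescence_field`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "fluorescence_field"))
  channels <- list(calcium = field$calcium, mito = field$mito,
                   er = field$er)
  ctrl_names <- character(0)
  if (!is.null(field$controls)) {
    for (nm in names(field$controls)) {
      channels[[paste0("control_", nm)]] <- field$controls[[nm]]
      ctrl_names <- c(ctrl_names, nm)
    }
  }
  scale <- max(1, vapply(channels, max, 0))
  tiff::writeTIFF(lapply(channels, function(m) m / scale), path,
                  bits.per.sample = 32, reduce = FALSE)
  sidecar <- list(channels = names(channels), controls = ctrl_names,
                  scale = scale, pixel_size = field$pixel_size,
                  katp_level = field$katp_level,
                  rotenone = field$rotenone,
                  replicate_id = field$replicate_id,
                  field_id = field$field_id)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a fluorescence field written by [write_field()]
#'
#' @param path TIFF path (with `<path>.json` sidecar alongside).
#' @return a `fluorescence_field`.
#' @export
read_field <- function(path) {
  sc_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("missing image: ", path)
  if (!file.exists(sc_path)) stop("missing sidecar: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(sc$channels)) {
    stop("page count does not match sidecar for ", path)
  }
  names(pages) <- sc$channels
  pages <- lapply(pages, function(m) m * sc$scale)
  controls <- NULL
  if (length(sc$controls)) {
    controls <- lapply(setNames(sc$controls, sc$controls),
                       function(nm) pages[[paste0("control_", nm)]])
  }
  fluorescence_field(calcium = pages$calcium, mito = pages$mito,
                     er = pages$er, pixel_size = sc$pixel_size,
                     controls = controls,
                     katp_level = sc$katp_level, rotenone = sc$rotenone,
                     replicate_id = sc$replicate_id,
                     field_id = sc$field_id)
}
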