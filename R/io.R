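## File I/O: 16-bit TIFF images, CSV tables with schema checks, YAML
## configuration.

#' Write / read an ImageField as 16-bit multi-page TIFF
#'
#' One page per channel, in channel order (`aggregate` first, then
#' `organelle`). Integer intensities in `[0, 65535]` round-trip exactly.
#'
#' @param field an [ImageField-class].
#' @param path output TIFF path.
#' @return `writeImageField`: the path, invisibly. `readImageField`: an
#'   [ImageField-class].
#' @export
writeImageField <- function(field, path) {
  pages <- lapply(field@channels, function(ch) {
    if (any(ch < 0 | ch > 65535))
      stop("channel intensities must lie in [0, 65535] for 16-bit TIFF")
    ch / 65535
  })
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 16L)
  invisible(path)
}

#' @param channelNames names assigned to the pages on reading.
#' @rdname writeImageField
#' @export
readImageField <- function(path, channelNames = c("aggregate",
                                                  "organelle")) {
  if (!file.exists(path)) stop("no such TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) > length(channelNames))
    stop("TIFF has ", length(pages), " pages but only ",
         length(channelNames), " channel names were given")
  channels <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # tolerate grayscale-as-RGB
    round(p * 65535)
  })
  names(channels) <- channelNames[seq_along(channels)]
  imageField(channels, provenance = path)
}

#' Write a result table as CSV
#'
#' Full-precision CSV (15 significant digits), no row names, columns in
#' the order given.
#'
#' @param table data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeResultTable <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], function(x)
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE,
                                scientific = FALSE)))
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV table and check its schema
#'
#' @param path CSV path.
#' @param required column names that must be present; a missing column is
#'   reported by name.
#' @return data.frame.
#' @export
readCheckedTable <- function(path, required = character()) {
  if (!file.exists(path)) stop("no such table: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("table ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Read a screen replicate table
#'
#' CSV with columns `mutant_id`, `replicate`, `class3_percent` — the
#' tabular interface to [callHits()].
#'
#' @param path CSV path.
#' @return data.frame with the three required columns.
#' @export
readScreenTable <- function(path) {
  readCheckedTable(path, c("mutant_id", "replicate", "class3_percent"))
}

#' Write the ground truth of a synthetic field
#'
#' `cells.csv`, `inclusions.csv` and a JSON field manifest in `dir`.
#' Pixel coordinates are 1-based row/column indices.
#'
#' @param truth a [GroundTruth-class].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @return invisibly, the vector of written paths.
#' @export
writeGroundTruth <- function(truth, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("cells.csv", "inclusions.csv",
                                           "field.json")))
  writeResultTable(groundTruthCells(truth), paths[1])
  writeResultTable(groundTruthInclusions(truth), paths[2])
  jsonlite::write_json(list(summary = plantedSummary(truth),
                            n_cells = nrow(groundTruthCells(truth)),
                            n_inclusions = nrow(groundTruthInclusions(truth))),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
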