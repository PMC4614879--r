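# ESRI ASCII-grid reader/writer, one year-stamped file per layer.
# The grid is abstract (50 km cells); no CRS handling.

.read_asc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", trimws(lines[i]))) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize"))
    if (is.null(hdr[[k]])) .stop_fmt("%s: missing header field %s", path, k)
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    .stop_fmt("%s: expected %d values, found %d", path,
              hdr$ncols * hdr$nrows, length(vals))
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(header = hdr[c("ncols", "nrows", "cellsize")], values = m)
}

#' Read a yearly grid series from ESRI ASCII files
#'
#' Accepts a directory of `<year>.asc` files (or any filenames containing a
#' 4-digit year) or a character vector of file paths. All files must share
#' ncols/nrows/cellsize. NODATA cells define the land mask; a cell that is
#' NODATA in any year is land everywhere.
#'
#' @param path directory or vector of .asc file paths
#' @return a [grid_series()]
#' @export
read_grid_series <- function(path) {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.asc$", full.names = TRUE) else path
  if (!length(files)) .stop_fmt("no .asc files under %s", path[1L])
  years <- suppressWarnings(
    as.integer(regmatches(basename(files),
                          regexpr("[0-9]{4}", basename(files)))))
  if (anyNA(years) || length(years) != length(files))
    .stop_fmt("cannot parse a 4-digit year from every grid filename")
  ord <- order(years)
  files <- files[ord]; years <- years[ord]
  parsed <- lapply(files, .read_asc)
  hdr <- parsed[[1L]]$header
  for (j in seq_along(parsed))
    if (!isTRUE(all.equal(parsed[[j]]$header, hdr)))
      .stop_fmt("grid header of %s differs from %s",
                basename(files[j]), basename(files[1L]))
  layers <- lapply(parsed, `[[`, "values")
  mask <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  grid_series(years, layers, mask, cell_size_km = hdr$cellsize)
}

#' Write a grid series as yearly ESRI ASCII files
#'
#' @param gs a [grid_series()]
#' @param dir output directory (created if absent); files are `<year>.asc`
#' @param digits significant digits for cell values
#' @return the directory, invisibly
#' @export
write_grid_series <- function(gs, dir, digits = 7) {
  stopifnot(inherits(gs, "grid_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("ncols %d\nnrows %d\nxllcorner 0\nyllcorner 0\ncellsize %g\nNODATA_value -9999",
                 ncol(gs$mask), nrow(gs$mask), gs$cell_size_km)
  for (i in seq_along(gs$years)) {
    m <- gs$layers[[i]]
    m[!gs$mask | is.na(m)] <- -9999
    rows <- apply(signif(m, digits), 1L, paste, collapse = " ")
    writeLines(c(hdr, rows), file.path(dir, sprintf("%d.asc", gs$years[i])))
  }
  invisible(dir)
}
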