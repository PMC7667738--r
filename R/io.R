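#' Read and write CDE tables
#'
#' CDE tables are plain tab-separated text with columns `plate`, `row`,
#' `col`, `strain`, `control_flag`, `dubious_flag`, `condition` (`light` or
#' `dark`), `day` (0, 1 or 6) and `cde`.
#'
#' @param path File path.
#' @return `read_cde_table()` returns the table as a data frame.
#' @export
read_cde_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("plate", "row", "col", "strain", "control_flag", "dubious_flag",
            "condition", "day", "cde")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("CDE table ", path, " missing columns: ", paste(miss, collapse = ", "))
  tab
}

#' @rdname read_cde_table
#' @param tab CDE table (data frame).
#' @export
write_cde_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write array layouts
#'
#' Layouts are stored as tab-separated strain maps (`plate`, `row`, `col`,
#' `strain`, `control_flag`, `dubious_flag`) preceded by commented
#' `# key = value` header lines carrying the grid geometry.
#'
#' @param path File path.
#' @param layout_tab Data frame strain map covering all plates.
#' @param geometry Named list of geometry values written to the header
#'   (rows, cols, band_height_px, spacing_px, top_k).
#' @return `read_layout()` returns a list with elements `geometry` (named
#'   list) and `map` (data frame).
#' @export
read_layout <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  geometry <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "\\s*=\\s*")[[1]]
    if (length(kv) == 2L) geometry[[kv[1]]] <- as.numeric(kv[2])
  }
  map <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                           stringsAsFactors = FALSE)
  list(geometry = geometry, map = map)
}

#' @rdname read_layout
#' @export
write_layout <- function(layout_tab, path,
                         geometry = list(rows = 16, cols = 24,
                                         band_height_px = 30, spacing_px = 60,
                                         top_k = 25)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(geometry))
    writeLines(sprintf("# %s = %s", k, geometry[[k]]), con)
  utils::write.table(layout_tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a plate photograph
#'
#' PNG and TIFF images are read through the \pkg{png} and \pkg{tiff}
#' packages, which return intensities on \[0, 1\]; these are rescaled by
#' `scale` so that in-memory pixel values match the 16-bit convention used
#' by the synthetic plate writer.  RGB images are collapsed with
#' [as_gray()].
#'
#' @param path Image file (`.png`, `.tif`/`.tiff`).
#' @param scale Multiplier from the decoded \[0, 1\] range to intensity
#'   units.
#' @return Numeric intensity matrix.
#' @export
read_plate_image <- function(path, scale = 65535) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  as_gray(px) * scale
}

#' @rdname read_plate_image
#' @param pixels Nonnegative intensity matrix; values above `scale` are
#'   clipped on write.  TIFF output is 16-bit; PNG output is 8-bit (the
#'   \pkg{png} encoder's depth), so TIFF is preferred for synthetic plates.
#' @export
write_plate_image <- function(pixels, path, scale = 65535) {
  ext <- tolower(tools::file_ext(path))
  px <- pmin(pmax(pixels / scale, 0), 1)
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 16L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read a gene-to-term annotation table
#'
#' Two-column delimited text mapping term identifiers to gene identifiers
#' (the layout of SGD `go_slim_mapping` style exports reduced to term and
#' gene columns).  Column order `term`, `gene`; a header is optional.
#'
#' @param path File path.
#' @return Data frame with columns `term` and `gene`.
#' @export
read_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term", "gene") %in% names(tab))) {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    names(tab)[1:2] <- c("term", "gene")
  }
  tab[c("term", "gene")]
}
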