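#' Colony-array plate densitometry
#'
#' A photographed colony array is quantified band by band: each 16x24 plate
#' image is split into 30-pixel-high row bands, each band is collapsed into a
#' one-value-per-column intensity profile (sum of the 25 brightest pixels per
#' column), the profile is cut into 60-pixel colony windows (one per colony,
#' colony centered), and each window yields a cell density estimate (CDE):
#' colony intensity (median of the 10 largest values among the central 20
#' profile positions) minus local background (mean of the flank minima at
#' positions 5-20 and 40-55).  All pixel positions are 1-based inclusive.
#'
#' @name imaging
NULL

#' Construct an array layout
#'
#' Geometry and strain map of a pinned colony array.  Defaults describe the
#' standard 384 format: 16 rows of 24 colonies, 30 px row bands, 60 px
#' center-to-center spacing, profiles built from the top 25 pixels of each
#' column.
#'
#' @param rows,cols Grid dimensions (colonies).
#' @param band_height_px Height of one row band in pixels.
#' @param spacing_px Center-to-center colony spacing in pixels; also the
#'   colony window length.
#' @param top_k Number of brightest pixels summed per profile column; must
#'   not exceed `band_height_px`.
#' @param strain_map Optional data frame with columns `row`, `col`, `strain`,
#'   `control_flag`, `dubious_flag` covering every grid position.
#' @param offset Integer `(row_px, col_px)` registration offset applied
#'   before cropping the image to the grid.
#' @return An object of class `array_layout`.
#' @export
array_layout <- function(rows = 16L, cols = 24L, band_height_px = 30L,
                         spacing_px = 60L, top_k = 25L, strain_map = NULL,
                         offset = c(0L, 0L)) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L)
    stop("grid dimensions must be positive")
  if (top_k > band_height_px)
    stop("top_k (", top_k, ") exceeds band height (", band_height_px, ")")
  if (!is.null(strain_map)) {
    need <- c("row", "col", "strain", "control_flag", "dubious_flag")
    if (!all(need %in% names(strain_map)))
      stop("strain_map must have columns: ", paste(need, collapse = ", "))
    key <- paste(strain_map$row, strain_map$col)
    want <- paste(rep(seq_len(rows), each = cols), rep(seq_len(cols), rows))
    if (!setequal(key, want) || anyDuplicated(key))
      stop("strain_map must cover every grid position exactly once")
  }
  structure(list(rows = rows, cols = cols,
                 band_height_px = as.integer(band_height_px),
                 spacing_px = as.integer(spacing_px),
                 top_k = as.integer(top_k),
                 strain_map = strain_map,
                 offset = as.integer(offset)),
            class = "array_layout")
}

#' Collapse colour channels to grayscale
#'
#' RGB(A) arrays are reduced by the unweighted mean of their channels;
#' matrices pass through unchanged.
#'
#' @param pixels Numeric matrix or 3-d array (rows x cols x channels).
#' @return Numeric matrix.
#' @export
as_gray <- function(pixels) {
  d <- dim(pixels)
  if (length(d) == 2L) return(pixels)
  if (length(d) == 3L) {
    out <- pixels[, , 1L]
    if (d[3L] > 1L)
      for (k in 2L:d[3L]) out <- out + pixels[, , k]
    return(out / d[3L])
  }
  stop("pixels must be a matrix or a rows x cols x channels array")
}

#' Band intensity profile
#'
#' One value per image column: the sum of the `top_k` largest pixel values in
#' that column of the band (ties counted with multiplicity).
#'
#' @param band Numeric matrix, one row band of the plate image
#'   (band height x width).
#' @param top_k Number of brightest pixels summed per column.
#' @return Numeric vector of length `ncol(band)`.
#' @export
band_profile <- function(band, top_k = 25L) {
  band <- as.matrix(band)
  if (nrow(band) < top_k)
    stop("band has ", nrow(band), " rows; need at least top_k = ", top_k)
  apply(band, 2L, function(col)
    sum(sort(col, decreasing = TRUE, method = "radix")[seq_len(top_k)]))
}

#' Cut a band profile into colony windows
#'
#' Steps over the profile in strides of `spacing_px`; window `i` holds
#' profile positions `(i-1)*spacing_px + 1` through `i*spacing_px`, so the
#' windows partition the profile exactly.
#'
#' @param profile Numeric vector, length a multiple of `spacing_px`.
#' @param spacing_px Colony spacing (window length).
#' @return List of numeric vectors of length `spacing_px`.
#' @export
colony_windows <- function(profile, spacing_px = 60L) {
  n <- length(profile)
  if (n %% spacing_px != 0L)
    stop("profile length ", n, " is not a multiple of spacing ", spacing_px)
  split(profile, rep(seq_len(n %/% spacing_px), each = spacing_px))
}

#' Colony intensity of a window
#'
#' Median of the 10 largest values among the central 20 positions (21-40 of
#' a 60-px window).  The median of an even count is the mean of the two
#' central order statistics.
#'
#' @param window Numeric vector of length `spacing_px`.
#' @param spacing_px Window length.
#' @param central Positions of the central region (1-based inclusive).
#' @param top_n How many of the largest central values enter the median.
#' @return Scalar colony intensity.
#' @export
colony_intensity <- function(window, spacing_px = 60L, central = 21:40,
                             top_n = 10L) {
  if (length(window) != spacing_px)
    stop("window length ", length(window), "; expected ", spacing_px)
  top <- sort(window[central], decreasing = TRUE)[seq_len(top_n)]
  stats::median(top)
}

#' Background intensity of a window
#'
#' Mean of the minimum profile value on the left flank (positions 5-20) and
#' on the right flank (positions 40-55), 1-based inclusive.
#'
#' @param window Numeric vector of length `spacing_px`.
#' @param spacing_px Window length.
#' @param left,right Flank positions (1-based inclusive).
#' @return Scalar background intensity.
#' @export
background_intensity <- function(window, spacing_px = 60L, left = 5:20,
                                 right = 40:55) {
  if (length(window) != spacing_px)
    stop("window length ", length(window), "; expected ", spacing_px)
  (min(window[left]) + min(window[right])) / 2
}

#' Cell density estimate of one colony window
#'
#' Colony intensity minus background intensity.  The value is not clipped:
#' empty positions can have background above the colony region and a
#' negative CDE is meaningful to the downstream thresholds.
#'
#' @inheritParams colony_intensity
#' @return Scalar CDE.
#' @export
colony_cde <- function(window, spacing_px = 60L) {
  colony_intensity(window, spacing_px) -
    background_intensity(window, spacing_px)
}

#' Quantify a plate image into a CDE table
#'
#' Applies the full densitometry chain to every grid position of a plate
#' photograph: grayscale conversion, registration crop, per-band top-k
#' profiles, colony windows, and window CDEs.
#'
#' @param pixels Numeric intensity matrix (or RGB array) of the plate
#'   photograph; nonnegative.
#' @param layout An [array_layout()].
#' @param plate_id Plate identifier stored in the output.
#' @param condition `"light"` or `"dark"`.
#' @param day Imaging day (integer).
#' @return A data frame with one row per grid position and columns `plate`,
#'   `row`, `col`, `strain`, `control_flag`, `dubious_flag`, `condition`,
#'   `day`, `cde`.  Strain columns are `NA` when the layout has no strain
#'   map.
#' @export
quantify_plate <- function(pixels, layout = array_layout(), plate_id = "plate1",
                           condition = c("light", "dark"), day = 0L) {
  condition <- match.arg(condition)
  px <- as_gray(pixels)
  need_r <- layout$rows * layout$band_height_px
  need_c <- layout$cols * layout$spacing_px
  r0 <- layout$offset[1L]; c0 <- layout$offset[2L]
  if (nrow(px) < r0 + need_r || ncol(px) < c0 + need_c)
    stop("plate ", plate_id, ": image ", nrow(px), "x", ncol(px),
         " too small for grid ", need_r, "x", need_c,
         " at offset (", r0, ",", c0, ")")
  px <- px[r0 + seq_len(need_r), c0 + seq_len(need_c), drop = FALSE]

  cde <- matrix(NA_real_, layout$rows, layout$cols)
  for (b in seq_len(layout$rows)) {
    band <- px[(b - 1L) * layout$band_height_px + seq_len(layout$band_height_px),
               , drop = FALSE]
    prof <- band_profile(band, layout$top_k)
    wins <- colony_windows(prof, layout$spacing_px)
    cde[b, ] <- vapply(wins, colony_cde, numeric(1),
                       spacing_px = layout$spacing_px)
  }

  out <- data.frame(
    plate = plate_id,
    row = rep(seq_len(layout$rows), each = layout$cols),
    col = rep(seq_len(layout$cols), layout$rows),
    cde = as.vector(t(cde)),
    stringsAsFactors = FALSE)
  if (!is.null(layout$strain_map)) {
    m <- layout$strain_map
    idx <- match(paste(out$row, out$col), paste(m$row, m$col))
    out$strain <- m$strain[idx]
    out$control_flag <- m$control_flag[idx]
    out$dubious_flag <- m$dubious_flag[idx]
  } else {
    out$strain <- NA_character_
    out$control_flag <- NA
    out$dubious_flag <- NA
  }
  out$condition <- condition
  out$day <- as.integer(day)
  out[c("plate", "row", "col", "strain", "control_flag", "dubious_flag",
        "condition", "day", "cde")]
}
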