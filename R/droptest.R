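#' Spot intensity per area after background subtraction
#'
#' Integrated intensity of a circular spot region minus the local
#' background, divided by the spot area (INT/mm^2).  The background level
#' is the median pixel intensity of an annulus around the spot.
#'
#' @param pixels Intensity matrix of the scanned plate.
#' @param center `(row, col)` spot center in pixels.
#' @param radius Spot radius in pixels; must enclose at least one pixel.
#' @param annulus_width Width of the background annulus (px) beyond the
#'   spot radius.
#' @param px_per_mm Pixel pitch; area is converted to mm^2.
#' @return Scalar INT/mm^2 (may be negative for empty spots).
#' @export
spot_intensity <- function(pixels, center, radius, annulus_width = 5,
                           px_per_mm = 1) {
  pixels <- as_gray(pixels)
  rows <- matrix(seq_len(nrow(pixels)), nrow(pixels), ncol(pixels))
  cols <- matrix(seq_len(ncol(pixels)), nrow(pixels), ncol(pixels),
                 byrow = TRUE)
  d2 <- (rows - center[1])^2 + (cols - center[2])^2
  spot <- d2 <= radius^2
  ann <- d2 > radius^2 & d2 <= (radius + annulus_width)^2
  if (!any(spot)) stop("spot region contains no pixels")
  if (!any(ann)) stop("background annulus contains no pixels")
  bg <- stats::median(pixels[ann])
  area_mm2 <- sum(spot) / px_per_mm^2
  (sum(pixels[spot]) - sum(spot) * bg) / area_mm2
}

#' Light/dark growth ratio of one drop-test experiment
#'
#' The light spot at dilution 1 is compared against the dark spot at
#' dilution 2 (one tenfold dilution deeper) to offset the slower growth
#' under illumination; both are taken from the day-3 scan, or day 5 for
#' strains flagged as slow growers.
#'
#' @param records Drop-test table rows for one strain and one experiment
#'   (columns `condition`, `dilution`, `day`, `intensity_per_area`).
#' @param day Quantification day for the dark spot (and the light spot
#'   unless `use_day5`).
#' @param use_day5 Take the light value from the day-5 scan (slow-grower
#'   fallback); the dilutions are unchanged.
#' @return Scalar ratio; `NA` (with a warning) when the dark intensity is
#'   not positive.
#' @export
light_dark_ratio <- function(records, day = 3L, use_day5 = FALSE) {
  light_day <- if (use_day5) 5L else day
  lt <- records$intensity_per_area[records$condition == "light" &
                                     records$dilution == 1L &
                                     records$day == light_day]
  dk <- records$intensity_per_area[records$condition == "dark" &
                                     records$dilution == 2L &
                                     records$day == day]
  if (length(lt) != 1L || length(dk) != 1L)
    stop("need exactly one light dilution-1 and one dark dilution-2 record")
  if (dk <= 0) {
    warning("dark intensity not positive; ratio undefined")
    return(NA_real_)
  }
  lt / dk
}

#' Drop-test significance against wild type
#'
#' Computes per-experiment light/dark ratios for every strain and tests
#' each strain's ratios against the wild-type reference with a two-sided
#' pooled-variance (equal-variance) Student t test; strains are flagged
#' significant at `p < alpha`.
#'
#' @param table Drop-test table (columns `strain`, `experiment`,
#'   `condition`, `dilution`, `day`, `intensity_per_area`), e.g. from
#'   [simulate_droptest()].
#' @param wt Wild-type strain id used as the reference.
#' @param alpha Significance level.
#' @param day5_strains Strain ids whose light value is taken at day 5.
#' @return An object of class `droptest_result`: a data frame with one row
#'   per strain (`strain`, `n`, `mean_ratio`, `sd_ratio`, `t`, `p`,
#'   `significant`), ordered by mean ratio.
#' @export
droptest <- function(table, wt = "wt", alpha = 0.05,
                     day5_strains = character()) {
  if (!wt %in% table$strain) stop("wild-type strain '", wt, "' not in table")
  ratios <- function(strain) {
    exps <- sort(unique(table$experiment[table$strain == strain]))
    vapply(exps, function(e)
      light_dark_ratio(table[table$strain == strain &
                               table$experiment == e, ],
                       use_day5 = strain %in% day5_strains),
      numeric(1))
  }
  wt_r <- ratios(wt)
  if (sum(!is.na(wt_r)) < 2L)
    stop("need at least 2 wild-type ratios for the t test")
  strains <- setdiff(unique(table$strain), wt)
  res <- do.call(rbind, lapply(strains, function(s) {
    r <- ratios(s)
    r <- r[!is.na(r)]
    if (length(r) < 2L)
      stop("strain ", s, ": need at least 2 ratios for the t test")
    if (stats::sd(r) == 0 && stats::sd(wt_r) == 0) {
      tt <- list(statistic = c(t = if (mean(r) == mean(wt_r)) 0 else
        sign(mean(r) - mean(wt_r)) * Inf),
        p.value = if (mean(r) == mean(wt_r)) 1 else 0)
    } else {
      tt <- stats::t.test(r, wt_r, var.equal = TRUE)
    }
    data.frame(strain = s, n = length(r), mean_ratio = mean(r),
               sd_ratio = stats::sd(r), t = unname(tt$statistic),
               p = tt$p.value, significant = tt$p.value < alpha,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$mean_ratio), ]
  rownames(res) <- NULL
  attr(res, "wt") <- wt
  attr(res, "wt_mean_ratio") <- mean(wt_r, na.rm = TRUE)
  attr(res, "alpha") <- alpha
  class(res) <- c("droptest_result", "data.frame")
  res
}

#' @export
print.droptest_result <- function(x, ...) {
  cat("Drop test vs '", attr(x, "wt"), "' (mean ratio ",
      sprintf("%.3f", attr(x, "wt_mean_ratio")), "): ",
      sum(x$significant), "/", nrow(x), " strains significant at p < ",
      attr(x, "alpha"), "\n", sep = "")
  print.data.frame(x, digits = 3)
  invisible(x)
}
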