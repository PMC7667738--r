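#' Screen calling thresholds
#'
#' All cutoffs used to call light-sensitive and light-resistant strains.
#' Strains are banded by their day-0 (initial) light CDE into `discarded`
#' (below the moderate band), `moderate`, and `high` confidence bands; day-6
#' light growth below the band cutoff is the first calling criterion, and a
#' control-normalized light/dark growth index (LGnorm) below `lgnorm_cutoff`
#' is the second.  Strains with less than `slow_growth_fold` dark growth
#' over the first day are excluded.  The three assay variants carry the
#' band definitions of the primary screen, the haploid confirmation assay
#' (no moderate band) and the diploid confirmation assay.
#'
#' @param variant `"primary"`, `"confirm_haploid"` or `"confirm_diploid"`.
#' @param ... Named overrides of any threshold field (`moderate_min`,
#'   `high_min`, `day6_cutoff_moderate`, `day6_cutoff_high`,
#'   `lgnorm_cutoff`, `slow_growth_fold`, `resistant_day6_cutoff`,
#'   `resistant_day0_min`).
#' @return An object of class `screen_thresholds`.  The moderate band is
#'   `[moderate_min, high_min)` (absent when `moderate_min` is `NA`), the
#'   high band `[high_min, Inf)`.
#' @export
screen_thresholds <- function(variant = c("primary", "confirm_haploid",
                                          "confirm_diploid"), ...) {
  variant <- match.arg(variant)
  thr <- switch(variant,
    primary = list(moderate_min = 61, high_min = 121,
                   day6_cutoff_moderate = 400, day6_cutoff_high = 900),
    confirm_haploid = list(moderate_min = NA_real_, high_min = 13,
                           day6_cutoff_moderate = NA_real_,
                           day6_cutoff_high = 900),
    confirm_diploid = list(moderate_min = 45, high_min = 105,
                           day6_cutoff_moderate = 500,
                           day6_cutoff_high = 900))
  thr <- c(thr, list(lgnorm_cutoff = 0.75, slow_growth_fold = 1.5,
                     resistant_day6_cutoff = 1642, resistant_day0_min = 61,
                     variant = variant))
  over <- list(...)
  bad <- setdiff(names(over), names(thr))
  if (length(bad)) stop("unknown threshold fields: ", paste(bad, collapse = ", "))
  thr[names(over)] <- over
  if (!is.na(thr$moderate_min) && thr$moderate_min >= thr$high_min)
    stop("band boundaries must be ordered: moderate_min < high_min")
  structure(thr, class = "screen_thresholds")
}

#' @export
print.screen_thresholds <- function(x, ...) {
  cat("Screen thresholds (", x$variant, " variant)\n", sep = "")
  if (is.na(x$moderate_min)) {
    cat("  high band: day-0 CDE >=", x$high_min,
        "; day-6 cutoff <", x$day6_cutoff_high, "(no moderate band)\n")
  } else {
    cat("  moderate band: day-0 CDE in [", x$moderate_min, ", ", x$high_min,
        "); day-6 cutoff < ", x$day6_cutoff_moderate, "\n", sep = "")
    cat("  high band: day-0 CDE >= ", x$high_min, "; day-6 cutoff < ",
        x$day6_cutoff_high, "\n", sep = "")
  }
  cat("  LGnorm cutoff <", x$lgnorm_cutoff,
      "; slow-growth exclusion fold <", x$slow_growth_fold, "\n")
  cat("  resistant: day-0 CDE >=", x$resistant_day0_min,
      "and day-6 CDE >", x$resistant_day6_cutoff, "\n")
  invisible(x)
}

#' Initial-density confidence band
#'
#' Maps day-0 CDE values to `discarded`, `moderate` or `high`.
#'
#' @param cde_day0 Numeric vector of day-0 light CDEs.
#' @param thresholds A [screen_thresholds()].
#' @return Character vector of band names.
#' @export
density_band <- function(cde_day0, thresholds = screen_thresholds()) {
  band <- rep("discarded", length(cde_day0))
  if (!is.na(thresholds$moderate_min))
    band[cde_day0 >= thresholds$moderate_min &
           cde_day0 < thresholds$high_min] <- "moderate"
  band[cde_day0 >= thresholds$high_min] <- "high"
  band[is.na(cde_day0)] <- NA_character_
  band
}

#' First calling criterion: banded day-6 growth cutoff
#'
#' A strain passes when its day-6 light CDE is strictly below its density
#' band's cutoff (900 for the high band, 400 for the moderate band of the
#' primary screen).  Must not be evaluated on discarded strains.
#'
#' @param cde_day0,cde_day6_light Numeric vectors (recycled pairwise).
#' @param thresholds A [screen_thresholds()].
#' @return Logical vector.
#' @export
criterium1 <- function(cde_day0, cde_day6_light,
                       thresholds = screen_thresholds()) {
  band <- density_band(cde_day0, thresholds)
  if (any(band == "discarded", na.rm = TRUE))
    stop("criterium I is undefined for discarded (low initial density) strains")
  cutoff <- ifelse(band == "high", thresholds$day6_cutoff_high,
                   thresholds$day6_cutoff_moderate)
  cde_day6_light < cutoff
}

#' Slow-grower exclusion
#'
#' Strains whose colony intensity increased less than
#' `slow_growth_fold`-fold during the first day of dark growth are excluded
#' from calling (they would otherwise be mistaken for light-sensitive).
#'
#' @param dark_day0,dark_day1 Dark CDEs at day 0 and day 1.
#' @param thresholds A [screen_thresholds()].
#' @return Logical vector: `TRUE` = excluded; `NA` where `dark_day0 <= 0`
#'   (fold undefined).
#' @export
slow_growth_excluded <- function(dark_day0, dark_day1,
                                 thresholds = screen_thresholds()) {
  ifelse(dark_day0 > 0, dark_day1 / dark_day0 < thresholds$slow_growth_fold,
         NA)
}

#' Double-normalized light growth (LGnorm)
#'
#' `(light day-6 CDE / dark day-1 CDE) / ctrl_median`, where `ctrl_median`
#' is the median of the same light/dark ratio over the control colonies of
#' the strain's plate and density band.  A value of 1 means the strain
#' tolerated light exactly as well as the plate's controls; the second
#' calling criterion requires it below the LGnorm cutoff.
#'
#' @param lg_day6_light,dg_day1_dark,ctrl_median Numeric vectors (recycled).
#' @return Numeric vector; `NA` where a denominator is not positive.
#' @export
lgnorm <- function(lg_day6_light, dg_day1_dark, ctrl_median) {
  ifelse(dg_day1_dark > 0 & ctrl_median > 0,
         (lg_day6_light / dg_day1_dark) / ctrl_median, NA_real_)
}

# Reshape light/dark CDE tables into one row per plate position with columns
# ld0, ld6, dd0, dd1.  Positions present in the layout but missing a
# measurement keep NA in that column.
assemble_screen <- function(light, dark, layout) {
  key <- function(tab) paste(tab$plate, tab$row, tab$col)
  wide <- layout
  pick <- function(tab, cond, d) {
    sel <- tab[tab$condition == cond & tab$day == d, ]
    sel$cde[match(key(wide), key(sel))]
  }
  wide$ld0 <- pick(light, "light", 0L)
  wide$ld6 <- pick(light, "light", 6L)
  wide$dd0 <- pick(dark, "dark", 0L)
  wide$dd1 <- pick(dark, "dark", 1L)
  wide
}

#' Per-plate, per-band control light/dark medians
#'
#' For every plate and density band, the median over control colonies of
#' (day-6 light CDE / day-1 dark CDE); this is the LGnorm denominator.
#' When a plate has no in-band control the value is borrowed from the
#' nearest plate (by index) that has one, preferring the lower index on
#' ties.
#'
#' @param light,dark CDE tables.
#' @param layout Layout data frame (`plate`, `row`, `col`, `strain`,
#'   `control_flag`, `dubious_flag`).
#' @param thresholds A [screen_thresholds()].
#' @return Data frame with columns `plate`, `band`, `ctrl_median`,
#'   `source_plate`.  A band with no control value on any plate keeps
#'   `NA`; [score_screen()] raises an error only when a scored strain
#'   falls in such a band.
#' @export
control_band_medians <- function(light, dark, layout,
                                 thresholds = screen_thresholds()) {
  wide <- assemble_screen(light, dark, layout)
  ctl <- wide[wide$control_flag & !is.na(wide$ld0) & !is.na(wide$ld6) &
                !is.na(wide$dd1) & wide$dd1 > 0, ]
  ctl$band <- density_band(ctl$ld0, thresholds)
  ctl <- ctl[ctl$band != "discarded", ]
  plates <- unique(layout$plate)
  bands <- if (is.na(thresholds$moderate_min)) "high" else c("moderate", "high")
  grid <- expand.grid(plate = plates, band = bands, stringsAsFactors = FALSE)
  raw <- vapply(seq_len(nrow(grid)), function(i) {
    r <- ctl$ld6[ctl$plate == grid$plate[i] & ctl$band == grid$band[i]] /
      ctl$dd1[ctl$plate == grid$plate[i] & ctl$band == grid$band[i]]
    if (length(r)) stats::median(r) else NA_real_
  }, numeric(1))
  grid$ctrl_median <- raw
  grid$source_plate <- grid$plate
  for (i in which(is.na(raw))) {
    b <- grid$band[i]
    have <- grid[grid$band == b & !is.na(grid$ctrl_median), ]
    if (!nrow(have)) {
      # band empty on every plate: left NA; the caller errors only if a
      # scored strain actually needs this band
      grid$source_plate[i] <- NA_character_
      next
    }
    pi <- match(grid$plate[i], plates)
    pj <- match(have$plate, plates)
    j <- which.min(abs(pj - pi) + 1e-9 * pj)   # nearest; ties -> lower index
    grid$ctrl_median[i] <- have$ctrl_median[j]
    grid$source_plate[i] <- have$plate[j]
  }
  grid
}

#' Control-based false-positive rate for one band
#'
#' Fraction of in-band control colonies whose day-6 light CDE satisfies the
#' band's first-criterion cutoff (i.e. would have been called sensitive).
#'
#' @param light Light CDE table (must contain day 0 and day 6 records with
#'   `control_flag`).
#' @param thresholds A [screen_thresholds()].
#' @param band `"moderate"` or `"high"`.
#' @return Fraction in `[0, 1]`.
#' @export
estimate_false_positive_rate <- function(light,
                                         thresholds = screen_thresholds(),
                                         band = c("moderate", "high")) {
  band <- match.arg(band)
  d0 <- light[light$control_flag & light$day == 0L, ]
  d6 <- light[light$control_flag & light$day == 6L, ]
  key <- function(tab) paste(tab$plate, tab$row, tab$col)
  d0$ld6 <- d6$cde[match(key(d0), key(d6))]
  d0 <- d0[!is.na(d0$ld6), ]
  d0$band <- density_band(d0$cde, thresholds)
  sel <- d0[d0$band == band, ]
  if (!nrow(sel)) stop("no control colonies in band '", band, "'")
  cutoff <- if (band == "high") thresholds$day6_cutoff_high else
    thresholds$day6_cutoff_moderate
  mean(sel$ld6 < cutoff)
}

#' Call light-resistant strains
#'
#' Strains with a scoreable initial density (day-0 CDE at least
#' `resistant_day0_min`) whose day-6 light CDE strictly exceeds the
#' resistance cutoff.
#'
#' @param light Light CDE table.
#' @param thresholds A [screen_thresholds()].
#' @param include_controls Keep control colonies in the result (default
#'   drops them).
#' @return Character vector of resistant strain ids.
#' @export
call_resistant <- function(light, thresholds = screen_thresholds(),
                           include_controls = FALSE) {
  d0 <- light[light$day == 0L, ]
  d6 <- light[light$day == 6L, ]
  key <- function(tab) paste(tab$plate, tab$row, tab$col)
  d0$ld6 <- d6$cde[match(key(d0), key(d6))]
  hit <- !is.na(d0$cde) & !is.na(d0$ld6) &
    d0$cde >= thresholds$resistant_day0_min &
    d0$ld6 > thresholds$resistant_day6_cutoff
  if (!include_controls) hit <- hit & !d0$control_flag
  unique(d0$strain[hit])
}

#' Score a light-sensitivity screen
#'
#' Assembles per-position verdicts from light (day 0/6) and dark (day 0/1)
#' CDE tables: positions missing any required measurement are excluded;
#' initial densities below the moderate band are discarded; slow growers
#' (dark day-1 fold below the threshold) are excluded; the remaining
#' strains are called sensitive when both the banded day-6 cutoff
#' (criterion I) and the LGnorm cutoff (criterion II) hold, or resistant
#' when day-6 light growth exceeds the resistance cutoff.  Control
#' positions are scored like strains (their verdicts calibrate the
#' false-positive estimates) but are never part of the sensitive/resistant
#' strain sets reported by [summary.screen_calls()].
#'
#' @param light,dark CDE tables (see [read_cde_table()] for the format).
#' @param layout Layout data frame (`plate`, `row`, `col`, `strain`,
#'   `control_flag`, `dubious_flag`).
#' @param thresholds A [screen_thresholds()].
#' @return An object of class `screen_calls`: a list with `calls` (one row
#'   per layout position: band, lgnorm, verdict, reasons), `control_stats`
#'   (per plate/band control medians), `fp_rates` (per band control
#'   false-positive fractions), and `thresholds`.
#' @export
score_screen <- function(light, dark, layout,
                         thresholds = screen_thresholds()) {
  wide <- assemble_screen(light, dark, layout)
  ctrl <- control_band_medians(light, dark, layout, thresholds)

  n <- nrow(wide)
  verdict <- character(n)
  reasons <- character(n)
  band <- density_band(wide$ld0, thresholds)
  lgn <- rep(NA_real_, n)

  cm <- function(plate, bd) {
    v <- ctrl$ctrl_median[ctrl$plate == plate & ctrl$band == bd]
    if (!length(v) || is.na(v))
      stop("no control light/dark value in band '", bd, "' on any plate")
    v
  }

  for (i in seq_len(n)) {
    miss <- c("light_day0", "light_day6", "dark_day0",
              "dark_day1")[is.na(c(wide$ld0[i], wide$ld6[i], wide$dd0[i],
                                   wide$dd1[i]))]
    if (length(miss)) {
      verdict[i] <- "excluded_missing_data"
      reasons[i] <- paste("missing", paste(miss, collapse = "+"))
      next
    }
    if (band[i] == "discarded") {
      verdict[i] <- "excluded_low_density"
      reasons[i] <- sprintf("day0 CDE %.1f below moderate band", wide$ld0[i])
      next
    }
    if (wide$dd0[i] <= 0) {
      verdict[i] <- "excluded_missing_data"
      reasons[i] <- "dark day0 CDE not positive; growth fold undefined"
      next
    }
    crit1 <- criterium1(wide$ld0[i], wide$ld6[i], thresholds)
    if (isTRUE(slow_growth_excluded(wide$dd0[i], wide$dd1[i], thresholds))) {
      verdict[i] <- "excluded_slow_growth"
      reasons[i] <- sprintf("dark growth fold %.2f below %.2f",
                            wide$dd1[i] / wide$dd0[i],
                            thresholds$slow_growth_fold)
      next
    }
    if (wide$dd1[i] <= 0) {
      verdict[i] <- "excluded_missing_data"
      reasons[i] <- "dark day1 CDE not positive; LGnorm undefined"
      next
    }
    lgn[i] <- lgnorm(wide$ld6[i], wide$dd1[i], cm(wide$plate[i], band[i]))
    crit2 <- !is.na(lgn[i]) && lgn[i] < thresholds$lgnorm_cutoff
    if (crit1 && crit2) {
      verdict[i] <- paste0("sensitive_", band[i])
      reasons[i] <- sprintf("criterium I (day6 %.1f) and II (LGnorm %.3f)",
                            wide$ld6[i], lgn[i])
    } else if (wide$ld0[i] >= thresholds$resistant_day0_min &&
               wide$ld6[i] > thresholds$resistant_day6_cutoff) {
      verdict[i] <- "resistant"
      reasons[i] <- sprintf("day6 CDE %.1f above %.1f", wide$ld6[i],
                            thresholds$resistant_day6_cutoff)
    } else {
      verdict[i] <- "not_called"
      reasons[i] <- sprintf("criterium I %s; criterium II %s (LGnorm %.3f)",
                            ifelse(crit1, "met", "not met"),
                            ifelse(crit2, "met", "not met"), lgn[i])
    }
  }

  calls <- cbind(wide[c("plate", "row", "col", "strain", "control_flag",
                        "dubious_flag")],
                 data.frame(cde_day0 = wide$ld0, cde_day6 = wide$ld6,
                            band = band, lgnorm = lgn, verdict = verdict,
                            reasons = reasons, stringsAsFactors = FALSE))

  fp <- vapply(unique(ctrl$band), function(b)
    tryCatch(estimate_false_positive_rate(light, thresholds, b),
             error = function(e) NA_real_), numeric(1))

  structure(list(calls = calls, control_stats = ctrl,
                 fp_rates = fp, thresholds = thresholds),
            class = "screen_calls")
}

#' @export
print.screen_calls <- function(x, ...) {
  tab <- table(x$calls$verdict[!x$calls$control_flag])
  cat("Light-sensitivity screen:", sum(!x$calls$control_flag),
      "strain positions,", sum(x$calls$control_flag), "controls\n")
  for (v in names(tab)) cat(sprintf("  %-24s %d\n", v, tab[[v]]))
  fp <- x$fp_rates
  cat("Control false-positive rate:",
      paste(sprintf("%s %.1f%%", names(fp), 100 * fp), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn score_screen Sensitive/resistant strain sets and per-band
#'   counts.
#' @param object A `screen_calls` object.
#' @param ... Unused.
#' @export
summary.screen_calls <- function(object, ...) {
  calls <- object$calls[!object$calls$control_flag, ]
  out <- list(
    n_strains = length(unique(calls$strain)),
    band_counts = table(calls$band),
    verdict_counts = table(calls$verdict),
    sensitive_high = unique(calls$strain[calls$verdict == "sensitive_high"]),
    sensitive_moderate =
      unique(calls$strain[calls$verdict == "sensitive_moderate"]),
    resistant = unique(calls$strain[calls$verdict == "resistant"]),
    slow_excluded =
      unique(calls$strain[calls$verdict == "excluded_slow_growth"]),
    fp_rates = object$fp_rates)
  class(out) <- "summary.screen_calls"
  out
}

#' @export
print.summary.screen_calls <- function(x, ...) {
  cat("Strains scored:", x$n_strains, "\n")
  cat("Bands:", paste(sprintf("%s %d", names(x$band_counts), x$band_counts),
                      collapse = ", "), "\n")
  cat("Sensitive: ", length(x$sensitive_high), " high + ",
      length(x$sensitive_moderate), " moderate; resistant: ",
      length(x$resistant), "; slow-growth excluded: ",
      length(x$slow_excluded), "\n", sep = "")
  invisible(x)
}
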