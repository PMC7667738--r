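#' Specification of a synthetic plate photograph
#'
#' Describes a rendered colony-array image: grid geometry, one nonnegative
#' amplitude per colony, a radially symmetric Gaussian colony kernel, a
#' constant background with optional linear gradient, and additive Gaussian
#' pixel noise.  Colony centers sit at column `30 + 60*(i-1)` of their band
#' (1-based) and at the vertical middle of the 30-px band; each colony is
#' rendered within its own grid cell.
#'
#' @param rows,cols Grid dimensions; image is `rows*band_height_px` by
#'   `cols*spacing_px` pixels.
#' @param band_height_px,spacing_px Band height and colony spacing (px).
#'   Band height must be at least 25 so that top-25 column sums are defined.
#' @param amplitudes `rows x cols` matrix of nonnegative peak intensities.
#' @param kernel_sd Gaussian kernel width (px).
#' @param background Constant background level.
#' @param gradient Length-2 `(per-row, per-column)` linear background slope.
#' @param noise_sd Additive Gaussian pixel noise sd (0 = none).
#' @param seed Integer seed; identical specs render identical images.
#' @return An object of class `synthetic_plate_spec`.
#' @export
synthetic_plate_spec <- function(rows = 16L, cols = 24L, band_height_px = 30L,
                                 spacing_px = 60L,
                                 amplitudes = matrix(0, rows, cols),
                                 kernel_sd = 6, background = 200,
                                 gradient = c(0, 0), noise_sd = 0, seed = 1L) {
  if (rows < 1L || cols < 1L) stop("grid dimensions must be positive")
  if (band_height_px < 25L)
    stop("band height must be at least 25 px (top-25 column sums)")
  amplitudes <- as.matrix(amplitudes)
  if (!all(dim(amplitudes) == c(rows, cols)))
    stop("amplitudes must be a ", rows, "x", cols, " matrix")
  if (any(amplitudes < 0)) stop("amplitudes must be nonnegative")
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 band_height_px = as.integer(band_height_px),
                 spacing_px = as.integer(spacing_px),
                 amplitudes = amplitudes, kernel_sd = kernel_sd,
                 background = background, gradient = gradient,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_plate_spec")
}

#' Render a synthetic plate image
#'
#' @param spec A [synthetic_plate_spec()].
#' @return List with `pixels` (intensity matrix) and `truth` (data frame
#'   `row`, `col`, `amplitude`).
#' @export
simulate_plate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_plate_spec"))
  h <- spec$rows * spec$band_height_px
  w <- spec$cols * spec$spacing_px
  px <- matrix(spec$background, h, w) +
    outer(seq_len(h) * spec$gradient[1], rep(1, w)) +
    outer(rep(1, h), seq_len(w) * spec$gradient[2])
  for (r in seq_len(spec$rows)) {
    rr <- (r - 1L) * spec$band_height_px + seq_len(spec$band_height_px)
    cy <- (r - 1L) * spec$band_height_px + (spec$band_height_px + 1) / 2
    ky <- exp(-((rr - cy)^2) / (2 * spec$kernel_sd^2))
    for (cc in seq_len(spec$cols)) {
      a <- spec$amplitudes[r, cc]
      if (a == 0) next
      ccols <- (cc - 1L) * spec$spacing_px + seq_len(spec$spacing_px)
      cx <- (cc - 1L) * spec$spacing_px + spec$spacing_px / 2
      kx <- exp(-((ccols - cx)^2) / (2 * spec$kernel_sd^2))
      px[rr, ccols] <- px[rr, ccols] + a * (ky %o% kx)
    }
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    px <- px + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    px[px < 0] <- 0
  }
  truth <- data.frame(row = rep(seq_len(spec$rows), each = spec$cols),
                      col = rep(seq_len(spec$cols), spec$rows),
                      amplitude = as.vector(t(spec$amplitudes)))
  list(pixels = px, truth = truth)
}

#' Specification of a synthetic screen
#'
#' Defines the statistical structure of a whole-collection light screen with
#' planted ground truth.  Initial (day-0) cell density per colony follows a
#' right-skewed lognormal law; expected day-6 growth under light is a
#' logistic function of initial density times a strain-specific effect,
#' reproducing the near-binary control behaviour (colonies above a density
#' threshold grow well under light, below it variably); dark growth
#' multiplies initial density by a per-strain 1-day fold.  Planted mutants
#' draw their initial density from the same law truncated to the scoreable
#' range so their phenotype is defined relative to a confidence band.
#'
#' @param n_strains Number of deletion strains (excluding controls).
#' @param n_sensitive,n_resistant,n_slow Counts of planted light-sensitive,
#'   light-resistant and slow-growing strains; the three sets are disjoint.
#' @param sensitive_effect Multiplier on expected day-6 light growth for
#'   planted sensitive strains.
#' @param resistant_effect Multiplier for planted resistant strains; must
#'   put day-6 light CDE above the resistance cutoff across the scoreable
#'   density range.
#' @param slow_fold Dark 1-day growth fold of planted slow growers (below
#'   the 1.5-fold exclusion threshold).
#' @param slow_light_effect Light-growth multiplier of slow growers (they
#'   look light-sensitive until the dark-growth filter removes them).
#' @param grid `(rows, cols)` of each plate.
#' @param controls_per_plate Neutral control colonies per plate; spare
#'   positions on the last plate are filled with additional controls.
#' @param day0_meanlog,day0_sdlog Lognormal parameters of initial density.
#' @param scoreable_min Lower edge of the scoreable day-0 band used to
#'   truncate planted strains' initial densities.
#' @param light_lmax,light_mid,light_scale Logistic light-response curve:
#'   expected day-6 CDE of a neutral strain with initial density `d` is
#'   `light_lmax / (1 + exp(-(d - light_mid)/light_scale))`.
#' @param dark_fold Neutral 1-day dark growth fold.
#' @param dubious_fraction Fraction of strains flagged as dubious ORFs.
#' @param noise_sd Additive Gaussian measurement noise on every emitted CDE.
#' @param seed Integer seed.
#' @return An object of class `synthetic_screen_spec`.
#' @export
synthetic_screen_spec <- function(n_strains = 308L, n_sensitive = 0L,
                                  n_resistant = 0L, n_slow = 0L,
                                  sensitive_effect = 0.2,
                                  resistant_effect = 1.5, slow_fold = 1.2,
                                  slow_light_effect = 0.4,
                                  grid = c(16L, 24L),
                                  controls_per_plate = 76L,
                                  day0_meanlog = log(100), day0_sdlog = 0.7,
                                  scoreable_min = 61,
                                  light_lmax = 1500, light_mid = 40,
                                  light_scale = 15, dark_fold = 3,
                                  dubious_fraction = 0.05,
                                  noise_sd = 5, seed = 1L) {
  if (n_sensitive + n_resistant + n_slow > n_strains)
    stop("planted sets exceed n_strains")
  if (resistant_effect <= 1 || sensitive_effect >= 1)
    stop("planted effect sizes contradict the light response range")
  if (slow_fold >= 1.5)
    stop("slow_fold must be below the 1.5-fold exclusion threshold")
  structure(list(n_strains = as.integer(n_strains),
                 n_sensitive = as.integer(n_sensitive),
                 n_resistant = as.integer(n_resistant),
                 n_slow = as.integer(n_slow),
                 sensitive_effect = sensitive_effect,
                 resistant_effect = resistant_effect,
                 slow_fold = slow_fold,
                 slow_light_effect = slow_light_effect,
                 grid = as.integer(grid),
                 controls_per_plate = as.integer(controls_per_plate),
                 day0_meanlog = day0_meanlog, day0_sdlog = day0_sdlog,
                 scoreable_min = scoreable_min,
                 light_lmax = light_lmax, light_mid = light_mid,
                 light_scale = light_scale, dark_fold = dark_fold,
                 dubious_fraction = dubious_fraction,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_screen_spec")
}

light_response <- function(d0, spec) {
  spec$light_lmax / (1 + exp(-(d0 - spec$light_mid) / spec$light_scale))
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower) {
  p0 <- stats::plnorm(lower, meanlog, sdlog)
  stats::qlnorm(p0 + stats::runif(n) * (1 - p0), meanlog, sdlog)
}

#' Simulate light/dark CDE tables for a whole screen
#'
#' Emits the four tables the scoring stage consumes (light day 0 and 6, dark
#' day 0 and 1), a layout, and the planted ground truth.  Controls are
#' scattered over every plate; each deletion strain occupies exactly one
#' position.  With `noise_sd = 0` the output is a deterministic function of
#' the spec (planted positions and initial densities are still drawn, but
#' from the seeded generator).
#'
#' @param spec A [synthetic_screen_spec()].
#' @return List with elements `light`, `dark` (CDE tables), `layout`
#'   (data frame `plate`, `row`, `col`, `strain`, `control_flag`,
#'   `dubious_flag`) and `truth` (data frame `strain`, `role` in
#'   `neutral/sensitive/resistant/slow`, `effect`).
#' @export
simulate_screen_tables <- function(spec) {
  stopifnot(inherits(spec, "synthetic_screen_spec"))
  set.seed(spec$seed)
  rows <- spec$grid[1]; cols <- spec$grid[2]
  per_plate <- rows * cols
  mut_per_plate <- per_plate - spec$controls_per_plate
  if (mut_per_plate < 1L) stop("controls_per_plate fills the whole plate")
  n_plates <- ceiling(spec$n_strains / mut_per_plate)

  strains <- sprintf("mut%04d", seq_len(spec$n_strains))
  planted <- sample(strains, spec$n_sensitive + spec$n_resistant + spec$n_slow)
  sens <- planted[seq_len(spec$n_sensitive)]
  resi <- planted[spec$n_sensitive + seq_len(spec$n_resistant)]
  slow <- planted[spec$n_sensitive + spec$n_resistant + seq_len(spec$n_slow)]
  dubious <- sample(setdiff(strains, planted),
                    round(spec$dubious_fraction * spec$n_strains))

  role <- rep("neutral", spec$n_strains); names(role) <- strains
  role[sens] <- "sensitive"; role[resi] <- "resistant"; role[slow] <- "slow"
  effect <- c(neutral = 1, sensitive = spec$sensitive_effect,
              resistant = spec$resistant_effect, slow = spec$slow_light_effect)

  # layout: controls at random positions, mutants filling the rest in order
  layout <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
    ctl <- sample(per_plate, spec$controls_per_plate)
    lab <- rep(NA_character_, per_plate)
    lab[ctl] <- "his3ctl"
    data.frame(plate = sprintf("plate%02d", p),
               row = rep(seq_len(rows), each = cols),
               col = rep(seq_len(cols), rows),
               strain = lab, stringsAsFactors = FALSE)
  }))
  open <- which(is.na(layout$strain))
  layout$strain[open[seq_along(strains)]] <- strains
  layout$strain[is.na(layout$strain)] <- "his3ctl"   # spare slots: controls
  layout$control_flag <- layout$strain == "his3ctl"
  layout$dubious_flag <- layout$strain %in% dubious

  n <- nrow(layout)
  is_planted <- !layout$control_flag & role[layout$strain] != "neutral"
  d0 <- stats::rlnorm(n, spec$day0_meanlog, spec$day0_sdlog)
  d0[is_planted] <- rlnorm_trunc(sum(is_planted), spec$day0_meanlog,
                                 spec$day0_sdlog, spec$scoreable_min)

  light_eff <- ifelse(layout$control_flag, 1, effect[role[layout$strain]])
  fold <- ifelse(!layout$control_flag & role[layout$strain] == "slow",
                 spec$slow_fold, spec$dark_fold)

  noise <- function(m) if (spec$noise_sd > 0)
    stats::rnorm(m, 0, spec$noise_sd) else numeric(m)

  mk <- function(condition, day, value)
    cbind(layout[c("plate", "row", "col", "strain", "control_flag",
                   "dubious_flag")],
          data.frame(condition = condition, day = day,
                     cde = value + noise(n)))

  light <- rbind(mk("light", 0L, d0),
                 mk("light", 6L, light_response(d0, spec) * light_eff))
  dark <- rbind(mk("dark", 0L, d0),
                mk("dark", 1L, d0 * fold))

  truth <- data.frame(strain = strains, role = unname(role[strains]),
                      effect = unname(ifelse(role[strains] == "slow",
                                             spec$slow_fold,
                                             effect[role[strains]])),
                      stringsAsFactors = FALSE)
  list(light = light, dark = dark,
       layout = layout[c("plate", "row", "col", "strain", "control_flag",
                         "dubious_flag")],
       truth = truth)
}

#' Simulate a serial-dilution drop-test table
#'
#' Emits per-strain, per-experiment spot intensities (INT/mm^2) for light
#' and dark plates over six tenfold dilutions at the quantification day.
#' Dark intensity at dilution `d` is `base * 10^-(d-1)`; light intensity is
#' the strain's light/dark ratio times the dark intensity one dilution
#' deeper, so the scored ratio (light dilution 1 over dark dilution 2)
#' recovers the strain ratio exactly at zero noise.  A wild-type row set is
#' always present.
#'
#' @param n_strains Number of mutant strains (`strain01`, ...).
#' @param n_experiments Independent experiments (at least 2; one ratio per
#'   experiment feeds the t test).
#' @param effect_map Named vector of multiplicative effects on the
#'   wild-type light/dark ratio (1 = no effect); names are strain ids,
#'   missing strains default to 1.
#' @param wt_ratio Wild-type light/dark ratio.
#' @param base Dark dilution-1 intensity (INT/mm^2).
#' @param noise_cv Lognormal coefficient of variation applied per spot
#'   (0 = none).
#' @param seed Integer seed.
#' @return Data frame with columns `strain`, `experiment`, `condition`,
#'   `dilution`, `day`, `intensity_per_area`.
#' @export
simulate_droptest <- function(n_strains = 10L, n_experiments = 2L,
                              effect_map = NULL, wt_ratio = 0.8,
                              base = 1000, noise_cv = 0, seed = 1L) {
  if (n_experiments < 2L)
    stop("n_experiments must be at least 2 (t test undefined otherwise)")
  set.seed(seed)
  strains <- c("wt", sprintf("strain%02d", seq_len(n_strains)))
  eff <- stats::setNames(rep(1, length(strains)), strains)
  if (!is.null(effect_map)) eff[names(effect_map)] <- effect_map
  grid <- expand.grid(strain = strains,
                      experiment = seq_len(n_experiments),
                      condition = c("light", "dark"),
                      dilution = 1:6, day = 3L,
                      stringsAsFactors = FALSE)
  dark_at <- function(d) base * 10^(-(d - 1))
  val <- ifelse(grid$condition == "dark", dark_at(grid$dilution),
                wt_ratio * eff[grid$strain] * dark_at(grid$dilution + 1))
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    val <- val * stats::rlnorm(nrow(grid), -sdlog^2 / 2, sdlog)
  }
  grid$intensity_per_area <- unname(val)
  grid[order(grid$strain, grid$experiment, grid$condition, grid$dilution), ]
}
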