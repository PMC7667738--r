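# Small hand-built screen fixture: one plate, controls plus a few strains
# with prescribed CDEs.
make_fixture <- function(strains) {
  # strains: data.frame(strain, control_flag, ld0, ld6, dd0, dd1)
  n <- nrow(strains)
  layout <- data.frame(plate = "p1", row = 1, col = seq_len(n),
                       strain = strains$strain,
                       control_flag = strains$control_flag,
                       dubious_flag = FALSE, stringsAsFactors = FALSE)
  mk <- function(cond, day, val)
    cbind(layout, data.frame(condition = cond, day = day, cde = val))
  list(light = rbind(mk("light", 0L, strains$ld0),
                     mk("light", 6L, strains$ld6)),
       dark = rbind(mk("dark", 0L, strains$dd0),
                    mk("dark", 1L, strains$dd1)),
       layout = layout)
}

test_that("density bands follow the inclusive boundaries", {
  thr <- screen_thresholds()
  expect_equal(density_band(c(121, 61, 60, 0, 200, 120.5), thr),
               c("high", "moderate", "discarded", "discarded", "high",
                 "moderate"))
  # confirmation variants shift the band edges
  hap <- screen_thresholds("confirm_haploid")
  expect_equal(density_band(c(13, 12), hap), c("high", "discarded"))
  dip <- screen_thresholds("confirm_diploid")
  expect_equal(density_band(c(105, 104, 45, 44), dip),
               c("high", "moderate", "moderate", "discarded"))
})

test_that("criterium I applies the band's strict day-6 cutoff", {
  thr <- screen_thresholds()
  expect_true(criterium1(150, 899, thr))
  expect_false(criterium1(150, 900, thr))
  expect_true(criterium1(100, 399, thr))
  expect_false(criterium1(100, 400, thr))
  expect_error(criterium1(50, 100, thr), "discarded")
  dip <- screen_thresholds("confirm_diploid")
  expect_true(criterium1(50, 499, dip))
  expect_false(criterium1(50, 500, dip))
})

test_that("slow growers are excluded strictly below the 1.5-fold boundary", {
  thr <- screen_thresholds()
  expect_true(slow_growth_excluded(100, 149, thr))
  expect_false(slow_growth_excluded(100, 150, thr))
  expect_false(slow_growth_excluded(100, 300, thr))
  expect_true(is.na(slow_growth_excluded(0, 100, thr)))
})

test_that("control band medians aggregate in-band control ratios", {
  fx <- make_fixture(data.frame(
    strain = c("c1", "c2", "c3", "m1"),
    control_flag = c(TRUE, TRUE, TRUE, FALSE),
    ld0 = c(150, 160, 170, 150), ld6 = c(100, 400, 400, 500),
    dd0 = c(100, 100, 100, 100), dd1 = c(100, 200, 100, 300)))
  cm <- control_band_medians(fx$light, fx$dark, fx$layout)
  # ratios 1, 2, 4 -> odd-count median 2
  expect_equal(cm$ctrl_median[cm$band == "high"], 2)
  # moderate band empty on every plate -> NA median, and scoring a
  # moderate-band strain against it errors
  fx2 <- make_fixture(data.frame(
    strain = c("c1", "m1"), control_flag = c(TRUE, FALSE),
    ld0 = c(150, 80), ld6 = c(300, 300), dd0 = c(100, 100),
    dd1 = c(100, 200)))
  cm2 <- control_band_medians(fx2$light, fx2$dark, fx2$layout)
  expect_true(is.na(cm2$ctrl_median[cm2$band == "moderate"]))
  expect_error(score_screen(fx2$light, fx2$dark, fx2$layout), "no control")
})

test_that("missing in-band controls borrow from the nearest plate by index", {
  lay <- data.frame(plate = rep(c("p1", "p2", "p3"), each = 2),
                    row = 1, col = rep(1:2, 3),
                    strain = "ctl", control_flag = TRUE,
                    dubious_flag = FALSE, stringsAsFactors = FALSE)
  # p1 controls: high band ratio 2; p2: high only; p3: high + moderate
  ld0 <- c(150, 80, 150, 150, 150, 80)
  ld6 <- c(200, 100, 300, 300, 400, 150)
  dd1 <- c(100, 50, 100, 100, 100, 50)
  mk <- function(cond, day, val)
    cbind(lay, data.frame(condition = cond, day = day, cde = val))
  light <- rbind(mk("light", 0L, ld0), mk("light", 6L, ld6))
  dark <- rbind(mk("dark", 0L, ld0), mk("dark", 1L, dd1))
  cm <- control_band_medians(light, dark, lay)
  # p2 moderate is missing; p1 and p3 are equidistant -> lower index wins
  expect_equal(cm$ctrl_median[cm$plate == "p2" & cm$band == "moderate"],
               100 / 50)
  expect_equal(cm$source_plate[cm$plate == "p2" & cm$band == "moderate"],
               "p1")
})

test_that("LGnorm is the doubly normalized light/dark growth", {
  expect_equal(lgnorm(100, 200, 2), 0.25)
  expect_equal(lgnorm(300, 100, 3), 1)
  expect_true(is.na(lgnorm(100, 0, 2)))
  expect_true(is.na(lgnorm(100, 50, -1)))
})

test_that("median control LGnorm is exactly 1 per plate and band", {
  spec <- synthetic_screen_spec(n_strains = 400, n_sensitive = 20, seed = 8)
  tabs <- simulate_screen_tables(spec)
  sc <- score_screen(tabs$light, tabs$dark, tabs$layout)
  calls <- sc$calls[sc$calls$control_flag & !is.na(sc$calls$lgnorm), ]
  meds <- tapply(calls$lgnorm, paste(calls$plate, calls$band), median)
  expect_true(all(abs(meds - 1) < 1e-12))
})

test_that("verdicts assemble criteria, exclusions and audit reasons", {
  fx <- make_fixture(data.frame(
    strain = c("c1", "c2", "c3", "mlow", "mslow", "msens", "mok", "mres",
               "mmiss"),
    control_flag = c(TRUE, TRUE, TRUE, rep(FALSE, 6)),
    ld0 = c(150, 160, 170, 40, 150, 150, 150, 200, 150),
    ld6 = c(1300, 1400, 1500, 100, 500, 200, 1300, 1700, 1300),
    dd0 = c(100, 100, 100, 100, 100, 100, 100, 100, 100),
    dd1 = c(300, 300, 300, 300, 120, 300, 300, 300, NA)))
  sc <- score_screen(fx$light, fx$dark, fx$layout)
  v <- setNames(sc$calls$verdict, sc$calls$strain)
  expect_equal(unname(v[c("mlow", "mslow", "msens", "mok", "mres",
                          "mmiss")]),
               c("excluded_low_density", "excluded_slow_growth",
                 "sensitive_high", "not_called", "resistant",
                 "excluded_missing_data"))
  # every layout position gets exactly one verdict, with a reason on
  # every exclusion
  expect_equal(nrow(sc$calls), nrow(fx$layout))
  excl <- grepl("^excluded", sc$calls$verdict)
  expect_true(all(nzchar(sc$calls$reasons[excl])))
  # msens: LG/DG = 200/300 vs control median 1400/300 -> lgnorm = 1/7
  expect_equal(v[["msens"]], "sensitive_high")
  expect_equal(sc$calls$lgnorm[sc$calls$strain == "msens"], (200 / 300) /
                 (1400 / 300))
})

test_that("sensitive verdicts need both criteria", {
  # criterium I met but LGnorm above cutoff: dark growth equally poor
  fx <- make_fixture(data.frame(
    strain = c("c1", "c2", "c3", "mdark"),
    control_flag = c(TRUE, TRUE, TRUE, FALSE),
    ld0 = c(150, 160, 170, 150),
    ld6 = c(1300, 1400, 1500, 800),
    dd0 = c(100, 100, 100, 100),
    dd1 = c(300, 300, 300, 180)))
  sc <- score_screen(fx$light, fx$dark, fx$layout)
  row <- sc$calls[sc$calls$strain == "mdark", ]
  expect_equal(row$verdict, "not_called")   # lgnorm = (800/180)/(1400/300)
  expect_gt(row$lgnorm, 0.75)
})

test_that("null screens call nothing and planted screens are recovered", {
  null_spec <- synthetic_screen_spec(n_strains = 300, noise_sd = 0, seed = 6)
  tabs <- simulate_screen_tables(null_spec)
  s <- summary(score_screen(tabs$light, tabs$dark, tabs$layout))
  expect_length(c(s$sensitive_high, s$sensitive_moderate), 0)
  expect_length(s$resistant, 0)

  spec <- synthetic_screen_spec(n_strains = 400, n_sensitive = 40,
                                n_resistant = 10, n_slow = 10,
                                noise_sd = 0, seed = 6)
  tabs <- simulate_screen_tables(spec)
  s <- summary(score_screen(tabs$light, tabs$dark, tabs$layout))
  truth <- tabs$truth
  expect_setequal(c(s$sensitive_high, s$sensitive_moderate),
                  truth$strain[truth$role == "sensitive"])
  expect_setequal(s$resistant, truth$strain[truth$role == "resistant"])
  expect_setequal(s$slow_excluded, truth$strain[truth$role == "slow"])
})

test_that("package calls match a naive re-scoring of the same tables", {
  spec <- synthetic_screen_spec(n_strains = 500, n_sensitive = 50,
                                n_resistant = 15, n_slow = 15, seed = 10)
  tabs <- simulate_screen_tables(spec)
  s <- summary(score_screen(tabs$light, tabs$dark, tabs$layout))
  naive <- naive_rescore(tabs)
  expect_setequal(c(s$sensitive_high, s$sensitive_moderate), naive$sensitive)
  expect_setequal(s$slow_excluded, naive$slow)
  expect_setequal(s$resistant,
                  setdiff(naive$resistant, c(naive$slow, naive$sensitive)))
})

test_that("LGnorm is equivariant under per-plate light rescaling", {
  fx <- make_fixture(data.frame(
    strain = c("c1", "c2", "c3", "m1", "m2"),
    control_flag = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    ld0 = c(200, 210, 250, 230, 260),
    ld6 = c(1300, 1400, 1500, 700, 1200),
    dd0 = c(100, 100, 100, 100, 100),
    dd1 = c(300, 300, 300, 300, 250)))
  sc1 <- score_screen(fx$light, fx$dark, fx$layout)
  k <- 1.2   # all day-0 CDEs stay within the high band
  fx$light$cde <- fx$light$cde * k
  sc2 <- score_screen(fx$light, fx$dark, fx$layout)
  expect_equal(sc2$calls$lgnorm, sc1$calls$lgnorm)
})

test_that("false-positive rate is the in-band control fraction below cutoff", {
  fx <- make_fixture(data.frame(
    strain = sprintf("c%d", 1:20),
    control_flag = TRUE,
    ld0 = rep(150, 20),
    ld6 = c(899, rep(1300, 19)),
    dd0 = 100, dd1 = 300))
  expect_equal(estimate_false_positive_rate(fx$light, band = "high"), 0.05)
  fx$light$cde[fx$light$day == 6] <- 1300
  expect_equal(estimate_false_positive_rate(fx$light, band = "high"), 0)
  expect_error(estimate_false_positive_rate(fx$light, band = "moderate"),
               "no control")
})

test_that("resistant calls respect the strict boundary and density gate", {
  fx <- make_fixture(data.frame(
    strain = c("a", "b", "c", "d"),
    control_flag = FALSE,
    ld0 = c(100, 100, 50, 61),
    ld6 = c(1642, 1643, 5000, 1700),
    dd0 = 100, dd1 = 300))
  expect_setequal(call_resistant(fx$light), c("b", "d"))
})

test_that("thresholds validate overrides and band ordering", {
  thr <- screen_thresholds(lgnorm_cutoff = 0.25)
  expect_equal(thr$lgnorm_cutoff, 0.25)
  expect_error(screen_thresholds(nonsense = 1), "unknown")
  expect_error(screen_thresholds(moderate_min = 200), "ordered")
})
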