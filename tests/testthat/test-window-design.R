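test_that("one global 4-Th grid (offset 1) reproduces both printed placements", {
  w1 <- place_pair_windows(pair_l858r)
  expect_equal(w1$start_mz, c(453, 457))
  expect_equal(w1$end_mz, c(457, 461))
  w2 <- place_pair_windows(pair_del19wt)
  expect_equal(w2$start_mz, c(513, 517))
  expect_equal(w2$end_mz, c(517, 521))
  expect_false(any(w1$off_grid) || any(w2$off_grid))
  expect_error(place_pair_windows(c(300, 304)), "outside scan range")
})

test_that("same-grid-cell pairs get midpoint-re-anchored windows, flagged", {
  # both m/z inside grid cell [501, 505): spacing 1.5 < width 4
  w <- place_pair_windows(c(501.5, 503.0))
  expect_true(all(w$off_grid))
  expect_equal(w$end_mz[1], 502.25)  # midpoint of the pair
  expect_equal(w$start_mz[1], 502.25 - 4)
  expect_equal(w$end_mz[2], 502.25 + 4)
  # each precursor strictly inside its own window
  expect_true(w$start_mz[1] < 501.5 && 501.5 < w$end_mz[1])
  expect_true(w$start_mz[2] < 503.0 && 503.0 < w$end_mz[2])
})

test_that("heavy-Lys 2+ pairs always land in distinct cells; adjacent off boundaries", {
  set.seed(23)
  spacing <- isotope_label("heavy_K")$mass_shift / 2
  mz <- runif(1000, 405, 990)
  cell <- function(x) floor((x - 1) / 4)
  cl <- cell(mz); ch <- cell(mz + spacing)
  expect_true(all(ch > cl))  # spacing 4.0071 > 4 guarantees distinct cells
  # adjacency holds except when light sits within spacing-4 below a boundary
  frac <- (mz - 1) %% 4
  generic <- frac < 4 - (spacing - 4)
  expect_true(all((ch - cl)[generic] == 1))
})

test_that("designer: 8 well-separated pairs -> 16 narrow + 20 wide = 36 windows", {
  pairs <- synth_panel(8, seed = 7)
  sch <- design_scheme(pairs, n_wide = 20)
  counts <- table(sch$windows$kind)
  expect_identical(unname(counts[["narrow_target"]]), 16L)
  expect_identical(unname(counts[["wide_profile"]]), 20L)
  expect_identical(nrow(sch$windows), 36L)
  rep <- validate_scheme(sch, pairs)
  expect_true(rep$ok)
  expect_true(all(rep$pair_separation$pair_separation_ok))
})

test_that("scheme tiling invariants: widths sum to span, contiguous, sorted", {
  for (seed in c(2, 9, 31)) {
    pairs <- synth_panel(sample(3:10, 1), seed = seed)
    sch <- design_scheme(pairs, n_wide = 20)
    w <- sch$windows
    expect_equal(sum(w$width), diff(sch$scan_range), tolerance = 1e-9)
    expect_equal(w$start_mz[-1], w$end_mz[-nrow(w)], tolerance = 1e-9)
    expect_equal(w$start_mz[1], sch$scan_range[1])
    expect_equal(w$end_mz[nrow(w)], sch$scan_range[2])
  }
})

test_that("single-pair scheme with two wide windows matches the hand tiling", {
  sch <- design_scheme(list(pair_l858r), n_wide = 2)
  expect_equal(sch$windows$start_mz, c(400, 453, 457, 461))
  expect_equal(sch$windows$end_mz, c(453, 457, 461, 1000))
  expect_identical(sch$windows$kind, c("wide_profile", "narrow_target",
                                       "narrow_target", "wide_profile"))
})

test_that("zero pairs with 40 wide windows is the fixed 15-Th scheme", {
  sch <- design_scheme(list(), n_wide = 40)
  expect_identical(nrow(sch$windows), 40L)
  expect_equal(unique(round(sch$windows$width, 9)), 15)
})

test_that("equal-width scheme: 40 x 15 Th, and the coisolating window is [505, 520)", {
  sch <- equal_width_scheme(c(400, 1000), 40)
  expect_equal(sch$windows$width, rep(15, 40))
  expect_equal(sch$windows$start_mz, seq(400, 985, by = 15))
  il <- assign_window(sch, pair_del19wt$light$mz)
  ih <- assign_window(sch, pair_del19wt$heavy$mz)
  expect_identical(il, ih)
  expect_equal(sch$windows$start_mz[il], 505)
  expect_equal(sch$windows$end_mz[il], 520)
  one <- equal_width_scheme(c(0, 10), 1)
  expect_equal(one$windows$start_mz, 0)
  expect_equal(one$windows$end_mz, 10)
})

test_that("assign_window follows the half-open boundary rule", {
  sch <- design_scheme(list(pair_l858r), n_wide = 2)
  expect_equal(sch$windows$start_mz[assign_window(sch, 454.25)], 453)
  # exactly on the shared boundary -> right-hand window
  expect_equal(sch$windows$start_mz[assign_window(sch, 457)], 457)
  expect_error(assign_window(sch, 1200), "outside scan range")
})

test_that("uniform density reduces variable widths to the equal-width scheme", {
  d <- precursor_density(c(400, 1000), c(1, 1))
  vs <- variable_width_scheme(c(400, 1000), 40, d)
  es <- equal_width_scheme(c(400, 1000), 40)
  expect_equal(vs$windows$start_mz, es$windows$start_mz, tolerance = 1e-9)
  expect_equal(vs$windows$end_mz, es$windows$end_mz, tolerance = 1e-9)
})

test_that("variable widths track local density; mass split 3:1 puts the boundary at 50%", {
  # 3/4 of the precursor mass below 550: windows narrower there
  d <- precursor_density(c(400, 549.999, 550.001, 1000),
                         c(3 / 150, 3 / 150, 1 / 450, 1 / 450))
  vs <- variable_width_scheme(c(400, 1000), 20, d)
  low <- vs$windows$width[vs$windows$end_mz <= 550]
  high <- vs$windows$width[vs$windows$start_mz >= 550]
  expect_true(median(low) < median(high))
  # per-window density mass approximately equal (cumulative-sum oracle)
  cum <- function(x) {
    g <- seq(400, 1000, length.out = 20001)
    w <- approx(d$mz, d$weight, g, rule = 2)$y
    f <- c(0, cumsum(diff(g) * (w[-1] + w[-length(w)]) / 2))
    approx(g, f, x)$y
  }
  mass <- cum(vs$windows$end_mz) - cum(vs$windows$start_mz)
  expect_true(max(abs(mass - mean(mass))) / mean(mass) < 0.05)
  # n = 2: boundary at the 50% cumulative point (= 500 for this density)
  vs2 <- variable_width_scheme(c(400, 1000), 2, d)
  expect_equal(vs2$windows$end_mz[1], 500, tolerance = 0.5)
  expect_error(variable_width_scheme(c(400, 1000), 5,
                                     precursor_density(c(400, 1000), c(0, 0))),
               "no mass")
})

test_that("largest-remainder allocation conserves the wide-window count", {
  set.seed(77)
  for (rep in 1:20) {
    pairs <- synth_panel(sample(2:8, 1), seed = rep)
    d <- precursor_density(seq(400, 1000, by = 50), runif(13, 0.1, 5))
    n_wide <- sample(10:40, 1)
    sch <- design_scheme(pairs, n_wide = n_wide, density = d)
    expect_identical(sum(sch$windows$kind == "wide_profile"), n_wide)
    expect_identical(sum(sch$windows$kind == "narrow_target"), 2L * length(pairs))
    expect_true(validate_scheme(sch, pairs)$ok)
  }
})

test_that("width clamping respects bounds and infeasible budgets error", {
  pairs <- synth_panel(8, seed = 7)
  sch <- design_scheme(pairs, n_wide = 20, wide_bounds = c(4, 60))
  wide <- sch$windows[sch$windows$kind == "wide_profile", ]
  expect_true(all(wide$width >= 4 - 1e-9 & wide$width <= 60 + 1e-9))
  expect_error(design_scheme(list(pair_l858r), n_wide = 2, wide_bounds = c(4, 60)),
               "cannot tile")
  expect_error(design_scheme(list(pair_l858r), n_wide = 1), "gaps to tile")
})

test_that("validate_scheme reports holes and coisolation", {
  holey <- window_scheme(
    data.frame(start_mz = c(400, 500), end_mz = c(450, 1000),
               kind = "wide_profile"), c(400, 1000))
  rep <- validate_scheme(holey)
  expect_false(rep$coverage_ok)
  fix <- equal_width_scheme(c(400, 1000), 40)
  rep2 <- validate_scheme(fix, list(pair_del19wt))
  expect_false(rep2$pair_separation[1, "pair_separation_ok"])
  iso <- design_scheme(list(pair_del19wt), n_wide = 2)
  rep3 <- validate_scheme(iso, list(pair_del19wt))
  expect_true(rep3$pair_separation[1, "pair_separation_ok"])
})
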