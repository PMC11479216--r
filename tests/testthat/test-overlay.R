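test_that("weighted overlay reproduces hand-computed scores", {
  mk <- function(score) grid_layer(matrix(score, 3, 3), pixel_size = 10)
  crit_names <- c("rainfall", "avg_temp", "min_temp", "max_temp", "ph",
                  "texture", "cec", "som", "elevation", "slope", "aspect",
                  "lulc", "dist_road", "dist_river")
  climate <- crit_names[1:4]

  # all suitable -> 3; all unsuitable -> 1 (weights sum to 1)
  w_eq <- setNames(rep(1 / 14, 14), crit_names)
  all3 <- weighted_overlay(setNames(lapply(crit_names, \(n) mk(3)), crit_names), w_eq)
  expect_true(all(abs(all3$values - 3) < 1e-12))
  all1 <- weighted_overlay(setNames(lapply(crit_names, \(n) mk(1)), crit_names), w_eq)
  expect_true(all(abs(all1$values - 1) < 1e-12))

  # climate group (total weight 0.6) suitable, everything else sub-suitable:
  # 3 * 0.6 + 2 * 0.4 = 2.6
  w_grp <- setNames(c(rep(0.6 / 4, 4), rep(0.4 / 10, 10)), crit_names)
  layers <- setNames(lapply(crit_names,
                            \(n) mk(if (n %in% climate) 3 else 2)),
                     crit_names)
  out <- weighted_overlay(layers, w_grp)
  expect_equal(out$values[2, 2], 2.6)
})

test_that("overlay validates names, weight sum and co-registration", {
  a <- grid_layer(matrix(2, 2, 2), pixel_size = 10)
  b <- grid_layer(matrix(3, 2, 2), pixel_size = 10)
  expect_error(weighted_overlay(list(a = a, b = b), c(a = 0.5, c = 0.5)),
               "mismatch")
  expect_error(weighted_overlay(list(a = a, b = b), c(a = 0.6, b = 0.6)),
               "sum to 1")
  off <- grid_layer(matrix(3, 2, 2), pixel_size = 20)
  expect_error(weighted_overlay(list(a = a, b = off), c(a = 0.5, b = 0.5)),
               "'b'")
})

test_that("overlay equals the per-cell brute-force oracle exactly on 32x32 grids", {
  set.seed(47)
  for (rep in 1:3) {
    layers <- setNames(lapply(1:5, \(i) random_score_layer(32, 32, na_frac = 0.05)),
                       paste0("c", 1:5))
    w_raw <- runif(5)
    w <- setNames(w_raw / sum(w_raw), names(layers))
    out <- weighted_overlay(layers, w)
    expect_identical(out$values, pacp_oracle(layers, w))
  }
})

test_that("raising one criterion's score never lowers the overlay score", {
  set.seed(53)
  layers <- setNames(lapply(1:4, \(i) random_score_layer(8, 8)), paste0("c", 1:4))
  w <- setNames(rep(0.25, 4), names(layers))
  base <- weighted_overlay(layers, w)
  bumped <- layers
  v <- bumped$c2$values
  cell <- which(v < 3)[1]
  v[cell] <- v[cell] + 1
  bumped$c2 <- grid_layer(v, pixel_size = 10)
  out <- weighted_overlay(bumped, w)
  expect_gte(out$values[cell], base$values[cell])
  expect_equal(out$values[-cell], base$values[-cell])
})

test_that("nodata policy: strict propagation by default, reweighting on request", {
  a <- grid_layer(matrix(c(3, 3), 1), pixel_size = 10)
  b <- grid_layer(matrix(c(1, NA), 1), pixel_size = 10)
  strict <- weighted_overlay(list(a = a, b = b), c(a = 0.75, b = 0.25))
  expect_equal(as.vector(strict$values), c(2.5, NA))
  rw <- weighted_overlay(list(a = a, b = b), c(a = 0.75, b = 0.25),
                         reweight_missing = TRUE)
  expect_equal(as.vector(rw$values), c(2.5, 3))
})

test_that("suitability classes follow the breaks with nodata preserved", {
  g <- grid_layer(matrix(c(1, 2, 3, 1.5, 5 / 3, 7 / 3, NA, 2.9, 1.1), 3, 3),
                  pixel_size = 10)
  cl <- classify_suitability(g)
  expect_equal(as.vector(cl$values), c(1, 2, 3, 1, 2, 3, NA, 3, 1))
  expect_error(classify_suitability(g, breaks = c(0.5, 2)), "breaks")
  expect_error(classify_suitability(g, breaks = c(2.5, 2)), "breaks")
  const <- classify_suitability(grid_layer(matrix(2, 4, 4), 10))
  expect_true(all(const$values == 2))
})

test_that("area tabulation matches hand arithmetic and degenerate cases", {
  v <- matrix(c(rep(1, 100), rep(2, 200), rep(3, 100)), 20, 20)
  g <- grid_layer(v, pixel_size = 10)
  tab <- tabulate_areas(g)
  expect_equal(tab$area_km2, c(0.01, 0.02, 0.01, 0.04))
  expect_equal(tab$pct, c(25, 50, 25, 100))

  one <- tabulate_areas(grid_layer(matrix(3, 5, 5), 10))
  expect_equal(one$pct[one$class == "3"], 100)

  empty <- tabulate_areas(grid_layer(matrix(NA_real_, 3, 3), 10))
  expect_equal(empty$area_km2[empty$class == "total"], 0)
  expect_true(all(empty$cells == 0))
})

test_that("class areas are conserved over random scenes (100 seeds)", {
  for (seed in 1:100) {
    set.seed(seed)
    nr <- sample(5:12, 1); nc <- sample(5:12, 1)
    v <- matrix(sample(c(1:3, NA), nr * nc, replace = TRUE), nr, nc)
    g <- grid_layer(v, pixel_size = 10)
    tab <- tabulate_areas(g)
    valid <- sum(!is.na(v))
    expect_equal(sum(tab$area_km2[tab$class != "total"]), valid * 1e-4)
    expect_equal(tab$area_km2[tab$class == "total"], valid * 1e-4)
    if (valid > 0) {
      expect_equal(sum(tab$pct[tab$class != "total"]), 100, tolerance = 1e-9)
    }
  }
})

test_that("accuracy metrics reproduce hand-computed values", {
  perfect <- accuracy_metrics(diag(c(10, 20, 30)))
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(perfect$kappa, 1)

  m <- matrix(c(40, 10, 10, 40), 2, byrow = TRUE)
  res <- accuracy_metrics(m)
  expect_equal(res$overall_accuracy, 0.8)
  expect_equal(res$kappa, 0.6)

  uniform <- accuracy_metrics(matrix(5, 3, 3))
  expect_equal(uniform$kappa, 0)

  # tidy long-format input
  df <- data.frame(reference = c("a", "a", "b", "b"),
                   predicted = c("a", "b", "b", "b"))
  res_df <- accuracy_metrics(df)
  expect_equal(res_df$overall_accuracy, 0.75)

  expect_error(accuracy_metrics(matrix(0, 2, 2)), "empty")
  degenerate <- matrix(c(7, 0, 0, 0), 2, byrow = TRUE)
  expect_warning(res_d <- accuracy_metrics(degenerate), "undefined")
  expect_true(is.na(res_d$kappa))
})

test_that("validation points report the class under each point", {
  v <- matrix(c(3, 1, NA, 2), 2, 2)
  g <- grid_layer(v, pixel_size = 10)
  pts <- tibble::tibble(x = c(5, 5, 15, 15), y = c(15, 5, 15, 5),
                        label = "coffee")
  rep <- validate_points(g, pts)
  expect_equal(rep$predicted_class, c(3, 1, NA, 2))
  expect_equal(rep$predicted_label[1], "suitable")
  expect_false(rep$scored[3])

  # points placed only inside class-3 cells all come back suitable
  set.seed(61)
  cl <- random_score_layer(16, 16)
  idx <- which(cl$values == 3, arr.ind = TRUE)
  pick <- idx[sample(nrow(idx), 20, replace = TRUE), , drop = FALSE]
  cc <- cell_centers(cl)
  pts3 <- tibble::tibble(x = cc$x[pick[, 2]], y = cc$y[pick[, 1]])
  rep3 <- validate_points(cl, pts3)
  expect_true(all(rep3$predicted_class == 3))
  smry <- attr(rep3, "summary")
  expect_equal(smry$points[smry$predicted_label == "suitable"], 20L)
})
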