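test_that("pairwise matrix validation rejects malformed judgments with cell indices", {
  expect_error(pairwise_matrix(matrix(1, 2, 3)), "square")
  expect_error(pairwise_matrix(rbind(c(1, 2), c(0.5, 1)), labels = "a"), "labels")

  m_neg <- rbind(c(1, -2), c(-0.5, 1))
  expect_error(pairwise_matrix(m_neg), "nonpositive.*cell \\(2,1\\)")

  m_diag <- rbind(c(2, 1), c(1, 1))
  expect_error(pairwise_matrix(m_diag), "diagonal.*\\(1,1\\)")

  m_recip <- rbind(c(1, 5), c(0.3, 1))
  expect_error(pairwise_matrix(m_recip), "reciprocity.*\\(2,1\\)")
})

test_that("an upper triangle is completed by reciprocity", {
  m <- matrix(NA_real_, 3, 3)
  diag(m) <- 1
  m[1, 2] <- 3; m[1, 3] <- 5; m[2, 3] <- 3 / 2
  pm <- pairwise_matrix(m, labels = c("a", "b", "c"))
  expect_equal(pm["b", "a"], 1 / 3)
  expect_equal(pm["c", "b"], 2 / 3)
})

test_that("fraction strings parse exactly as rationals", {
  expect_equal(parse_judgment(c("3/2", "2/3", "1", "0.25")),
               c(1.5, 2 / 3, 1, 0.25))
  # a stray trailing slash, as seen in hand-typed tables, is tolerated
  expect_equal(parse_judgment("1/3/"), 1 / 3)
  m <- pairwise_matrix(rbind(c("1", "3/2"), c("2/3", "1")))
  expect_equal(m[2, 1], 2 / 3)
})

test_that("the all-ones matrix is valid, equal-weighted and perfectly consistent", {
  for (n in c(2, 4, 7)) {
    pm <- pairwise_matrix(matrix(1, n, n))
    w <- priority_weights(pm)
    expect_equal(w$weight, rep(1 / n, n))
    expect_equal(lambda_max(pm), n, tolerance = 1e-12)
    res <- ahp_consistency(pm)
    expect_equal(res$ci, 0, tolerance = 1e-12)
    expect_equal(res$cr, 0, tolerance = 1e-12)
  }
})

test_that("a consistent matrix built from known weights recovers them exactly", {
  w_true <- c(0.5, 0.3, 0.2)
  m <- outer(w_true, w_true, `/`)
  pm <- pairwise_matrix(m, labels = c("a", "b", "c"))
  norm <- normalize_columns(pm)
  # every normalised column equals the weight vector
  for (col in c("a", "b", "c")) expect_equal(norm[[col]], w_true)
  expect_equal(priority_weights(pm)$weight, w_true, tolerance = 1e-12)
  expect_equal(lambda_max(pm), 3, tolerance = 1e-12)
})

test_that("main-factor matrix reproduces the published normalisation and weights", {
  m <- worked_matrices()$main
  norm <- normalize_columns(m)
  # printed column: 0.606, 0.121, 0.151, 0.121 (third entry truncated from
  # the exact 0.25/1.65 = 0.1515)
  expect_lt(max(abs(norm$climatology - c(0.606, 0.121, 0.151, 0.121))), 1e-3)

  w <- priority_weights(m)
  expect_equal(round_half_up(w$weight[1:3], 2), c(0.60, 0.16, 0.15))
  # the published table truncates the fourth weight (0.0972) to 0.09
  expect_lt(abs(w$weight[4] - 0.09), 0.01)
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)

  res <- ahp_consistency(m)
  expect_lt(abs(res$lambda_max - 4.08), 0.01)
  expect_lt(abs(res$ci - 0.0267), 5e-4)
  expect_lt(abs(res$cr - 0.029), 2e-3)
})

test_that("all sub-factor matrices reproduce their published weights at 2 dp", {
  wm <- worked_matrices()
  published <- list(
    climatology = c(0.27, 0.39, 0.13, 0.21),
    edaphic = c(0.37, 0.28, 0.20, 0.15),
    physiographic = c(0.65, 0.21, 0.14),
    socioeconomic = c(0.60, 0.23, 0.17)
  )
  for (nm in names(published)) {
    w <- priority_weights(wm[[nm]])
    expect_equal(round_half_up(w$weight, 2), published[[nm]],
                 info = nm)
  }
  expect_lt(abs(ahp_consistency(wm$edaphic)$cr - 0.008), 1e-3)
  expect_lt(abs(ahp_consistency(wm$physiographic)$cr - 0.001), 1e-3)
})

test_that("row-average weights agree with the principal eigenvector within 0.01", {
  for (nm in names(worked_matrices())) {
    m <- worked_matrices()[[nm]]
    pw <- priority_weights(m)$weight
    ev <- power_iteration(unclass(m))$vector
    expect_lt(max(abs(pw - ev)), 0.01)
    # and the row-ratio lambda estimate is close to the principal eigenvalue
    expect_equal(lambda_max(m), power_iteration(unclass(m))$value,
                 tolerance = 0.01)
  }
})

test_that("lambda_max >= n, with equality exactly for consistent matrices", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(3:6, 1)
    # random reciprocal matrix from Saaty-scale judgments
    m <- diag(n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- sample(c(1 / 5, 1 / 3, 1 / 2, 2 / 3, 1, 3 / 2, 2, 3, 5), 1)
        m[i, j] <- a
        m[j, i] <- 1 / a
      }
    }
    pm <- pairwise_matrix(m)
    expect_gte(lambda_max(pm), n - 1e-9)
  }
  # consistency: aik = aij * ajk implies lambda = n
  w <- c(0.4, 0.35, 0.15, 0.1)
  cm <- pairwise_matrix(outer(w, w, `/`))
  expect_equal(lambda_max(cm), 4, tolerance = 1e-9)
})

test_that("permuting labels permutes weights identically", {
  set.seed(23)
  m <- worked_matrices()$main
  for (rep in 1:10) {
    p <- sample(nrow(m))
    mp <- pairwise_matrix(unclass(m)[p, p], labels = rownames(m)[p])
    w0 <- priority_weights(m)
    wp <- priority_weights(mp)
    expect_equal(wp$weight, w0$weight[p], tolerance = 1e-12)
    expect_equal(wp$criterion, w0$criterion[p])
  }
})

test_that("matrix order outside the RI table is an explicit error", {
  m <- pairwise_matrix(matrix(1, 11, 11))
  expect_error(ahp_consistency(m), "RI table")
  # a custom RI table extends the supported orders
  ri_ext <- c(ri_saaty, "11" = 1.51)
  expect_equal(ahp_consistency(m, ri = ri_ext)$cr, 0)
})

test_that("hierarchical composition reproduces the published composite weights", {
  h <- coffee_hierarchy()
  w <- compose_weights(h)
  expect_equal(sum(w$weight), 1, tolerance = 1e-6)

  published <- c(
    rainfall = 0.162, avg_temp = 0.234, min_temp = 0.078, max_temp = 0.126,
    ph = 0.0592, texture = 0.0448, cec = 0.032, som = 0.024,
    elevation = 0.0975, slope = 0.0315, aspect = 0.021,
    lulc = 0.054, dist_road = 0.0207, dist_river = 0.0153
  )
  got <- setNames(w$weight, w$criterion)
  for (nm in names(published)) {
    expect_lt(abs(got[[nm]] - published[[nm]]), 0.005)
  }
  # spot-check the multiplicative structure against the printed products
  expect_equal(got[["avg_temp"]],
               w$main_weight[w$criterion == "avg_temp"] *
                 w$sub_weight[w$criterion == "avg_temp"])
})

test_that("composition refuses inconsistent hierarchies, naming the matrix", {
  # a deliberately erratic 3x3 judgment set (CR well above 0.1)
  bad <- pairwise_matrix(rbind(
    c(1, 9, 1 / 9), c(1 / 9, 1, 9), c(9, 1 / 9, 1)
  ), labels = c("p", "q", "r"))
  main <- pairwise_matrix(matrix(1, 2, 2), labels = c("A", "B"))
  sub_ok <- pairwise_matrix(matrix(1, 2, 2), labels = c("s1", "s2"))
  h <- ahp_hierarchy(main, list(A = bad, B = sub_ok))
  expect_error(compose_weights(h), "'A'")
  forced <- compose_weights(h, force = TRUE)
  expect_equal(sum(forced$weight), 1, tolerance = 1e-9)
})

test_that("a single main criterion with one sub-criterion composes to weight 1", {
  main <- pairwise_matrix(matrix(1, 2, 2), labels = c("only", "other"))
  # degenerate 2-level case: each main criterion has equal-importance subs
  h <- ahp_hierarchy(main, list(
    only = pairwise_matrix(matrix(1, 2, 2), labels = c("l1", "l2")),
    other = pairwise_matrix(matrix(1, 2, 2), labels = c("l3", "l4"))
  ))
  w <- compose_weights(h)
  expect_equal(w$weight, rep(0.25, 4))
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)
})

test_that("pairwise CSV input round-trips with fractions and a blank lower triangle", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "criterion,a,b,c",
    "a,1,3/2,2",
    "b,,1,3",
    "c,,,1"
  ), path)
  m <- read_pairwise_csv(path)
  expect_s3_class(m, "pairwise_matrix")
  expect_equal(m["b", "a"], 2 / 3)
  expect_equal(m["c", "b"], 1 / 3)
})

test_that("tidy and glance expose weights and diagnostics", {
  res <- ahp_consistency(worked_matrices()$main)
  td <- tidy(res)
  expect_named(td, c("criterion", "weight"))
  expect_equal(nrow(td), 4)
  gl <- glance(res)
  expect_named(gl, c("n", "lambda_max", "ci", "cr", "ri_used"))
  expect_equal(gl$n, 4)
})
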