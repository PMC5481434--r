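test_that("parser implements the stated grammar and precedence", {
  e <- parse_expression("CA199 AND NOT STRA")
  expect_equal(e$kind, "and")
  expect_equal(e$a$name, "CA199")
  expect_equal(e$b$kind, "not")
  expect_equal(e$b$a$name, "STRA")

  e2 <- parse_expression("NOT A AND B")
  expect_equal(e2$kind, "and")
  expect_equal(e2$a$kind, "not")
  expect_equal(e2$b$name, "B")

  # OR binds loosest; infix NOT is A AND NOT B
  e3 <- parse_expression("A OR B AND C")
  expect_equal(e3$kind, "or")
  expect_equal(e3$b$kind, "and")
  e4 <- parse_expression("A NOT B")
  expect_equal(e4$kind, "and")
  expect_equal(e4$b$kind, "not")

  expect_error(parse_expression("A AND"), "unexpected end")
  expect_error(parse_expression("(A OR B"), "parenthesis")
  expect_error(parse_expression("A ! B"), "unexpected characters")
  expect_error(parse_expression("A AND C", scan_names = c("A", "B")),
               "unknown scan")
})

test_that("evaluator follows pixel-set semantics", {
  t <- matrix(TRUE, 1, 3)
  A <- matrix(c(TRUE, TRUE, FALSE), 1)   # {p1, p2}
  B <- matrix(c(FALSE, TRUE, TRUE), 1)   # {p2, p3}
  maps <- list(A = A, B = B)
  expect_equal(evaluate_expression("A AND B", maps, t),
               matrix(c(FALSE, TRUE, FALSE), 1))
  expect_equal(evaluate_expression("A NOT B", maps, t),
               matrix(c(TRUE, FALSE, FALSE), 1))
  expect_equal(evaluate_expression("A OR B", maps, t),
               matrix(c(TRUE, TRUE, TRUE), 1))
  # NOT of an empty map is the full tissue mask
  empty <- matrix(FALSE, 1, 3)
  expect_equal(evaluate_expression("NOT E", list(E = empty), t), t)
  expect_error(evaluate_expression("A AND B",
                                   list(A = A, B = matrix(TRUE, 2, 2)), t),
               "grids")
})

test_that("evaluator agrees with the per-pixel brute-force oracle", {
  set.seed(21)
  nm <- c("A", "B", "C")
  for (i in 1:40) {
    maps <- setNames(lapply(nm, function(x)
      random_logical_matrix(12, 12)), nm)
    tissue <- random_logical_matrix(12, 12, 0.8)
    expr <- structure(random_expression(nm, 3), class = "marker_expression")
    expect_identical(evaluate_expression(expr, maps, tissue),
                     oracle_eval_pixelwise(expr, maps, tissue))
  }
})

test_that("De Morgan holds within the tissue mask", {
  set.seed(22)
  maps <- list(A = random_logical_matrix(20, 20),
               B = random_logical_matrix(20, 20))
  tissue <- random_logical_matrix(20, 20, 0.7)
  expect_identical(
    evaluate_expression("NOT (A OR B)", maps, tissue),
    evaluate_expression("(NOT A) AND (NOT B)", maps, tissue))
})

test_that("marker quantification: worked example and identity cases", {
  # 30% ca199, 20% stra, 12% overlap on 100 tissue pixels
  t <- matrix(TRUE, 10, 10)
  a <- matrix(FALSE, 10, 10); a[1:30] <- TRUE
  b <- matrix(FALSE, 10, 10); b[19:38] <- TRUE
  mq <- quantify_markers(a, b, t)
  expect_equal(unclass(mq)[c("ca199", "stra", "dual", "ca199_only",
                             "stra_only")],
               c(ca199 = 30, stra = 20, dual = 12, ca199_only = 18,
                 stra_only = 8))

  mq0 <- quantify_markers(a & FALSE, b & FALSE, t)
  expect_true(all(unclass(mq0) == 0))

  mqe <- quantify_markers(a, a, t)
  expect_equal(mqe[["ca199_only"]], 0)
  expect_equal(mqe[["stra_only"]], 0)
  expect_equal(mqe[["dual"]], mqe[["ca199"]])

  expect_error(quantify_markers(a, b, !t), "contained")
})

test_that("conservation identities are exact for random maps", {
  set.seed(23)
  for (i in 1:25) {
    tissue <- random_logical_matrix(15, 15, 0.8)
    a <- random_logical_matrix(15, 15) & tissue
    b <- random_logical_matrix(15, 15) & tissue
    mq <- quantify_markers(a, b, tissue)
    expect_identical(mq[["ca199_only"]] + mq[["dual"]], mq[["ca199"]])
    expect_identical(mq[["stra_only"]] + mq[["dual"]], mq[["stra"]])
  }
})

test_that("core aggregation averages tiles and calls categories", {
  mk <- function(ca, st, co, so, du, px = 100) {
    structure(c(ca199 = ca, stra = st, ca199_only = co, stra_only = so,
                dual = du),
              class = "marker_quant", tissue_pixels = px)
  }
  one <- aggregate_core(list(mk(5, 0.2, 4.8, 0, 0.2)), "c")
  expect_equal(unname(one$markers[["ca199"]]), 5)
  expect_equal(one$category, "ca199_only_core")

  three <- aggregate_core(list(mk(2, 2, 1, 1, 10), mk(2, 2, 1, 1, 20),
                               mk(2, 2, 1, 1, 30)), "c")
  expect_equal(unname(three$markers[["dual"]]), 20)

  # linearity: mean(only) + mean(dual) equals mean(total)
  set.seed(24)
  tiles <- lapply(1:4, function(i) {
    du <- runif(1, 0, 20); co <- runif(1, 0, 20); so <- runif(1, 0, 20)
    mk(co + du, so + du, co, so, du, sample(50:200, 1))
  })
  cq <- aggregate_core(tiles)
  expect_equal(cq$markers[["ca199_only"]] + cq$markers[["dual"]],
               cq$markers[["ca199"]])
  # tissue-weighted variant also respects the identity
  cqw <- aggregate_core(tiles, weighting = "tissue")
  expect_equal(cqw$markers[["ca199_only"]] + cqw$markers[["dual"]],
               cqw$markers[["ca199"]])

  expect_error(aggregate_core(list()), "no tiles")
})

test_that("presence call is strict at 1 percent", {
  expect_equal(call_core_category(5.0, 0.2), "ca199_only_core")
  expect_equal(call_core_category(1.0, 0.2), "neither")   # strict >
  expect_equal(call_core_category(1.0000001, 1.2), "both")
  expect_equal(call_core_category(0, 0), "neither")
  expect_equal(call_core_category(0.3, 2), "stra_only_core")
})

test_that("high-contrast planted cores reproduce their planted category", {
  cls <- list(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10), c(0, 0, 0),
              c(8, 8, 8))
  want <- c("both", "ca199_only_core", "stra_only_core", "neither", "both")
  for (i in seq_along(cls)) {
    sp <- scene_from_markers(cls[[i]][1], cls[[i]][2], cls[[i]][3],
                             mean_intensity = 300, texture_sd = 0,
                             core_diameter_um = 120, pixel_size_um = 1,
                             fov_width_um = 60, fov_height_um = 40,
                             seed = 30 + i)
    cq <- aggregate_core(quantify_core(generate_scene(sp)))
    expect_equal(cq$category, want[i], label = paste("core", i))
  }
})
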