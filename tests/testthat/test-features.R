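test_that("endpoint asymmetry H matches its truth table", {
  ep <- list(has_endpoint = TRUE)
  no <- list(has_endpoint = FALSE)
  expect_identical(endpoint_asymmetry_H(ep, no), 1)
  expect_identical(endpoint_asymmetry_H(ep, ep), 0)
  expect_identical(endpoint_asymmetry_H(no, ep), 0)
  expect_identical(endpoint_asymmetry_H(no, no), 0)
})

test_that("F substitutes directly and only H breaks its symmetry", {
  p <- fscore_params(a = 1, b = 1, c = 1)
  side <- function(r, p_, T_, ep) list(r = r, p = p_, T = T_,
                                       has_endpoint = ep)
  i <- side(2, 100, 1, FALSE)
  j <- side(1, 100, 1, FALSE)
  expect_equal(score_F(i, j, p), 1 + 0 + 0 - 2)
  same <- side(1.5, 80, 1.2, FALSE)
  expect_equal(score_F(same, same, fscore_params(a = 1, b = 1, c = 0)), 0)
  withr::with_seed(3L, {
    for (r in 1:50) {
      a <- side(runif(1, 0.5, 3), runif(1), runif(1, 1, 2),
                runif(1) > 0.5)
      b <- side(runif(1, 0.5, 3), runif(1), runif(1, 1, 2),
                runif(1) > 0.5)
      expect_equal(score_F(a, b, p) - score_F(b, a, p),
                   endpoint_asymmetry_H(a, b) - endpoint_asymmetry_H(b, a))
    }
  })
})

test_that("F* uses the printed coefficients exactly", {
  side <- function(r, p_) list(r = r, p = p_)
  expect_equal(score_Fstar(side(1.5, 0.3), side(1.5, 0.3)), 0)
  expect_equal(score_Fstar(side(2.0, 0.5), side(1.0, 0.5)), 0.19367,
               tolerance = 1e-12)
  expect_equal(score_Fstar(side(1.0, 0.6), side(1.0, 0.5)), -0.71199,
               tolerance = 1e-12)
  # scale covariance of the radius term
  base <- score_Fstar(side(2.0, 0.5), side(1.0, 0.5))
  expect_equal(score_Fstar(side(3.0, 0.5), side(1.0, 0.5)), 2 * base,
               tolerance = 1e-12)
})

test_that("tortuosity is arc over chord with the stated edge cases", {
  straight <- cbind(seq(0, 20, by = 0.5), 3, 4)
  expect_identical(tortuosity(straight), 1)
  th <- seq(0, pi, length.out = 300)
  semi <- cbind(10 + 8 * cos(th), 10 + 8 * sin(th), 5)
  expect_lt(abs(tortuosity(semi) - pi / 2) / (pi / 2), 0.05)
  expect_equal(tortuosity(semi[rev(seq_len(nrow(semi))), ]),
               tortuosity(semi))
  loop <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0))
  expect_error(tortuosity(loop), "coincident")
})

test_that("sphere-union stats recover tube radius and constant intensity", {
  v <- tube_volume(2, "x")
  mask <- v$data >= 0.5
  sk <- skeletonize3d(mask, spacing = v$spacing)
  g <- skeleton_to_graph(sk)
  path <- g$edges[[1]]$path
  st <- sphere_union_stats(path, mask, v)
  expect_gte(st$r, 1.6)   # discretization band frozen at 1 mm/0.5 mm grids
  expect_lte(st$r, 2.2)
  expect_lte(st$r, max(array(cowpipe:::.cpp_edt(as.logical(mask),
                                                as.integer(dim(mask)),
                                                v$spacing), dim(mask))))
  flat <- cow_volume(array(100, dim(mask)), v$spacing)
  expect_equal(sphere_union_stats(path, mask, flat)$p, 100)
  outside <- rbind(path, c(1, 1, 1))
  expect_error(sphere_union_stats(outside, mask, v), "outside")
})

test_that("hypoplastic-to-normal radius ratio tracks the generator factor", {
  run_side <- function(variant, seed) {
    ph <- make_phantom(phantom_config(variant = variant, seed = seed))
    res <- graph_from_volume(ph$volume)
    atlas <- default_atlas()
    bas <- label_basilar(res$bignodes, res$graph, atlas)
    m1 <- label_m1a1(res$graph, res$bignodes, atlas, exclude = bas$node)
    list(l = a1_features(res$graph, m1$left, atlas$median_sagittal_y,
                         res$seg$mask_relaxed, ph$volume),
         r = a1_features(res$graph, m1$right, atlas$median_sagittal_y,
                         res$seg$mask_relaxed, ph$volume))
  }
  hypo <- run_side("a1_hypoplasia_left", 31)
  expect_identical(hypo$l$status, "ok")
  expect_identical(hypo$r$status, "ok")
  ratio <- hypo$l$r / hypo$r$r
  expect_gte(ratio, 0.3)
  expect_lte(ratio, 0.5)
})

test_that("classify_hypoplasia applies the threshold rule", {
  expect_identical(classify_hypoplasia(-0.5, threshold = 0.08), "normal")
  expect_identical(classify_hypoplasia(0.5, threshold = 0.08), "hypoplastic")
})

test_that("fit_fstar_coefficients recovers generating coefficients", {
  withr::with_seed(21L, {
    cohort <- data.frame(dr = runif(50, 0, 3), dp = runif(50, 0, 0.1),
                         H = rbinom(50, 1, 0.3), Tsum = runif(50, 2, 3))
    # response is the linear score itself plus negligible jitter (keeps the
    # OLS standard errors well defined without moving the coefficients)
    cohort$label <- 0.19367 * cohort$dr - 7.1199 * cohort$dp +
      rnorm(50, 0, 1e-6)
  })
  fit <- fit_fstar_coefficients(cohort)
  expect_lt(abs(fit[["dr"]] - 0.19367) / 0.19367, 0.10)
  expect_lt(abs(fit[["dp"]] - (-7.1199)) / 7.1199, 0.10)
  expect_false("H" %in% names(fit))
  expect_false("Tsum" %in% names(fit))
})

test_that("degenerate cohorts are handled as specified", {
  withr::with_seed(22L, {
    cohort <- data.frame(dr = runif(20, 0, 3), dp = 0.05,
                         H = rbinom(20, 1, 0.5), Tsum = runif(20, 2, 3))
    cohort$label <- as.numeric(cohort$dr > 1.5)
  })
  fit <- fit_fstar_coefficients(cohort)
  expect_false("dp" %in% names(fit))  # zero-variance predictor dropped
  single <- transform(cohort, label = 1)
  expect_error(fit_fstar_coefficients(single), "single-class")
})
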