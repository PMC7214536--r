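test_that("a degenerate single-point grid yields one area and no assertion", {
  cen <- make_centers(30, seed = 23)
  abl <- select_ablation_region(cen, 2)
  out <- recoil_sensitivity_study(cen, abl, "gamma", grid = 0.2)
  expect_equal(nrow(out), 1L)
  expect_true(out$converged[1])
  expect_gt(out$recoil_area_um2[1], 0)
})

test_that("bisection honours its bracket contract", {
  # synthetic closure oracle with a known threshold at 2.25
  oracle <- function(Y) Y >= 2.25
  res <- closure_threshold_search(NULL, NULL, bracket = c(1.5, 3.0),
                                  resolution = 0.1, runner = oracle)
  expect_equal(res$threshold, 2.3, tolerance = 1e-9)
  # widening the bracket does not change the returned threshold
  res2 <- closure_threshold_search(NULL, NULL, bracket = c(1.5, 6.0),
                                   resolution = 0.1, runner = oracle)
  expect_equal(res2$threshold, res$threshold, tolerance = 0.1 + 1e-9)
  expect_error(
    closure_threshold_search(NULL, NULL, bracket = c(2.5, 3.0), runner = oracle),
    "lower")
  expect_error(
    closure_threshold_search(NULL, NULL, bracket = c(0.5, 1.0), runner = oracle),
    "widen")
})
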