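test_that("gravity vectors reproduce the six-pose case table", {
  expect_equal(gravity_vector("left-side-down"), c(1, 0, 0))
  expect_equal(gravity_vector("right-side-down"), c(-1, 0, 0))
  expect_equal(gravity_vector("upright"), c(0, 1, 0))
  expect_equal(gravity_vector("head-down"), c(0, -1, 0))
  expect_equal(gravity_vector("screen-up"), c(0, 0, 1))
  expect_equal(gravity_vector("screen-down"), c(0, 0, -1))
  for (pose in c("left-side-down", "right-side-down", "upright",
                 "head-down", "screen-up", "screen-down")) {
    expect_equal(sqrt(sum(gravity_vector(pose, 9.81)^2)), 9.81)
  }
  expect_error(gravity_vector("dangling"), "arg")
})

test_that("static limit: zero amplitude and noise reproduce gravity", {
  pr <- list(a = activity_profile("a", 0, 0, 1, 0, "upright"),
             b = activity_profile("b", 0, 0, 1, 0, "screen-down"))
  rec <- simulate_recording(pr, 2, data.frame(label = c("a", "b"),
                                              length = c(10, 10)), seed = 1)
  expect_true(all(rec$channels[1:10, "p1_y"] == 1))
  expect_true(all(rec$channels[1:10, "p1_x"] == 0))
  expect_true(all(rec$channels[11:20, "p2_z"] == -1))
})

test_that("simulation is deterministic per seed and validates input", {
  plan <- data.frame(label = c("a", "b"), length = c(50, 50))
  pr <- list(a = activity_profile("a", 0.5, 0.1),
             b = activity_profile("b", 0.5, 0.2))
  r1 <- simulate_recording(pr, 3, plan, scalars = 1, seed = 42)
  r2 <- simulate_recording(pr, 3, plan, scalars = 1, seed = 42)
  expect_identical(r1$channels, r2$channels)
  expect_false(identical(
    r1$channels, simulate_recording(pr, 3, plan, scalars = 1,
                                    seed = 43)$channels))
  expect_error(simulate_recording(pr, 3, plan[0, ]), "empty segment plan")
  expect_error(simulate_recording(pr[1], 3, plan), "at least two")
  expect_error(simulate_recording(pr, 3,
                                  data.frame(label = "c", length = 5)),
               "without a profile")
})

test_that("kappa = 1 with no noise makes same-axis channels coherent", {
  pr <- list(a = activity_profile("a", 0.5, 0.07, 1, 0, "screen-up"),
             b = activity_profile("b", 0.5, 0.13, 1, 0, "upright"))
  rec <- simulate_recording(pr, 3, data.frame(label = c("a", "b"),
                                              length = c(300, 300)), seed = 5)
  rep <- axis_correlation_report(rec)
  expect_true(all(rep$same_axis$abs_r > 1 - 1e-9))
  expect_equal(rep$summary["same_axis", "weak_fraction"], 0)
})

test_that("class balance counts every sample and matches the plan", {
  plan <- data.frame(label = c("a", "b", "a"), length = c(100, 100, 50))
  pr <- list(a = activity_profile("a", 0.4, 0.1),
             b = activity_profile("b", 0.4, 0.2))
  rec <- simulate_recording(pr, 2, plan, seed = 2)
  cb <- class_balance(rec)
  expect_identical(cb, c(a = 150L, b = 100L))
  expect_identical(sum(cb), length(rec))
  # the default imbalanced plan is conserved too
  plan2 <- default_segment_plan(5000, seed = 3)
  rec2 <- simulate_recording(default_profiles(), 2, plan2, seed = 3)
  cb2 <- class_balance(rec2)
  expect_identical(sum(cb2), 5000L)
  planned <- tapply(plan2$length, plan2$label, sum)
  expect_identical(as.integer(planned[names(cb2)]), unname(cb2))
})

test_that("outputs are finite and labels align with channels", {
  rec <- simulate_recording(default_profiles(), 4,
                            default_segment_plan(2000, 1), scalars = 2,
                            seed = 9)
  expect_true(all(is.finite(rec$channels)))
  expect_identical(length(rec$labels), nrow(rec$channels))
})

test_that("the noise-free task is separable by a nearest-centroid rule", {
  profiles <- default_profiles(kappa = 0.8, noise_sd = 0)
  rec <- simulate_recording(profiles, 4, default_segment_plan(6000, 2),
                            seed = 11)
  pics <- recording_to_pictures(rec, 24, 0.5)
  feats <- t(vapply(pics, function(ap) c(ap$x, ap$y, ap$z),
                    numeric(3 * 4 * 24)))
  labs <- vapply(pics, `[[`, character(1), "label")
  train <- seq_along(labs) %% 2 == 1
  centroids <- vapply(split(as.data.frame(feats[train, ]), labs[train]),
                      colMeans, numeric(ncol(feats)))
  pred <- apply(feats[!train, ], 1, function(v)
    colnames(centroids)[which.min(colSums((centroids - v)^2))])
  # windows straddling a segment boundary mix two activities; everything
  # else separates cleanly on raw windows
  expect_gt(mean(pred == labs[!train]), 0.95)
})
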