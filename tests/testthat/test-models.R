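test_that("layer and stack parameter accounting is exact", {
  expect_identical(count_layer_params(conv_layer_spec(3, 3, 1, 64)), 640L)
  expect_identical(count_layer_params(conv_layer_spec(3, 3, 64, 64)), 36928L)
  expect_identical(count_layer_params(conv_layer_spec(5, 1, 64, 64)), 20544L)
  expect_identical(count_layer_params(conv_layer_spec(1, 1, 1, 1)), 2L)
  expect_identical(count_conv_params(reference_stack(64), shared = FALSE),
                   235968L)
  expect_identical(count_conv_params(reference_stack(64), shared = TRUE),
                   78656L)
})

test_that("sharing divides conv parameters by the picture count, any spec", {
  set.seed(21)
  for (rep in 1:25) {
    stack <- lapply(seq_len(sample(1:5, 1)), function(i)
      conv_layer_spec(sample(1:5, 1), sample(1:5, 1),
                      sample(1:64, 1), sample(1:64, 1)))
    pc <- sample(2:5, 1)
    expect_identical(count_conv_params(stack, shared = FALSE,
                                       picture_count = pc),
                     as.integer(pc * count_conv_params(stack, shared = TRUE)))
  }
  # one picture: sharing is a no-op
  stack <- reference_stack(8)
  expect_identical(count_conv_params(stack, FALSE, picture_count = 1L),
                   count_conv_params(stack, TRUE))
})

test_that("har_spec variants count their stores correctly", {
  spec_t <- har_spec("T", 4, 24, letters[1:3], maps = 8)
  spec_ts <- har_spec("TS", 4, 24, letters[1:3], maps = 8)
  expect_identical(count_conv_params(spec_t),
                   3L * count_conv_params(spec_ts))
  net_t <- build_network(spec_t, 1)
  net_ts <- build_network(spec_ts, 1)
  expect_length(net_t$stores, 3)
  expect_length(net_ts$stores, 1)
  # shared store enumerates exactly the shared parameter count (+ dense)
  n_conv_params <- sum(vapply(net_ts$stores[[1]], function(k)
    length(k$weights) + length(k$biases), numeric(1)))
  expect_identical(as.integer(n_conv_params), count_conv_params(spec_ts))
  # M variants add an unshared scalar stack once
  spec_ms <- har_spec("MS", 4, 24, letters[1:3], maps = 8, scalars = 2)
  expect_identical(count_conv_params(spec_ms),
                   as.integer(count_conv_params(spec_ts) +
                                sum(vapply(scalar_stack(8),
                                           count_layer_params, numeric(1)))))
  expect_length(build_network(spec_ms, 1)$stores, 2)
})

test_that("initialization is deterministic per seed", {
  spec <- har_spec("TS", 4, 24, letters[1:4], maps = 4)
  expect_identical(network_params(build_network(spec, 99)),
                   network_params(build_network(spec, 99)))
  expect_false(identical(network_params(build_network(spec, 99)),
                         network_params(build_network(spec, 100))))
})

test_that("network forward composes the core ops and is deterministic", {
  stack <- list(conv_layer_spec(3, 3, 1, 2), conv_layer_spec(2, 3, 2, 2))
  spec <- har_spec("T", 4, 12, c("a", "b", "c"), conv_stack = stack)
  net <- build_network(spec, 5)
  set.seed(8)
  ap <- random_pictures(4, 12)
  p1 <- network_forward(net, ap)
  expect_identical(p1, network_forward(net, ap))
  expect_lt(abs(sum(p1) - 1), 1e-12)
  # manual composition with cnn_core ops
  feats <- c()
  for (bi in 1:3) {
    h <- list(ap$x, ap$y, ap$z)[[bi]]
    for (k in net$stores[[bi]]) h <- activate(conv2d_forward(h, k))
    feats <- c(feats, as.vector(h))
  }
  manual <- dense_softmax_forward(feats, net$dense$W, net$dense$b)
  expect_equal(unname(p1), manual, tolerance = 1e-14)
})

test_that("shared branches give identical maps for identical pictures", {
  spec <- har_spec("TS", 3, 12, c("a", "b"), maps = 3,
                   conv_stack = list(conv_layer_spec(2, 3, 1, 3),
                                     conv_layer_spec(2, 3, 3, 3)))
  net <- build_network(spec, 2)
  set.seed(12)
  pic <- matrix(rnorm(36), 3, 12)
  ap <- structure(list(x = pic, y = pic, z = pic, scalar = NULL,
                       label = "a"), class = "action_pictures")
  fc <- wearcnn:::forward_cache(net, ap)
  expect_identical(fc$caches[[1]]$zs, fc$caches[[2]]$zs)
  expect_identical(fc$caches[[2]]$zs, fc$caches[[3]]$zs)
})

test_that("analytic gradients match finite differences, incl. shared sum", {
  res <- gradient_check_suite(6, seed = 17)
  expect_true(all(res$max_rel_err < 1e-5))
  expect_setequal(unique(res$variant), c("T", "TS"))
  # scalar-branch (MS) gradients verified the same way
  spec <- har_spec("MS", 3, 10, c("a", "b", "c"), maps = 2, scalars = 2,
                   conv_stack = list(conv_layer_spec(2, 3, 1, 2),
                                     conv_layer_spec(2, 3, 2, 2)),
                   scalar_conv_stack = list(
                     conv_layer_spec(1, 3, 1, 2, conv_dim = "1d"),
                     conv_layer_spec(1, 3, 2, 2, conv_dim = "1d")))
  net <- build_network(spec, 31)
  set.seed(31)
  ap <- random_pictures(3, 10, S = 2)
  chk <- gradient_check(net, ap, 2L)
  expect_lt(chk$max_rel_err, 1e-5)
})

test_that("training updates behave: null update, descent, shared identity", {
  stack <- list(conv_layer_spec(2, 3, 1, 2), conv_layer_spec(2, 3, 2, 2))
  spec <- har_spec("TS", 3, 12, c("a", "b"), conv_stack = stack)
  net <- build_network(spec, 3)
  set.seed(19)
  pics <- lapply(1:6, function(i) random_pictures(3, 12,
                                                  label = c("a", "b")[1 + i %% 2]))
  # lr = 0: parameters unchanged, threshold stops after one epoch
  frozen <- train_network(net, pics,
                          training_config(learning_rate = 0, epochs = 10,
                                          threshold = 1e-9, seed = 1))
  expect_identical(network_params(frozen), network_params(net))
  expect_length(frozen$history, 1)
  # single sample, small lr: loss non-increasing over 10 epochs
  one <- train_network(net, pics[1],
                       training_config(learning_rate = 0.005, epochs = 10,
                                       batch_size = 1, seed = 1))
  expect_true(all(diff(one$history) <= 1e-12))
  # shared store remains one object: all branches see updated weights
  trained <- train_network(net, pics,
                           training_config(epochs = 2, seed = 1))
  expect_length(trained$stores, 1)
  expect_false(identical(network_params(trained), network_params(net)))
  # unknown labels are rejected
  bad <- pics[1]; bad[[1]]$label <- "zz"
  expect_error(train_network(net, bad, training_config(epochs = 1)), "zz")
})

test_that("checkpoints reload to bit-identical forward outputs", {
  spec <- har_spec("TS", 3, 12, c("a", "b"), maps = 2,
                   conv_stack = list(conv_layer_spec(2, 3, 1, 2),
                                     conv_layer_spec(2, 3, 2, 2)))
  net <- build_network(spec, 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_network(net, path)
  net2 <- load_network(path)
  set.seed(23)
  ap <- random_pictures(3, 12)
  expect_identical(network_forward(net, ap), network_forward(net2, ap))
})
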