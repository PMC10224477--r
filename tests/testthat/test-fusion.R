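# Head rules, min-max normalization, (weighted) fusion and thresholds.

test_that("avg-sigmoid head rule averages per-head sigmoids", {
  # n = 1, zero logits: sigma(0) = 1/2 everywhere
  p <- aggregate_avg_sigmoid(mask_stack(matrix(0, 3, 3)))
  expect_equal(unclass(p)[, ], matrix(0.5, 3, 3))
  # symmetric heads cancel to 1/2
  st <- mask_stack(list(matrix(6.9, 1, 1), matrix(-6.9, 1, 1)))
  expect_equal(as.numeric(aggregate_avg_sigmoid(st)), 0.5)
  # scalar logistic oracle at double precision
  st <- mask_stack(list(matrix(2, 1, 1), matrix(4, 1, 1)))
  oracle <- (1 / (1 + exp(-2)) + 1 / (1 + exp(-4))) / 2
  expect_equal(as.numeric(aggregate_avg_sigmoid(st)), oracle)
})

test_that("sum-sigmoid head rule sigmoids the summed logits", {
  st <- mask_stack(list(matrix(2, 1, 1), matrix(4, 1, 1)))
  expect_equal(as.numeric(aggregate_sum_sigmoid(st)), 1 / (1 + exp(-6)))
  # +a / -a cancellation
  for (a in c(0.1, 6.9, 123)) {
    st <- mask_stack(list(matrix(a, 2, 2), matrix(-a, 2, 2)))
    expect_equal(unclass(aggregate_sum_sigmoid(st))[, ], matrix(0.5, 2, 2))
  }
})

test_that("head rules coincide exactly at n = 1", {
  set.seed(42)
  for (i in 1:10) {
    st <- mask_stack(matrix(rnorm(48, sd = 30), 6, 8))
    expect_identical(unclass(aggregate_avg_sigmoid(st))[, ],
                     unclass(aggregate_sum_sigmoid(st))[, ])
  }
})

test_that("sum rule saturates at least as hard as averaging (Jensen)", {
  # on sign-coherent stacks, |sum_sigmoid - 0.5| >= |avg_sigmoid - 0.5|
  set.seed(7)
  for (i in 1:25) {
    n <- sample(2:4, 1)
    signs <- matrix(sample(c(-1, 1), 30, replace = TRUE), 5, 6)
    heads <- lapply(seq_len(n), function(j) {
      signs * matrix(runif(30, 0.1, 40), 5, 6)
    })
    st <- mask_stack(heads)
    a <- abs(unclass(aggregate_avg_sigmoid(st)) - 0.5)
    s <- abs(unclass(aggregate_sum_sigmoid(st)) - 0.5)
    expect_true(all(s >= a - 1e-12))
  }
})

test_that("min-max normalization spans [0,1] and rejects constant masks", {
  p <- prob_mask(matrix(c(0.2, 0.8), 1, 2))
  expect_equal(as.vector(unclass(minmax_normalize(p))), c(0, 1))
  # idempotent on an already-spanning mask
  q <- prob_mask(matrix(c(0, 0.25, 1, 0.5), 2, 2))
  expect_equal(unclass(minmax_normalize(q))[, ], unclass(q)[, ])
  # the objectless pathology surfaces as an error
  expect_error(minmax_normalize(prob_mask(matrix(0.4, 3, 3))), "constant")
})

test_that("normalization forces a spurious foreground on objectless frames", {
  # an all-background logit mask + faint noise: after sum-sigmoid +
  # min-max the mask attains 0 and 1 exactly and thresholding "finds" an
  # object that is not there; the avg-sigmoid pipeline does not
  set.seed(5)
  logits <- matrix(-40 + rnorm(64, sd = 0.5), 8, 8)
  st <- mask_stack(logits)
  norm <- minmax_normalize(aggregate_sum_sigmoid(st))
  expect_equal(min(norm), 0)
  expect_equal(max(norm), 1)
  expect_gt(sum(binarize(norm, 0.5)), 0)          # spurious foreground
  expect_equal(sum(binarize(aggregate_avg_sigmoid(st), 0.5)), 0)
})

test_that("fuse computes the normalized weighted pixelwise mean", {
  a <- prob_mask(matrix(0.2, 1, 1))
  b <- prob_mask(matrix(0.4, 1, 1))
  c3 <- prob_mask(matrix(0.8, 1, 1))
  # sum rule = arithmetic mean
  expect_equal(as.numeric(fuse(list(a, b))), 0.3)
  # degenerate weight returns the first mask
  expect_equal(as.numeric(fuse(list(a, b), c(1, 0))), 0.2)
  # hand-computed weighted mean (0.2 + 0.4 + 1.6) / 4
  expect_equal(as.numeric(fuse(list(a, b, c3), c(1, 1, 2))), 0.55)
  # guards
  expect_error(fuse(list()), "non-empty")
  expect_error(fuse(list(a, prob_mask(matrix(0.1, 2, 2)))), "shape")
  expect_error(fuse(list(a, b), c(0, 0)), "zero")
})

test_that("fusion is invariant to rescaling all weights", {
  set.seed(9)
  masks <- lapply(1:4, function(i) prob_mask(matrix(runif(20), 4, 5)))
  w <- runif(4, 0.1, 3)
  base <- unclass(fuse(masks, w))
  for (cc in c(0.01, 1, 7, 1000)) {
    expect_equal(unclass(fuse(masks, cc * w))[, ], base[, ])
  }
})

test_that("equal_method_weights gives every method the same total", {
  expect_equal(equal_method_weights(1), 1.0)
  expect_equal(equal_method_weights(c(4, 4)), rep(0.125, 8))
  w <- equal_method_weights(c(8, 4, 4))
  expect_equal(w, c(rep(1 / 24, 8), rep(1 / 12, 4), rep(1 / 12, 4)))
  expect_equal(sum(w), 1)
  # per-method totals equal to machine precision, random sizes
  set.seed(13)
  for (i in 1:20) {
    sizes <- sample(1:9, sample(2:5, 1), replace = TRUE)
    w <- equal_method_weights(sizes)
    expect_equal(sum(w), 1)
    totals <- vapply(split(w, rep(seq_along(sizes), sizes)), sum,
                     numeric(1))
    expect_equal(max(totals) - min(totals), 0, tolerance = 1e-15)
  }
  expect_error(equal_method_weights(integer(0)), "at least one")
})

test_that("run_ensemble reproduces a brute-force weighted mean", {
  set.seed(21)
  truth <- blob_mask()
  # one member: identical to the head rule applied directly
  st <- gen_head_stack(truth, head_model_config(n_heads = 2, seed = 1))
  spec1 <- ensemble_spec(list(list(stacks = list(img = st))),
                         head_rule = "avg_sigmoid")
  expect_equal(unclass(run_ensemble(spec1, "img"))[, ],
               unclass(aggregate_avg_sigmoid(st))[, ])

  # two identical members under the sum rule: idempotent
  spec2 <- ensemble_spec(list(list(stacks = list(img = st)),
                              list(stacks = list(img = st))))
  expect_equal(unclass(run_ensemble(spec2, "img"))[, ],
               unclass(aggregate_avg_sigmoid(st))[, ])

  # Ens1-shaped: 4 + 4 members, equal per-method totals, weighted sum
  stacks <- lapply(1:8, function(i) {
    gen_head_stack(truth, head_model_config(
      n_heads = if (i <= 4) 2L else 4L, logit_gain = 10 + 3 * i,
      boundary_softness = 2 + i / 2, noise_sd = 1, seed = 100 + i))
  })
  w <- equal_method_weights(c(4, 4))
  members <- lapply(seq_len(8), function(i) {
    list(stacks = list(img = stacks[[i]]), weight = w[i])
  })
  spec <- ensemble_spec(members, fusion_rule = "weighted_sum",
                        head_rule = "avg_sigmoid")
  got <- unclass(run_ensemble(spec, "img"))
  # independent brute force: explicit per-pixel loops over members/heads
  brute <- matrix(0, nrow(truth), ncol(truth))
  for (i in seq_len(8)) {
    acc <- matrix(0, nrow(truth), ncol(truth))
    for (h in seq_len(n_heads(stacks[[i]]))) {
      acc <- acc + 1 / (1 + exp(-unclass(stacks[[i]][[h]])))
    }
    brute <- brute + w[i] * acc / n_heads(stacks[[i]])
  }
  expect_equal(got[, ], brute[, ] / sum(w))
  expect_error(run_ensemble(spec, "missing_image"), "no stack")
})

test_that("binarize uses strict > with a threshold inside (0,1)", {
  p <- prob_mask(matrix(0.5, 2, 2))
  expect_equal(sum(binarize(p, 0.5)), 0)          # tie goes to background
  p2 <- prob_mask(matrix(c(0.49, 0.51), 1, 2))
  expect_equal(as.vector(unclass(binarize(p2, 0.5))), c(0, 1))
  # sigma(positive) > 0.5 everywhere
  st <- mask_stack(list(matrix(runif(16, 0.5, 90), 4, 4),
                        matrix(runif(16, 0.5, 90), 4, 4)))
  expect_equal(sum(binarize(aggregate_avg_sigmoid(st), 0.5)), 16)
  expect_error(binarize(p, 0), "threshold")
  expect_error(binarize(p, 1), "threshold")
})
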