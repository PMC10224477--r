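# Resize protocol, mask restoration, directory evaluation, CLI wiring.

test_that("resize_for_inference always yields 352 x 352", {
  out <- resize_for_inference(make_rgb(100, 180))
  expect_identical(dim(out), c(352L, 352L, 3L))
  outg <- resize_for_inference(matrix(runif(64), 8, 8))
  expect_identical(dim(outg), c(352L, 352L))
  # constant invariance
  const <- resize_for_inference(matrix(0.37, 704, 704))
  expect_equal(const, matrix(0.37, 352, 352), tolerance = 1e-12)
  expect_error(resize_for_inference(numeric(0)), "empty")
})

test_that("restore_mask is the identity at the original size", {
  p <- prob_mask(matrix(runif(352 * 352), 352, 352))
  expect_identical(unclass(restore_mask(p, c(352, 352)))[, ],
                   unclass(p)[, ])
  # constant masks restore to the constant at any size
  pc <- prob_mask(matrix(0.6, 352, 352))
  r <- restore_mask(pc, c(123, 77))
  expect_equal(unclass(r)[, ], matrix(0.6, 123, 77), tolerance = 1e-12)
  expect_error(restore_mask(pc, c(0, 10)), "original_size")
})

test_that("the 500x600 -> 352x352 -> 500x600 round trip tracks a smooth field", {
  # analytic test function, evaluated densely at both resolutions
  f <- function(h, w) {
    r <- matrix(seq(0, 1, length.out = h), h, w)
    c <- matrix(seq(0, 1, length.out = w), h, w, byrow = TRUE)
    0.5 + 0.45 * sin(2 * pi * r) * cos(2 * pi * c)
  }
  dense <- prob_mask(f(500, 600))
  down <- restore_mask(dense, c(352, 352))
  up <- restore_mask(down, c(500, 600))
  # bilinear interpolation error for a C^2 field ~ (grid step)^2 * |f''|;
  # bound it well above that but far below the field's 0.9 dynamic range
  expect_lt(max(abs(unclass(up) - f(500, 600))), 0.02)
})

test_that("evaluate pairs files, restores sizes and averages Dice/IoU", {
  root <- tempfile("eval")
  pred <- file.path(root, "pred"); gt <- file.path(root, "gt")
  dir.create(pred, recursive = TRUE); dir.create(gt, recursive = TRUE)

  # image 1: perfect prediction at native size
  t1 <- blob_mask(40, 40, 10)
  write_mask_png(t1, file.path(gt, "im1.png"))
  write_mask_png(t1, file.path(pred, "im1.png"))
  # image 2: disjoint prediction -> dice 0
  t2 <- matrix(0, 40, 40); t2[1:10, 1:10] <- 1
  p2 <- matrix(0, 40, 40); p2[30:40, 30:40] <- 1
  write_mask_png(binary_mask(t2), file.path(gt, "im2.png"))
  write_mask_png(binary_mask(p2), file.path(pred, "im2.png"))

  res <- evaluate(pred, gt)
  expect_s3_class(res, "eval_result")
  expect_equal(res$per_image$dice, c(1, 0))
  expect_equal(res$mean_dice, 0.5)
  expect_equal(res$mean_iou, 0.5)
  expect_identical(res$per_image$image_id, c("im1", "im2"))

  # a prediction stored at inference size is restored before scoring
  p1_small <- restore_mask(prob_mask(unclass(t1) * 1), c(352, 352))
  write_mask_png(p1_small, file.path(pred, "im1.png"))
  res2 <- evaluate(pred, gt)
  expect_gt(res2$per_image$dice[1], 0.95)

  # guards: unpaired files and empty directories
  file.remove(file.path(pred, "im2.png"))
  expect_error(evaluate(pred, gt), "unpaired")
  empty <- file.path(root, "empty"); dir.create(empty)
  expect_error(evaluate(empty, empty), "no PNG")
})

test_that("the full offline chain reaches Dice > 0.9 at zero noise", {
  # synth -> heads -> avg-sigmoid ensemble -> restore -> evaluate
  root <- tempfile("e2e")
  pred <- file.path(root, "pred"); gt <- file.path(root, "gt")
  dir.create(pred, recursive = TRUE); dir.create(gt, recursive = TRUE)
  for (i in 1:4) {
    sc <- gen_scene(scene_config(120, 150, n_objects = 1,
                                 object_scale = 0.3, seed = i))
    members <- lapply(1:3, function(j) {
      st <- gen_head_stack(sc$truth, head_model_config(
        n_heads = 2, logit_gain = c(30, 60) + 5 * j,
        boundary_softness = c(2, 4), noise_sd = 0, seed = 10 * i + j))
      list(stacks = stats::setNames(list(st), sprintf("im%d", i)))
    })
    spec <- ensemble_spec(members, head_rule = "avg_sigmoid")
    fused <- run_ensemble(spec, sprintf("im%d", i))
    # emulate the inference protocol: predict at 352x352, restore to
    # native size, then score at the ground truth's resolution
    at_352 <- restore_mask(fused, c(352, 352))
    restored <- restore_mask(at_352, dim(sc$truth)[1:2])
    write_mask_png(restored, file.path(pred, sprintf("im%d.png", i)))
    write_mask_png(sc$truth, file.path(gt, sprintf("im%d.png", i)))
  }
  res <- evaluate(pred, gt)
  expect_gt(res$mean_dice, 0.9)
})

test_that("the CLI subcommands run end to end on synthetic data", {
  root <- tempfile("cli")
  dir.create(root, recursive = TRUE)
  synth_dir <- file.path(root, "synth")
  # synth
  expect_equal(segfuse_main(c("synth", "--out", synth_dir,
                              "--seed", "3")), 0L)
  expect_length(list.files(file.path(synth_dir, "stacks")), 4)
  # saturation
  rep_csv <- file.path(root, "report.csv")
  expect_equal(segfuse_main(c("saturation", "--stacks",
                              file.path(synth_dir, "stacks"),
                              "--out", rep_csv)), 0L)
  expect_true(file.exists(rep_csv))
  rep <- read.csv(rep_csv)
  expect_true(all(c("min_max", "avg_max", "avg_min", "max_min",
                    "sat_avg_rate", "sat_sum_rate") %in% names(rep)))
  # fuse with a YAML spec over the written stacks
  spec_path <- file.path(root, "spec.yaml")
  writeLines(c(
    "head_rule: avg_sigmoid",
    "fusion_rule: sum",
    "members:",
    sprintf("  - {family: synthetic, path: %s}",
            file.path(synth_dir, "stacks"))), spec_path)
  fused_dir <- file.path(root, "fused")
  expect_equal(segfuse_main(c("fuse", "--spec", spec_path,
                              "--out", fused_dir)), 0L)
  bins <- list.files(fused_dir, pattern = "_bin\\.png$")
  expect_length(bins, 4)
  # eval: rename fused binaries to match the ground-truth names
  pred_dir <- file.path(root, "pred")
  dir.create(pred_dir)
  for (b in bins) {
    file.copy(file.path(fused_dir, b),
              file.path(pred_dir, sub("_bin", "", b)))
  }
  metrics_csv <- file.path(root, "metrics.csv")
  expect_equal(segfuse_main(c("eval", "--pred", pred_dir,
                              "--gt", file.path(synth_dir, "masks"),
                              "--out", metrics_csv)), 0L)
  m <- read.csv(metrics_csv)
  expect_gt(m$dice[m$image_id == "__mean__"], 0.9)
  # augment
  expect_equal(segfuse_main(c("augment",
                              "--images", file.path(synth_dir, "images"),
                              "--masks", file.path(synth_dir, "masks"),
                              "--strategy", "da1",
                              "--out", file.path(root, "aug"))), 0L)
  man <- read.csv(file.path(root, "aug", "manifest.csv"))
  expect_equal(nrow(man), 4 * 4)
  # a bad invocation exits nonzero instead of raising
  expect_equal(segfuse_main(c("fuse", "--out", "nowhere")), 1L)
})
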