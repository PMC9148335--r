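tiny_dataset <- function(seeds) lapply(seeds, desk_phantom)

test_that("pre-training splits subjects deterministically with a floor rule", {
  dat <- tiny_dataset(1:10)
  cfg <- desk_net_config()
  tc <- train_config(epochs = 2, seed = 5, slices_per_subject = 4)
  m1 <- pretrain(dat, cfg, tc)
  expect_length(m1$split$train, 8)          # floor(10 * 0.8)
  expect_length(m1$split$validation, 2)
  m2 <- pretrain(dat, cfg, tc)
  expect_identical(m1$split, m2$split)
  expect_identical(m1$nets$axial$params, m2$nets$axial$params)
  # training reduces the validation loss on easy phantoms
  h <- m1$history$axial
  expect_lte(h$val_loss[nrow(h)], h$val_loss[1])
  expect_error(pretrain(list(dat[[1]]), cfg, tc), "at least 2")
})

test_that("subjects without labels are rejected", {
  dat <- tiny_dataset(1:2)
  dat[[2]]$labels <- NULL
  expect_error(pretrain(dat, desk_net_config(),
                        train_config(epochs = 1)), "missing labels")
})

test_that("the frozen phase leaves non-unfrozen parameters exactly unchanged", {
  dat <- tiny_dataset(1:3)
  init <- desk_pretrained()
  sch <- finetune_schedule(frozen_epochs = 1, full_epochs = 0)
  m <- finetune(init, dat, sch, seed = 2, slices_per_subject = 3)
  for (view in c("axial", "coronal", "sagittal")) {
    p0 <- init$nets[[view]]$params
    p1 <- m$nets[[view]]$params
    frozen_groups <- setdiff(names(p0), c("classifier", "dec1"))
    for (g in frozen_groups)
      expect_identical(p1[[g]], p0[[g]])
    expect_false(identical(p1$classifier, p0$classifier))
    expect_false(identical(p1$dec1, p0$dec1))
  }
  expect_true(all(m$history$axial$phase == "frozen"))
})

test_that("a schedule with no frozen phase is plain full-network training", {
  dat <- tiny_dataset(1:3)
  init <- desk_pretrained()
  m <- finetune(init, dat, finetune_schedule(frozen_epochs = 0,
                                             full_epochs = 2),
                seed = 3, slices_per_subject = 3)
  expect_true(all(m$history$axial$phase == "full"))
  expect_identical(nrow(m$history$axial), 2L)
  # ablation arm folds the frozen budget into full training
  m0 <- finetune(NULL, dat, finetune_schedule(frozen_epochs = 1,
                                              full_epochs = 1),
                 net_config = desk_net_config(), seed = 3,
                 slices_per_subject = 3)
  expect_identical(nrow(m0$history$axial), 2L)
  expect_true(all(m0$history$axial$phase == "full"))
})

test_that("training loss trends downward over the schedule", {
  dat <- tiny_dataset(1:4)
  m <- finetune(NULL, dat, finetune_schedule(frozen_epochs = 0,
                                             full_epochs = 6, lr = 1e-3),
                net_config = desk_net_config(), seed = 8,
                slices_per_subject = 6)
  tr <- m$history$coronal$train_loss
  expect_lt(tr[length(tr)], tr[1])
})

test_that("identical seeds give identical fine-tuned weights", {
  dat <- tiny_dataset(1:3)
  sch <- finetune_schedule(frozen_epochs = 0, full_epochs = 2)
  m1 <- finetune(NULL, dat, sch, net_config = desk_net_config(), seed = 4,
                 slices_per_subject = 4)
  m2 <- finetune(NULL, dat, sch, net_config = desk_net_config(), seed = 4,
                 slices_per_subject = 4)
  expect_equal(m1$nets$sagittal$params, m2$nets$sagittal$params,
               tolerance = 1e-12)
})

test_that("LOOCV never leaks the held-out subject and records every fold", {
  dat <- tiny_dataset(1:4)
  cv <- loocv(dat, init = NULL,
              schedule = finetune_schedule(frozen_epochs = 0,
                                           full_epochs = 1),
              seed = 6, net_config = desk_net_config(),
              slices_per_subject = 3)
  expect_length(cv$folds, 4)
  for (f in cv$folds) {
    expect_length(f$train_ids, 3)
    expect_false(f$held_out %in% f$train_ids)
    expect_s3_class(f$prediction, "idseg_labels")
  }
  expect_error(loocv(dat[1:2], schedule = finetune_schedule()), "at least 3")
})
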