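test_that("backpropagation matches numerical gradients", {
  ko <- asNamespace("korosound")
  par <- ko$.cnn_init(c(8L, 8L, 3L), c(2L, 3L, 4L), hidden = 5L, seed = 3)
  set.seed(1)
  img <- array(runif(8 * 8 * 3, -0.5, 0.5), c(8, 8, 3))
  y <- 1L
  lossfn <- function(p) {
    pr <- ko$.softmax(ko$.cnn_forward(p, img)$logits)
    -log(pr[y + 1])
  }
  fw <- ko$.cnn_forward(par, img, keep_cache = TRUE)
  pr <- ko$.softmax(fw$logits)
  dl <- pr; dl[y + 1] <- dl[y + 1] - 1
  g <- ko$.cnn_backward(par, fw$cache, dl)
  for (nm in c("W1", "b1", "W2", "W3", "F1", "f1", "F2", "f2")) {
    idx <- sample(length(par[[nm]]), min(4, length(par[[nm]])))
    num <- vapply(idx, function(j) {
      p2 <- par
      p2[[nm]][j] <- p2[[nm]][j] + 1e-5; l1 <- lossfn(p2)
      p2[[nm]][j] <- p2[[nm]][j] - 2e-5; l0 <- lossfn(p2)
      (l1 - l0) / 2e-5
    }, 0)
    expect_lt(max(abs(num - g[[nm]][idx]) / pmax(abs(num), 1e-6)), 1e-4)
  }
})

test_that("dataset building splits by subject, stratified, reproducibly", {
  tc <- tone_class_recordings(12)
  # give two recordings to one subject: both must land in the same split
  tc$recordings[[2]]$subject_id <- tc$recordings[[1]]$subject_id
  ds1 <- build_dataset(tc$recordings, tc$labels, split = c(0.6, 0.2, 0.2),
                       seed = 5, size = 16L, whole_record = TRUE)
  ds2 <- build_dataset(tc$recordings, tc$labels, split = c(0.6, 0.2, 0.2),
                       seed = 5, size = 16L, whole_record = TRUE)
  expect_identical(ds1$split, ds2$split)
  expect_identical(ds1$images, ds2$images)
  expect_identical(ds1$split[1], ds1$split[2])

  # zero subject leakage across splits
  tab <- table(ds1$subject_ids, ds1$split)
  expect_true(all(rowSums(tab > 0) == 1L))

  # per-split class ratio within one subject of the global ratio
  for (sp in unique(ds1$split)) {
    sel <- ds1$split == sp
    n1 <- length(unique(ds1$subject_ids[sel & ds1$labels == 1]))
    n0 <- length(unique(ds1$subject_ids[sel & ds1$labels == 0]))
    expect_lte(abs(n1 - n0), 1L)
  }
  expect_error(build_dataset(tc$recordings, tc$labels[-1]), "one label")
  expect_error(build_dataset(tc$recordings, tc$labels,
                             split = c(0.9, 0.2, 0.2), whole_record = TRUE),
               "sum to 1")
  expect_error(build_dataset(tc$recordings[1:12],
                             rep(c(0, 1), c(11, 1)), whole_record = TRUE),
               ">= 10 recordings")
})

test_that("confusion metrics reproduce the stated arithmetic", {
  perfect <- confusion_metrics(10, 0, 0, 12)
  expect_identical(perfect$sensitivity, 1)
  expect_identical(perfect$specificity, 1)
  expect_identical(perfect$precision_pos, 1)
  expect_identical(perfect$accuracy, 1)

  m <- confusion_metrics(21, 4, 2, 23)
  expect_equal(m$sensitivity, 0.84, tolerance = 1e-12)
  expect_equal(m$specificity, 0.92, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.88, tolerance = 1e-12)

  # round trip: identities always hold when recomputed from the counts
  set.seed(8)
  for (i in 1:20) {
    cts <- rmultinom(1, 50, c(0.3, 0.2, 0.1, 0.4))
    mm <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(mm$accuracy, (mm$tp + mm$tn) / sum(cts), tolerance = 1e-12)
    if (!is.na(mm$sensitivity))
      expect_equal(mm$sensitivity, mm$tp / (mm$tp + mm$fn), tolerance = 1e-12)
  }
})

test_that("an all-positive predictor scores chance on a balanced set", {
  ko <- asNamespace("korosound")
  par <- ko$.cnn_init(c(8L, 8L, 3L), c(2L, 2L, 2L), hidden = 4L, seed = 1)
  for (nm in c("W1", "W2", "W3", "F1", "F2")) par[[nm]][] <- 0
  par$f2 <- c(-5, 5)    # logits always favour class 1
  imgs <- lapply(1:10, function(i) array(runif(8 * 8 * 3) * 255, c(8, 8, 3)))
  ev <- evaluate_classifier(list(par = par), list(images = imgs,
                                                  labels = rep(0:1, 5)))
  expect_identical(ev$sensitivity, 1)
  expect_identical(ev$specificity, 0)
  expect_identical(ev$accuracy, 0.5)
})

test_that("training is reproducible and learns a linearly separable toy", {
  set.seed(20)
  mk_img <- function(cls) {
    base <- array(runif(16 * 16 * 3) * 40, c(16, 16, 3))
    if (cls == 1) base[4:8, 4:8, 1] <- 220 else base[10:14, 10:14, 2] <- 220
    base
  }
  imgs <- lapply(rep(0:1, each = 10), mk_img)
  labs <- rep(0:1, each = 10)
  tr <- list(images = imgs[c(1:7, 11:17)], labels = labs[c(1:7, 11:17)])
  va <- list(images = imgs[c(8:10, 18:20)], labels = labs[c(8:10, 18:20)])
  hy <- list(epochs = 10, lr = 5e-3, channels = c(4L, 6L, 8L))
  m1 <- train_compact_cnn(tr, va, hyper = hy, seed = 2)
  m2 <- train_compact_cnn(tr, va, hyper = hy, seed = 2)
  expect_identical(m1$history, m2$history)
  expect_gte(tail(m1$history$train_acc, 1), 0.9)
  expect_identical(nrow(m1$history), 10L)
  expect_error(train_compact_cnn(list(images = imgs[1:5],
                                      labels = rep(0, 5)), NULL),
               "single-class")
})
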