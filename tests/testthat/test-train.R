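test_that("cross-entropy matches analytic and hand-computed values", {
  expect_equal(crossEntropy(c(0, 0), 0L), log(2))
  expect_lt(crossEntropy(c(50, 0), 0L), 1e-9)
  set.seed(1)
  L <- matrix(rnorm(9), 3, 3)
  labs <- c(2L, 0L, 1L)
  by_hand <- -mean(sapply(1:3, function(n) {
    p <- exp(L[n, ]) / sum(exp(L[n, ]))
    log(p[labs[n] + 1])
  }))
  expect_equal(crossEntropy(L, labs), by_hand, tolerance = 1e-12)
  expect_error(crossEntropy(L, c(0L, 3L, 1L)), "out of range")
})

test_that("subject-level splits are exhaustive, disjoint and seeded", {
  labels <- data.frame(
    subject_id = sprintf("s%03d", 1:174),
    class_label = c(rep(0, 48), rep(1, 50), rep(2, 45), rep(3, 31)))
  sp <- makeSubjectSplit(labels, seed = 1)
  all_ids <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_ids, labels$subject_id)
  expect_identical(anyDuplicated(all_ids), 0L)
  expect_silent(assertSplitLeakFree(sp))
  # per-class totals preserved
  for (cl in 0:3) {
    ids <- labels$subject_id[labels$class_label == cl]
    n <- c(48, 50, 45, 31)[cl + 1]
    expect_identical(sum(all_ids %in% ids), as.integer(n))
    # every class in every partition
    for (p in sp) expect_gt(sum(p %in% ids), 0)
  }
  expect_identical(makeSubjectSplit(labels, seed = 1), sp)
  expect_false(identical(makeSubjectSplit(labels, seed = 2), sp))
  expect_error(assertSplitLeakFree(list(train = c("a", "b"), val = "a",
                                        test = "c")), "span partitions")
})

test_that("subject aggregation averages probabilities with first-wins ties", {
  expect_equal(aggregateSubject(list(c(0.2, 0.8)))$probs, c(0.2, 0.8))
  ag <- aggregateSubject(list(c(0.8, 0.2), c(0.4, 0.6)))
  expect_equal(ag$probs, c(0.6, 0.4))
  expect_identical(ag$label, 0L)
  expect_identical(aggregateSubject(list(c(0.5, 0.5)))$label, 0L)
  expect_error(aggregateSubject(list()), "no sessions")
})

test_that("classification metrics follow confusion-matrix arithmetic", {
  m <- classificationMetrics(truth = c(1L, 0L, 0L), pred = c(1L, 1L, 0L),
                             n_classes = 2L)
  expect_equal(m$accuracy, 100 * 2 / 3)
  # class 1: precision 1/2, recall 1; class 0: precision 1, recall 1/2
  expect_equal(m$precision, 100 * (1 + 0.5) / 2)
  expect_equal(m$recall, 100 * (0.5 + 1) / 2)
  expect_identical(m$confusion[1, 2], 1L)

  perfect <- classificationMetrics(c(0L, 1L, 1L), c(0L, 1L, 1L),
                                   probs = rbind(c(0.9, 0.1), c(0.2, 0.8),
                                                 c(0.1, 0.9)))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 100)
  expect_equal(perfect$auc, 100)

  expect_warning(
    one <- classificationMetrics(c(0L, 0L, 1L, 1L), rep(1L, 4),
                                 n_classes = 2L),
    "never predicted")
  expect_equal(one$accuracy, 50)
})

test_that("the rank-statistic AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(3)
  truth <- rep(c(0L, 1L), each = 20)
  scores <- runif(40) + 0.3 * truth
  probs <- cbind(1 - scores, scores)
  m <- classificationMetrics(truth, as.integer(scores > 0.5), probs)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
  expect_equal(m$auc, 100 * ref, tolerance = 1e-9)
})

test_that("paired comparison matches the textbook t formula with guards", {
  d <- c(2, -1, 3, 0, 1)
  x <- 80 + d; y <- rep(80, 5)
  pc <- pairedComparison(x, y)
  tref <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(pc$t, tref, tolerance = 1e-12)
  expect_equal(pc$p, 2 * pt(-abs(tref), df = 4), tolerance = 1e-12)

  same <- pairedComparison(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_match(same$flag, "identical")

  const <- pairedComparison(c(2, 3, 4), c(1, 2, 3))
  expect_identical(const$t, Inf)
  expect_match(const$flag, "constant")
  expect_error(pairedComparison(1:3, 1:4), "different lengths")
})

test_that("VAE pre-training recovers most of the learnable reconstruction", {
  cfg <- deskPreset("desk2", seed = 3)
  cfg$subjects_per_class <- c(10L, 10L)
  cohort <- generateCohort(cfg)
  dfcs <- lapply(cohort$sessions, buildDFC, cfg = dfcConfig(30, 2, TRUE))
  W <- do.call(rbind, lapply(dfcs, dfcVectors))
  tr <- W[1:(nrow(W) - 54), ]; va <- W[(nrow(W) - 53):nrow(W), ]
  vae <- vaeInit(c(190, 32), 8, kl_weight = 0.003, seed = 1)
  init_recon <- vaeLoss(vae, va)$recon
  p1 <- pretrainVAE(vae, tr, va, epochs = 8, batch_size = 32, seed = 1)
  final_recon <- vaeLoss(p1$vae, va)$recon
  # the best constant predictor (training feature means) bounds what any
  # input-independent decoder can achieve; training must close at least
  # half the gap from the untrained loss to that baseline, and beat it
  const_recon <- mean(rowSums((va - rep(colMeans(tr), each = nrow(va)))^2))
  expect_lt(final_recon, const_recon)
  expect_lt(final_recon - const_recon, 0.5 * (init_recon - const_recon))
  expect_lt(final_recon, init_recon)
  # reproducibility: same seed, same trajectory
  p2 <- pretrainVAE(vae, tr, va, epochs = 8, batch_size = 32, seed = 1)
  expect_identical(p1$history$train_loss, p2$history$train_loss)
  expect_error(pretrainVAE(vae, tr[0, ], va), "empty")
})

test_that("joint fine-tuning freezes the VAE bit-exactly through warmup", {
  cfg <- tinyConfig()
  dfcs <- tinyDFCs(8, K = 7, D = 10)
  model <- modelInit(cfg, seed = 2)
  before <- model@vae$params
  tcfg <- cfg$train
  tcfg$phase2_epochs <- 3L
  tcfg$warmup_epochs <- 3L
  tcfg$batch_size <- 4L
  tcfg$grid_update_every <- 0L
  res <- suppressWarnings(jointFinetune(model, dfcs[1:6], dfcs[7:8], tcfg,
                                        seed = 1))
  expect_identical(res$model@vae$params, before)
  expect_true(all(res$history$vae_frozen))
  # ... and moves it after warmup at the small differential rate
  tcfg$phase2_epochs <- 4L
  res2 <- suppressWarnings(jointFinetune(model, dfcs[1:6], dfcs[7:8], tcfg,
                                         seed = 1))
  expect_false(res2$history$vae_frozen[4])
  expect_error(jointFinetune(model, dfcs[1:6], dfcs[7:8],
                             within(tcfg, warmup_epochs <- 10L), 1),
               "warmup")
})

test_that("session prediction composes the evaluation path deterministically", {
  cfg <- tinyConfig()
  model <- modelInit(cfg, seed = 3)
  d <- tinyDFCs(1, K = 7, D = 10)[[1]]
  p1 <- predictSession(model, d)
  expect_equal(sum(p1$probs), 1, tolerance = 1e-9)
  expect_identical(predictSession(model, d)$probs, p1$probs)

  # identity Mamba: prediction equals the head on the mean latent
  for (l in 1:2) {
    model@mamba$params[[paste0("b", l, ".Wout")]] <-
      model@mamba$params[[paste0("b", l, ".Wout")]] * 0
  }
  mu <- vaeEncode(model@vae, dfcVectors(d))$mu
  ref <- classify(model@head, colMeans(mu))
  expect_equal(predictSession(model, d)$logits, ref$logits, tolerance = 1e-10)
  expect_error(predictSession(model, matrix(0, 3, 7)), "does not match")
})

test_that("multi-seed runs tabulate metrics and compare against a baseline", {
  dfcs <- tinyDFCs(10, K = 7, D = 10)
  sid <- sapply(dfcs, subjectId)
  split <- list(train = sid[1:6], val = sid[7:8], test = sid[9:10])
  cfg <- tinyConfig()
  cfg$train$phase1_epochs <- 1L
  cfg$train$phase2_epochs <- 1L
  cfg$train$warmup_epochs <- 1L
  cfg$train$batch_size <- 4L
  base <- suppressWarnings(multiSeedRun(dfcs, split, cfg, seeds = 1:2,
                                        variant = "no_mamba"))
  expect_identical(base$per_seed$seed, 1:2)
  expect_true(all(base$per_seed$accuracy >= 0 & base$per_seed$accuracy <= 100))
  same <- suppressWarnings(multiSeedRun(dfcs, split, cfg, seeds = 1:2,
                                        variant = "no_mamba",
                                        baseline = base))
  expect_equal(same$vs_baseline$t, 0)
  expect_match(same$vs_baseline$flag, "identical")
  expect_error(suppressWarnings(
    multiSeedRun(dfcs, split, cfg, seeds = 3:4, variant = "no_mamba",
                 baseline = base)), "different seeds")
})

test_that("the pipeline enforces leak-free splits and runs all variants", {
  dfcs <- tinyDFCs(10, K = 7, D = 10)
  sid <- sapply(dfcs, subjectId)
  bad_split <- list(train = sid[1:6], val = sid[6:7], test = sid[8:10])
  cfg <- tinyConfig()
  expect_error(trainPipeline(dfcs, bad_split, cfg, 1), "span partitions")

  cfg$train$phase1_epochs <- 2L
  cfg$train$phase2_epochs <- 2L
  cfg$train$warmup_epochs <- 1L
  cfg$train$batch_size <- 4L
  split <- list(train = sid[1:6], val = sid[7:8], test = sid[9:10])
  for (v in c("no_mamba", "mlp_head", "mean_pool")) {
    res <- suppressWarnings(trainPipeline(dfcs, split, cfg, 1, v))
    expect_true(res$report$accuracy >= 0 && res$report$accuracy <= 100)
    if (v %in% c("no_mamba", "mean_pool")) expect_length(res$model@mamba, 0)
    if (v %in% c("mlp_head", "mean_pool"))
      expect_identical(res$model@head$type, "mlp")
  }
})
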