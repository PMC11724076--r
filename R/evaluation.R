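#' Baseline classifiers with validation-tuned hyperparameters
#'
#' Fits one of the reference tabular classifiers under the standard
#' protocol: every point of a small hyperparameter grid is fitted on the
#' training partition, scored on the validation partition, and the best
#' grid point is scored once on the test partition. Test indices are never
#' touched during tuning (the returned audit log records which partitions
#' each stage saw).
#'
#' Methods and default grids:
#' \itemize{
#'   \item `random_forest`: mtry in \{sqrt(d), d/3\}, nodesize in \{1, 5\},
#'     500 trees.
#'   \item `logreg_l2`: ridge-penalised multinomial/logistic regression
#'     (glmnet, alpha = 0) over its automatic lambda path.
#'   \item `gbt_levelwise`: gradient-boosted trees with level-wise (depth-
#'     wise) growth: max_depth in \{4, 6\}, eta in \{0.1, 0.3\}, up to 400
#'     rounds with early stopping on the validation set.
#'   \item `gbt_leafwise`: leaf-wise (loss-guided) growth, the LightGBM-style
#'     strategy: max_leaves in \{31, 63\}, eta in \{0.05, 0.1\}, up to 600
#'     rounds with early stopping.
#' }
#'
#' @param ds a [TabularDataset-class] (raw values).
#' @param split a split from [splitDataset()].
#' @param method one of the method names above.
#' @param grid optional data.frame overriding the default grid.
#' @param seed RNG seed for the stochastic learners.
#' @return list with `testAccuracy` (percent), `valAccuracy`, `bestParams`,
#'   `method` and `audit`.
#' @export
runBaseline <- function(ds, split,
                        method = c("random_forest", "logreg_l2",
                                   "gbt_levelwise", "gbt_leafwise"),
                        grid = NULL, seed = 1L) {
  method <- match.arg(method)
  v <- featureValues(ds)
  y <- sampleLabels(ds)
  nc <- length(classLevels(ds))
  Xtr <- t(v[, split$train, drop = FALSE]);  ytr <- y[split$train]
  Xva <- t(v[, split$validation, drop = FALSE]); yva <- y[split$validation]
  Xte <- t(v[, split$test, drop = FALSE]);   yte <- y[split$test]
  audit <- c("tune: train+validation")
  accOf <- function(pred, truth) 100 * mean(pred == truth)

  if (method == "random_forest") {
    if (is.null(grid))
      grid <- expand.grid(
        mtry = unique(pmax(1L, c(floor(sqrt(ncol(Xtr))),
                                 floor(ncol(Xtr) / 3)))),
        nodesize = c(1L, 5L))
    fits <- lapply(seq_len(nrow(grid)), function(i) withSeed(
      deriveSeed(seed, paste0("rf", i)),
      randomForest::randomForest(Xtr, factor(ytr, levels = seq_len(nc)),
                                 ntree = 500, mtry = grid$mtry[i],
                                 nodesize = grid$nodesize[i])))
    valAcc <- vapply(fits, function(f)
      accOf(as.integer(predict(f, Xva)), yva), numeric(1))
    best <- which.max(valAcc)
    testAcc <- accOf(as.integer(predict(fits[[best]], Xte)), yte)
    bestParams <- as.list(grid[best, , drop = FALSE])
  } else if (method == "logreg_l2") {
    fam <- if (nc == 2) "binomial" else "multinomial"
    fit <- withSeed(deriveSeed(seed, "glmnet"),
      glmnet::glmnet(Xtr, factor(ytr, levels = seq_len(nc)), family = fam,
                     alpha = 0))
    predClass <- function(X) {
      pr <- predict(fit, X, type = "class")
      matrix(as.integer(pr), nrow(pr), ncol(pr))
    }
    valAcc <- apply(predClass(Xva), 2, accOf, truth = yva)
    best <- which.max(valAcc)
    testAcc <- accOf(predClass(Xte)[, best], yte)
    bestParams <- list(lambda = fit$lambda[best])
    valAcc <- valAcc[best]
    testAcc <- unname(testAcc)
  } else {
    leafwise <- method == "gbt_leafwise"
    if (is.null(grid)) {
      grid <- if (leafwise)
        expand.grid(max_leaves = c(31L, 63L), eta = c(0.05, 0.1),
                    nrounds = 600L)
      else
        expand.grid(max_depth = c(4L, 6L), eta = c(0.1, 0.3), nrounds = 400L)
    }
    obj <- if (nc == 2) "binary:logistic" else "multi:softprob"
    dtr <- xgboost::xgb.DMatrix(Xtr, label = ytr - 1)
    dva <- xgboost::xgb.DMatrix(Xva, label = yva - 1)
    fits <- lapply(seq_len(nrow(grid)), function(i) {
      params <- list(objective = obj, eta = grid$eta[i],
                     nthread = 1,
                     tree_method = "hist",
                     grow_policy = if (leafwise) "lossguide" else "depthwise",
                     max_depth = if (leafwise) 0L else grid$max_depth[i],
                     max_leaves = if (leafwise) grid$max_leaves[i] else 0L)
      if (nc > 2) params$num_class <- nc
      withSeed(deriveSeed(seed, paste0("xgb", i)),
        xgboost::xgb.train(params, dtr, nrounds = grid$nrounds[i],
                           evals = list(val = dva),
                           early_stopping_rounds = 40L, verbose = 0))
    })
    predClass <- function(f, X) {
      pr <- predict(f, xgboost::xgb.DMatrix(X))
      if (nc == 2) as.integer(pr > 0.5) + 1L
      else max.col(matrix(pr, ncol = nc, byrow = TRUE), ties.method = "first")
    }
    valAcc <- vapply(fits, function(f) accOf(predClass(f, Xva), yva),
                     numeric(1))
    best <- which.max(valAcc)
    testAcc <- accOf(predClass(fits[[best]], Xte), yte)
    bestParams <- as.list(grid[best, , drop = FALSE])
  }
  audit <- c(audit, "score: test (once, best grid point only)")
  list(method = method, testAccuracy = testAcc, valAccuracy = max(valAcc),
       bestParams = bestParams, audit = audit)
}

#' The printed three-representation recipe for the ringnorm benchmark
#'
#' t-SNE with hamming distance, t-SNE (Euclidean) with Gaussian blurring,
#' and UMAP -- the "tsne (hamming) + Blurring + umap" combination. The
#' blurring entry names only the filter, so it is attached to the default
#' (Euclidean) t-SNE manifold.
#'
#' @param seed seed shared by the representation specs.
#' @return list of three [RepresentationSpec-class] objects.
#' @export
ringnormRepresentations <- function(seed = 1L) {
  list(representationSpec("tsne", metric = "hamming", seed = seed),
       representationSpec("tsne", metric = "euclidean", filter = "blur",
                          seed = seed + 1L),
       representationSpec("umap", filter = "none", seed = seed + 2L))
}

# fit the image pipeline (normalizer, maps, stacks, CNN) and score the test
# partition by soft voting; used by runTable2Ringnorm for both the m = 1
# baseline and the m = 3 ensemble
fitImagePipeline <- function(ds, split, specs, p, q, config,
                             collision = "mean") {
  train <- subsetSamples(ds, split$train)
  val <- subsetSamples(ds, split$validation)
  test <- subsetSamples(ds, split$test)
  norm <- fitNorm2(train)
  trainN <- applyNorm2(norm, train)
  valN <- applyNorm2(norm, val)
  maps <- lapply(specs, function(s) computePixelMap(trainN, s, p, q))
  trStacks <- buildStacks(trainN, maps, collision)
  vaStacks <- buildStacks(valN, maps, collision)
  model <- trainModel(trStacks, sampleLabels(train), config,
                      vaStacks, sampleLabels(val),
                      classLevels = classLevels(ds), normalizer = norm,
                      collision = collision)
  preds <- predictBatch(test, model)
  list(model = model, predictions = preds, accuracy = accuracy(preds))
}

#' Benchmark run on freshly generated ringnorm data
#'
#' For every seed: generate ringnorm (7400 samples, 20 features by
#' default), split 80:10:10 stratified, run the four tuned baselines, the
#' single-representation image pipeline (classic DeepInsight: Euclidean
#' t-SNE, no filter) and the three-representation soft-voting ensemble
#' ([ringnormRepresentations()]), and score every method on the held-out
#' test partition. Results are reported per seed with a mean +/- sd
#' summary.
#'
#' @param seeds integer vector of seeds (each seed drives generation, split
#'   and all learners).
#' @param nSamples,nFeatures ringnorm dimensions (defaults 7400 x 20).
#' @param p,q image grid (default 16 x 16 -- ample for 20 features and fast
#'   on one CPU).
#' @param cnnConfig a [TrainConfig-class] for the image pipelines; the
#'   default trains 30 epochs with a learning-rate grid screened on the
#'   validation set.
#' @param includeCNN set FALSE to run only the four baselines.
#' @return an [ExperimentReport-class].
#' @export
runTable2Ringnorm <- function(seeds = 1:5, nSamples = 7400L,
                              nFeatures = 20L, p = 16L, q = 16L,
                              cnnConfig = NULL, includeCNN = TRUE) {
  seeds <- as.integer(seeds)
  methods_ <- c("random_forest", "logreg_l2", "gbt_levelwise", "gbt_leafwise")
  if (includeCNN) methods_ <- c(methods_, "deepinsight", "mrep_deepinsight")
  rows <- list()
  splitSizes <- NULL
  for (seed in seeds) {
    ds <- generateRingnorm(generatorConfig("ringnorm", nSamples = nSamples,
                                           nFeatures = nFeatures,
                                           seed = seed))
    split <- splitDataset(ds, c(0.8, 0.1, 0.1), seed = seed)
    splitSizes <- lengths(split[c("train", "validation", "test")])
    for (m in c("random_forest", "logreg_l2", "gbt_levelwise",
                "gbt_leafwise")) {
      res <- runBaseline(ds, split, m, seed = seed)
      rows[[length(rows) + 1L]] <- data.frame(method = m, seed = seed,
                                              accuracy = res$testAccuracy)
    }
    if (includeCNN) {
      cfg <- if (is.null(cnnConfig))
        trainConfig(epochs = 30L, batchSize = 128L, seed = seed,
                    params = list(lrGrid = c(1e-2, 1e-3, 1e-4),
                                  screenEpochs = 6L))
      else cnnConfig
      di <- fitImagePipeline(ds, split,
                             list(representationSpec("tsne", seed = seed)),
                             p, q, cfg)
      rows[[length(rows) + 1L]] <- data.frame(method = "deepinsight",
                                              seed = seed,
                                              accuracy = di$accuracy)
      mr <- fitImagePipeline(ds, split, ringnormRepresentations(seed),
                             p, q, cfg)
      rows[[length(rows) + 1L]] <- data.frame(method = "mrep_deepinsight",
                                              seed = seed,
                                              accuracy = mr$accuracy)
    }
  }
  results <- do.call(rbind, rows)
  summary_ <- do.call(rbind, lapply(methods_, function(m) {
    a <- results$accuracy[results$method == m]
    data.frame(method = m, mean = mean(a),
               sd = if (length(a) > 1) sd(a) else NA_real_)
  }))
  fp <- digest::digest(list(seeds = seeds, nSamples = nSamples,
                            nFeatures = nFeatures, p = p, q = q,
                            includeCNN = includeCNN))
  methods::new("ExperimentReport", results = results, summary = summary_,
               splitSizes = as.integer(splitSizes), seeds = seeds,
               fingerprint = fp)
}

#' Write an experiment report as CSV and Markdown
#'
#' @param report an [ExperimentReport-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report@results, file.path(dir, "results.csv"), row.names = FALSE)
  write.csv(report@summary, file.path(dir, "summary.csv"), row.names = FALSE)
  md <- c("| Method | Mean accuracy (%) | SD |", "|---|---|---|",
          sprintf("| %s | %.1f | %s |", report@summary$method,
                  report@summary$mean,
                  ifelse(is.na(report@summary$sd), "-",
                         sprintf("%.2f", report@summary$sd))))
  writeLines(c(md, "",
               paste0("Split sizes (train/validation/test): ",
                      paste(report@splitSizes, collapse = "/")),
               paste0("Seeds: ", paste(report@seeds, collapse = ", ")),
               paste0("Config fingerprint: ", report@fingerprint)),
             file.path(dir, "report.md"))
  invisible(dir)
}
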