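# Training configuration, the Adam optimizer with a time-decay learning
# rate, and the patient-disjoint two-fold cross-validation protocol.

#' Training configuration
#'
#' Defaults follow the published training recipe: Adam, 30 epochs, initial
#' learning rate 1e-4, batch size 32, learning rate decayed every epoch.
#' The decay constant of the time-decay schedule is not fixed by that
#' recipe; the default is 0.1 per epoch.
#'
#' @param optimizer only "adam" is supported.
#' @param initialLr initial learning rate (> 0).
#' @param epochs number of training epochs (>= 1).
#' @param batchSize minibatch size (>= 1).
#' @param decayConstant per-epoch time-decay constant `d` in
#'   `lr(e) = initialLr / (1 + d e)`.
#' @param seed RNG seed controlling shuffling and dropout.
#' @return a validated list of class `TrainConfig`.
#' @export
trainConfig <- function(optimizer = "adam", initialLr = 1e-4, epochs = 30L,
                        batchSize = 32L, decayConstant = 0.1, seed = 1L) {
  if (optimizer != "adam") stop("only the adam optimizer is supported")
  if (initialLr <= 0) stop("initialLr must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batchSize < 1L) stop("batchSize must be >= 1")
  structure(list(optimizer = optimizer, initialLr = initialLr,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 decayConstant = decayConstant, seed = as.integer(seed)),
            class = "TrainConfig")
}

#' Time-decay learning-rate schedule
#'
#' `lr(e) = initialLr / (1 + d e)` for epoch `e >= 0`: the learning rate is
#' reduced after every epoch, strictly decreasing whenever `d > 0`.
#'
#' @param epoch 0-based epoch index.
#' @param config a [trainConfig()].
#' @return the learning rate for that epoch.
#' @examples
#' lrSchedule(0, trainConfig())                        # 1e-4
#' lrSchedule(10, trainConfig(decayConstant = 0.1))    # 5e-5
#' @export
lrSchedule <- function(epoch, config = trainConfig()) {
  if (any(epoch < 0)) stop("epoch must be >= 0")
  config$initialLr / (1 + config$decayConstant * epoch)
}

# ---- Adam over the nested parameter structure -------------------------------

# Enumerate parameter paths: list of (layer index, sublayer key or NA,
# param name). Sublayer keys follow the list names used by the composite
# backward passes.
paramPaths <- function(layers) {
  paths <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (!is.null(ly$sublayers)) {
      for (s in names(ly$sublayers)) {
        for (p in names(ly$sublayers[[s]]$params))
          paths[[length(paths) + 1L]] <- list(i = i, sub = s, p = p)
      }
    } else if (!is.null(ly$params)) {
      for (p in names(ly$params))
        paths[[length(paths) + 1L]] <- list(i = i, sub = NA, p = p)
    }
  }
  paths
}

getParam <- function(layers, pt) {
  if (is.na(pt$sub)) layers[[pt$i]]$params[[pt$p]]
  else layers[[pt$i]]$sublayers[[pt$sub]]$params[[pt$p]]
}

setParam <- function(layers, pt, value) {
  if (is.na(pt$sub)) layers[[pt$i]]$params[[pt$p]] <- value
  else layers[[pt$i]]$sublayers[[pt$sub]]$params[[pt$p]] <- value
  layers
}

getGrad <- function(grads, pt) {
  g <- grads[[pt$i]]
  if (is.na(pt$sub)) g[[pt$p]] else g[[pt$sub]][[pt$p]]
}

adamInit <- function(layers, paths) {
  lapply(paths, function(pt) {
    z <- getParam(layers, pt) * 0
    list(m = z, v = z)
  })
}

adamStep <- function(layers, grads, state, paths, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in seq_along(paths)) {
    pt <- paths[[k]]
    g <- getGrad(grads, pt)
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    layers <- setParam(layers, pt,
                       getParam(layers, pt) - lr * mhat / (sqrt(vhat) + eps))
    state[[k]] <- st
  }
  list(layers = layers, state = state)
}

# ---- training ---------------------------------------------------------------

#' Train a tiny classifier
#'
#' Minibatch training with Adam under the time-decay schedule of
#' [lrSchedule()] and softmax cross-entropy loss. Frames are shuffled every
#' epoch with the configuration seed; the recorded training accuracy is the
#' running accuracy over the epoch's minibatches (dropout active), loss the
#' running mean cross-entropy.
#'
#' @param model a materialized (tiny-scale) [CNNClassifier-class].
#' @param x `side x side x 3 x N` training tensor in [0, 1] (already
#'   preprocessed).
#' @param labels integer 0/1 vector of length N; both classes must be
#'   present.
#' @param config a [trainConfig()].
#' @return a list with `model` (trained) and `history` (data.frame with one
#'   row per epoch: `epoch`, `loss`, `accuracy`).
#' @export
trainModel <- function(model, x, labels, config = trainConfig()) {
  n <- dim(x)[4]
  if (length(labels) != n) stop("labels must match the number of frames")
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  x <- x - model@inputCenter
  layers <- model@layers
  paths <- paramPaths(layers)
  state <- adamInit(layers, paths)
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        accuracy = NA_real_)
  t <- 0L
  withLocalSeed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      lr <- lrSchedule(epoch - 1L, config)
      idx <- sample.int(n)
      lossSum <- 0; correct <- 0L
      for (start in seq(1L, n, by = config$batchSize)) {
        bi <- idx[start:min(start + config$batchSize - 1L, n)]
        xb <- x[, , , bi, drop = FALSE]
        yb <- labels[bi]
        fw <- forwardModel(layers, xb, training = TRUE, keepCaches = TRUE)
        ls <- softmaxCrossEntropy(fw$logits, yb)
        bw <- backwardModel(layers, fw$caches, ls$dlogits)
        t <- t + 1L
        upd <- adamStep(layers, bw$grads, state, paths, lr, t)
        layers <- upd$layers; state <- upd$state
        lossSum <- lossSum + ls$loss * length(bi)
        correct <- correct + sum((ls$probs[2, ] > ls$probs[1, ]) == (yb == 1))
      }
      history$loss[epoch] <- lossSum / n
      history$accuracy[epoch] <- correct / n
    }
  })
  model@layers <- layers
  model@trained <- TRUE
  list(model = model, history = history)
}

# ---- two-fold protocol ------------------------------------------------------

foldFromManifest <- function(f) {
  structure(list(foldIndex = as.integer(f$foldIndex),
                 trainSequences = unlist(f$trainSequences),
                 testSequences = unlist(f$testSequences)),
            class = "FoldDefinition")
}

#' Run the two-fold ensemble experiment
#'
#' For each patient-disjoint fold: preprocess the frames, train one tiny
#' classifier per requested architecture on the fold's training sequences,
#' score the test frames, fuse the member scores with each combination
#' rule, and compute sensitivity / specificity / accuracy. Fold rows are
#' then combined with the testing-size-weighted average of
#' [weightedFoldAverage()], and per-rule ROC curves are averaged over folds
#' on the common FAR grid.
#'
#' @param datasetDir dataset directory written by [generateDataset()].
#' @param architectures character vector of member architectures.
#' @param rules combination rules to evaluate.
#' @param config a [trainConfig()]; member initialization seeds are derived
#'   from `config$seed`.
#' @param inputSide classifier input side (frames are preprocessed and
#'   resized to this).
#' @param thresholdFraction background-removal profile threshold.
#' @param dropoutRate head dropout for the member models.
#' @param verbose print per-fold progress.
#' @return a list of class `TwoFoldReport` with elements `folds` (per-fold
#'   member/rule `MetricsRow`s, counts, ROC curves), `averages`
#'   (weighted-average `MetricsRow` per member and rule), `roc` (fold-
#'   averaged per-rule and per-member curves), `history` (training
#'   histories) and `predictions` (per-frame data.frame: frame_id, fold,
#'   truth, member s1 scores, rule labels).
#' @export
runTwoFold <- function(datasetDir,
                       architectures = c("vgg", "inception", "densenet"),
                       rules = c("max", "average", "voting"),
                       config = trainConfig(), inputSide = 64L,
                       thresholdFraction = 0.10, dropoutRate = 0.5,
                       verbose = FALSE) {
  ds <- loadDataset(datasetDir)
  frames <- ds$frames
  folds <- lapply(ds$manifest$folds, foldFromManifest)
  x <- preprocessBatch(frames$path, thresholdFraction, inputSide)

  foldResults <- list()
  histories <- list()
  predictions <- list()
  for (fd in folds) {
    if (length(intersect(fd$trainSequences, fd$testSequences)) > 0L)
      stop("fold ", fd$foldIndex, " is not patient-disjoint")
    trainIdx <- which(frames$sequence %in% fd$trainSequences)
    testIdx <- which(frames$sequence %in% fd$testSequences)
    yTrain <- frames$label[trainIdx]
    yTest <- frames$label[testIdx]
    if (length(unique(yTrain)) < 2L)
      stop("fold ", fd$foldIndex, ": training partition has a single class")
    if (length(unique(yTest)) < 2L)
      stop("fold ", fd$foldIndex, ": test partition has a single class")

    memberScores <- array(0, c(length(testIdx), length(architectures), 2L))
    memberRows <- list()
    for (mi in seq_along(architectures)) {
      arch <- architectures[mi]
      if (verbose)
        message(sprintf("fold %d: training %s", fd$foldIndex, arch))
      mseed <- (config$seed * 131L + fd$foldIndex * 17L + mi) %% 2147483647L
      model <- buildClassifier(arch, scale = "tiny", inputSide = inputSide,
                               dropoutRate = dropoutRate, seed = mseed)
      mcfg <- config
      mcfg$seed <- mseed
      tr <- trainModel(model, x[, , , trainIdx, drop = FALSE], yTrain, mcfg)
      histories[[sprintf("fold%d_%s", fd$foldIndex, arch)]] <- tr$history
      probs <- predictProba(tr$model, x[, , , testIdx, drop = FALSE])
      memberScores[, mi, ] <- probs
      memberRows[[arch]] <- computeMetrics(
        confusionCounts(as.integer(probs[, "s1"] > probs[, "s0"]), yTest))
    }

    ruleRows <- list(); ruleRoc <- list(); ruleLabels <- list()
    for (rule in rules) {
      lab <- fuseLabels(memberScores, rule)
      ruleLabels[[rule]] <- lab
      ruleRows[[rule]] <- computeMetrics(confusionCounts(lab, yTest))
      ruleRoc[[rule]] <- rocCurve(fuseScores(memberScores, rule), yTest)
    }
    memberRoc <- lapply(seq_along(architectures), function(mi)
      rocCurve(memberScores[, mi, 2], yTest))
    names(memberRoc) <- architectures

    pred <- data.frame(frame_id = frames$frame_id[testIdx],
                       fold = fd$foldIndex, truth = yTest,
                       stringsAsFactors = FALSE)
    for (mi in seq_along(architectures))
      pred[[paste0("s1_", architectures[mi])]] <- memberScores[, mi, 2]
    for (rule in rules) pred[[paste0("label_", rule)]] <- ruleLabels[[rule]]
    predictions[[fd$foldIndex]] <- pred

    foldResults[[fd$foldIndex]] <- list(
      foldIndex = fd$foldIndex,
      positives = sum(yTest == 1), negatives = sum(yTest == 0),
      members = memberRows, rules = ruleRows,
      memberRoc = memberRoc, ruleRoc = ruleRoc)
  }

  P <- vapply(foldResults, `[[`, numeric(1), "positives")
  N <- vapply(foldResults, `[[`, numeric(1), "negatives")
  averages <- list(
    members = lapply(architectures, function(a)
      weightedFoldAverage(lapply(foldResults, function(fr) fr$members[[a]]),
                          P, N)),
    rules = lapply(rules, function(r)
      weightedFoldAverage(lapply(foldResults, function(fr) fr$rules[[r]]),
                          P, N)))
  names(averages$members) <- architectures
  names(averages$rules) <- rules
  roc <- list(
    members = lapply(architectures, function(a)
      averageRocCurves(lapply(foldResults, function(fr) fr$memberRoc[[a]]))),
    rules = lapply(rules, function(r)
      averageRocCurves(lapply(foldResults, function(fr) fr$ruleRoc[[r]]))))
  names(roc$members) <- architectures
  names(roc$rules) <- rules

  structure(list(folds = foldResults, averages = averages, roc = roc,
                 history = histories,
                 predictions = do.call(rbind, predictions)),
            class = "TwoFoldReport")
}

#' Flatten a two-fold report into a metrics table
#'
#' One row per fold (plus the weighted average) and per configuration
#' (member architectures then combination rules), with sensitivity,
#' specificity and accuracy in percent rounded to three decimals for
#' display.
#'
#' @param report a `TwoFoldReport` from [runTwoFold()].
#' @return a data.frame with columns `fold`, `configuration`, `sens`,
#'   `spec`, `accuracy`.
#' @export
reportTable <- function(report) {
  rows <- list()
  addRow <- function(fold, configuration, m) {
    rows[[length(rows) + 1L]] <<- data.frame(
      fold = fold, configuration = configuration,
      sens = roundHalfUp(m$sens), spec = roundHalfUp(m$spec),
      accuracy = roundHalfUp(m$accuracy), stringsAsFactors = FALSE)
  }
  for (fr in report$folds) {
    for (a in names(fr$members))
      addRow(as.character(fr$foldIndex), a, fr$members[[a]])
    for (r in names(fr$rules))
      addRow(as.character(fr$foldIndex), paste0(r, " rule"), fr$rules[[r]])
  }
  for (a in names(report$averages$members))
    addRow("average", a, report$averages$members[[a]])
  for (r in names(report$averages$rules))
    addRow("average", paste0(r, " rule"), report$averages$rules[[r]])
  do.call(rbind, rows)
}

#' @export
print.TwoFoldReport <- function(x, ...) {
  cat("Two-fold ensemble report\n")
  print(reportTable(x), row.names = FALSE)
  invisible(x)
}
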