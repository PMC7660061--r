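# Synthetic endoscopy-frame generator.
#
# Emulates the salient structure of in vivo GI endoscopy stills: a dark
# low-illumination border surrounding a bright tissue interior, and two frame
# classes - with or without a pathological site (a bright polyp-like blob or
# dark vascular-like curvilinear strokes). Frames are grouped into video
# sequences so that patient-disjoint fold splits can be exercised, and each
# sequence carries a Hamlyn-style annotation file: one tab-separated line per
# frame, `frame_id x y w h`, with all four geometry fields -1 for frames
# without a pathological site.

# Channel tint applied to the synthetic gray-level field. Chosen so that the
# BT.601 luma of the tinted pixel equals the gray level exactly
# (0.299*1.1 + 0.587*0.97 + 0.114*0.892 = 1), giving frames a reddish
# endoscopy cast without disturbing gray-level contracts.
.TINT <- c(1.1, 0.97, 0.892)

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps per-frame generation reproducible
# without clobbering the session RNG.
withLocalSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic per-frame child seed keyed by (dataset seed, sequence, frame).
frameSeedFor <- function(seed, sequenceIndex, frameIndex) {
  ((seed %% 2147483647) * 100003 + sequenceIndex * 10007 + frameIndex) %%
    2147483647
}

#' Specify a synthetic endoscopy frame
#'
#' Builds and validates the specification of one synthetic frame. A frame is
#' positive (`label = 1`) if and only if it carries a lesion
#' (`lesionKind != "none"`), in which case `lesionBox` must be given and must
#' lie strictly inside the bright interior (the region inside the dark
#' border).
#'
#' @param width,height frame size in pixels.
#' @param label 0 (without pathological site) or 1 (with).
#' @param lesionKind "none", "polyp" (bright Gaussian-profile blob) or
#'   "vascular" (dark curvilinear strokes).
#' @param lesionBox a [cropBox()] strictly inside the interior, or `NULL`.
#' @param borderWidth width of the dark border band in pixels;
#'   `1 <= borderWidth < min(width, height) / 2`.
#' @param foregroundMean mean interior gray level, 0-255.
#' @param foregroundNoiseSd interior noise standard deviation, gray levels.
#' @param seed integer seed; identical specs generate bit-identical frames.
#' @return a validated list of class `FrameSpec`.
#' @examples
#' frameSpec(64, 64, label = 0, seed = 1)
#' @export
frameSpec <- function(width, height, label, lesionKind = "none",
                      lesionBox = NULL, borderWidth = 8L,
                      foregroundMean = 150, foregroundNoiseSd = 15,
                      seed = 1L) {
  s <- list(width = as.integer(width), height = as.integer(height),
            label = as.integer(label), lesionKind = lesionKind,
            lesionBox = lesionBox, borderWidth = as.integer(borderWidth),
            foregroundMean = foregroundMean,
            foregroundNoiseSd = foregroundNoiseSd, seed = as.integer(seed))
  class(s) <- "FrameSpec"
  validateFrameSpec(s)
  s
}

validateFrameSpec <- function(s) {
  if (!s$label %in% c(0L, 1L))
    stop("FrameSpec invariant violated: label must be 0 or 1")
  if (!s$lesionKind %in% c("none", "polyp", "vascular"))
    stop("FrameSpec invariant violated: unknown lesionKind '", s$lesionKind, "'")
  if ((s$label == 1L) != (s$lesionKind != "none"))
    stop("FrameSpec invariant violated: label = 1 iff lesionKind != 'none'")
  if ((s$label == 1L) != (!is.null(s$lesionBox)))
    stop("FrameSpec invariant violated: lesionBox present iff label = 1")
  if (s$borderWidth < 1L || s$borderWidth >= min(s$width, s$height) / 2)
    stop("FrameSpec invariant violated: borderWidth must be >= 1 and < min(width, height)/2")
  if (!is.null(s$lesionBox)) {
    interior <- cropBox(s$borderWidth, s$height - s$borderWidth,
                        s$borderWidth, s$width - s$borderWidth)
    if (!boxContains(interior, s$lesionBox))
      stop("FrameSpec invariant violated: lesionBox must lie strictly inside the bright interior")
  }
  invisible(s)
}

# paint a bright elliptical Gaussian-profile blob into gray field `g`
paintPolyp <- function(g, box, amplitude) {
  rows <- (box$top + 1L):box$bottom
  cols <- (box$left + 1L):box$right
  cy <- mean(rows); cx <- mean(cols)
  ry <- max((box$bottom - box$top) / 2, 1)
  rx <- max((box$right - box$left) / 2, 1)
  r2 <- outer(((rows - cy) / ry)^2, ((cols - cx) / rx)^2, `+`)
  g[rows, cols] <- g[rows, cols] + amplitude * exp(-r2 / (2 * 0.45^2))
  g
}

# paint dark anti-aliased random-walk strokes into gray field `g`
paintVascular <- function(g, box, amplitude, nStrokes) {
  h <- box$bottom - box$top; w <- box$right - box$left
  for (k in seq_len(nStrokes)) {
    y <- box$top + runif(1, 0.2, 0.8) * h
    x <- box$left + runif(1, 0.2, 0.8) * w
    ang <- runif(1, 0, 2 * pi)
    nSteps <- max(h, w) * 2L
    for (step in seq_len(nSteps)) {
      ang <- ang + rnorm(1, 0, 0.35)
      y <- min(max(y + 0.5 * sin(ang), box$top + 1), box$bottom - 1)
      x <- min(max(x + 0.5 * cos(ang), box$left + 1), box$right - 1)
      i0 <- floor(y); j0 <- floor(x)
      fy <- y - i0; fx <- x - j0
      # bilinear deposit onto the four neighbouring pixels (1-based indices)
      for (d in list(c(0, 0, (1 - fy) * (1 - fx)), c(1, 0, fy * (1 - fx)),
                     c(0, 1, (1 - fy) * fx), c(1, 1, fy * fx))) {
        ii <- i0 + d[1] + 1L; jj <- j0 + d[2] + 1L
        g[ii, jj] <- g[ii, jj] - 0.6 * amplitude * d[3]
      }
    }
  }
  g
}

#' Generate one synthetic endoscopy frame
#'
#' Renders the frame described by a [frameSpec()]: a dark border band of the
#' requested width (mean gray < 15/255 of full scale), a bright noisy
#' interior, and - for positive frames - a lesion painted inside the lesion
#' box (polyp: bright elliptical blob; vascular: dark curvilinear strokes).
#' Identical specs (including the seed) produce bit-identical images.
#'
#' @param spec a `FrameSpec`.
#' @param frameId frame identifier written into the annotation record.
#' @return a list with `image` (height x width x 3 array in [0, 1], quantized
#'   to the 8-bit grid so PNG round-trips are exact) and `record` (a one-row
#'   data.frame `frame_id, x, y, w, h`; all four geometry fields are -1 for
#'   negative frames).
#' @examples
#' fr <- generateFrame(frameSpec(64, 64, label = 0, seed = 7))
#' dim(fr$image)
#' fr$record
#' @export
generateFrame <- function(spec, frameId = "frame_0001") {
  validateFrameSpec(spec)
  withLocalSeed(spec$seed, {
    H <- spec$height; W <- spec$width; bw <- spec$borderWidth
    g <- matrix(pmin(pmax(rnorm(H * W, mean = 6, sd = 2.5), 0), 12), H, W)
    rows <- (bw + 1L):(H - bw)
    cols <- (bw + 1L):(W - bw)
    g[rows, cols] <- rnorm(length(rows) * length(cols),
                           mean = spec$foregroundMean,
                           sd = spec$foregroundNoiseSd)
    if (spec$lesionKind == "polyp") {
      g <- paintPolyp(g, spec$lesionBox, runif(1, 30, 60))
    } else if (spec$lesionKind == "vascular") {
      g <- paintVascular(g, spec$lesionBox, runif(1, 30, 60), sample(3:8, 1))
    }
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- g * .TINT[ch]
    img <- round(pmin(pmax(img, 0), 255)) / 255
    rec <- if (spec$label == 1L) {
      data.frame(frame_id = frameId,
                 x = spec$lesionBox$left, y = spec$lesionBox$top,
                 w = spec$lesionBox$right - spec$lesionBox$left,
                 h = spec$lesionBox$bottom - spec$lesionBox$top,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(frame_id = frameId, x = -1L, y = -1L, w = -1L, h = -1L,
                 stringsAsFactors = FALSE)
    }
    list(image = img, record = rec)
  })
}

# Draw a random frame spec for dataset generation (under the caller's RNG).
randomFrameSpec <- function(width, height, borderWidth, positiveFraction,
                            foregroundMean, foregroundNoiseSd, seed) {
  positive <- runif(1) < positiveFraction
  lesionKind <- "none"; box <- NULL
  if (positive) {
    lesionKind <- if (runif(1) < 0.5) "polyp" else "vascular"
    inTop <- borderWidth; inBottom <- height - borderWidth
    inLeft <- borderWidth; inRight <- width - borderWidth
    side <- inBottom - inTop
    bh <- round(runif(1, 0.22, 0.38) * side)
    bwd <- round(runif(1, 0.22, 0.38) * (inRight - inLeft))
    top <- inTop + floor(runif(1) * (inBottom - inTop - bh))
    left <- inLeft + floor(runif(1) * (inRight - inLeft - bwd))
    box <- cropBox(top, top + bh, left, left + bwd)
  }
  frameSpec(width, height, label = as.integer(positive),
            lesionKind = lesionKind, lesionBox = box,
            borderWidth = borderWidth, foregroundMean = foregroundMean,
            foregroundNoiseSd = foregroundNoiseSd, seed = seed)
}

#' Generate a synthetic endoscopy dataset on disk
#'
#' Writes `nSequences` video-sequence directories, each holding
#' `framesPerSequence` PNG frames and one tab-separated annotation file
#' (`frame_id x y w h`, negatives as `-1 -1 -1 -1`), plus a JSON manifest
#' with per-sequence counts and the two patient-disjoint fold definitions
#' from [makeFoldSplits()]. Generation is keyed per frame by
#' (seed, sequence, frame index), so the same call is byte-identical and any
#' single frame can be regenerated without replaying the whole dataset.
#'
#' @param nSequences number of video sequences (>= 2).
#' @param framesPerSequence frames per sequence (>= 1).
#' @param positiveFraction expected fraction of positive frames, in [0, 1].
#' @param seed integer dataset seed.
#' @param outDir output directory (created if needed).
#' @param width,height frame size in pixels.
#' @param borderWidth dark border width in pixels.
#' @param foregroundMean,foregroundNoiseSd interior gray-level distribution.
#' @return the manifest, invisibly, as a list (also written to
#'   `manifest.json`).
#' @examples
#' d <- generateDataset(2, 3, 0.5, seed = 1, outDir = tempfile())
#' d$total
#' @export
generateDataset <- function(nSequences, framesPerSequence, positiveFraction,
                            seed, outDir, width = 64L, height = 64L,
                            borderWidth = 8L, foregroundMean = 150,
                            foregroundNoiseSd = 15) {
  if (nSequences < 2L) stop("nSequences must be >= 2")
  if (framesPerSequence < 1L) stop("framesPerSequence must be >= 1")
  if (positiveFraction < 0 || positiveFraction > 1)
    stop("positiveFraction must lie in [0, 1]")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("outDir is not writable: ", outDir)

  seqInfo <- vector("list", nSequences)
  for (s in seq_len(nSequences)) {
    seqId <- sprintf("seq_%02d", s)
    seqDir <- file.path(outDir, seqId)
    dir.create(seqDir, showWarnings = FALSE)
    records <- vector("list", framesPerSequence)
    for (f in seq_len(framesPerSequence)) {
      fs <- frameSeedFor(seed, s, f)
      spec <- withLocalSeed(fs, randomFrameSpec(width, height, borderWidth,
                                                positiveFraction,
                                                foregroundMean,
                                                foregroundNoiseSd,
                                                seed = fs))
      frameName <- sprintf("frame_%04d", f)
      out <- generateFrame(spec, frameId = paste(seqId, frameName, sep = "/"))
      png::writePNG(out$image, file.path(seqDir, paste0(frameName, ".png")))
      records[[f]] <- out$record
    }
    ann <- do.call(rbind, records)
    write.table(ann, file.path(seqDir, "annotations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    seqInfo[[s]] <- list(id = seqId, frames = framesPerSequence,
                         positives = sum(ann$x >= 0))
  }
  folds <- makeFoldSplits(vapply(seqInfo, `[[`, character(1), "id"))
  manifest <- list(
    nSequences = nSequences, framesPerSequence = framesPerSequence,
    width = width, height = height, borderWidth = borderWidth,
    positiveFraction = positiveFraction, seed = seed,
    total = nSequences * framesPerSequence,
    sequences = seqInfo,
    folds = lapply(folds, unclass)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Patient-disjoint two-fold splits over ordered sequences
#'
#' Fold 1 trains on the first half of the ordered sequence list and tests on
#' the second half; fold 2 exchanges the two sets. Because frames of one
#' video sequence (one patient) never straddle a split, both folds are
#' patient-disjoint.
#'
#' @param sequenceIds ordered character or integer vector of sequence ids
#'   (>= 2 ids).
#' @return a list of two `FoldDefinition` lists, each with `foldIndex`,
#'   `trainSequences` and `testSequences`.
#' @examples
#' makeFoldSplits(sprintf("seq_%02d", 1:10))
#' @export
makeFoldSplits <- function(sequenceIds) {
  sequenceIds <- as.character(sequenceIds)
  n <- length(sequenceIds)
  if (n < 2L)
    stop("patient-disjoint split impossible: need at least 2 sequences")
  if (anyDuplicated(sequenceIds)) stop("sequence ids must be unique")
  k <- ceiling(n / 2)
  first <- sequenceIds[seq_len(k)]
  second <- sequenceIds[(k + 1L):n]
  fold1 <- structure(list(foldIndex = 1L, trainSequences = first,
                          testSequences = second), class = "FoldDefinition")
  fold2 <- structure(list(foldIndex = 2L, trainSequences = second,
                          testSequences = first), class = "FoldDefinition")
  list(fold1, fold2)
}

#' @export
print.FoldDefinition <- function(x, ...) {
  cat(sprintf("Fold %d: train {%s} | test {%s}\n", x$foldIndex,
              paste(x$trainSequences, collapse = ", "),
              paste(x$testSequences, collapse = ", ")))
  invisible(x)
}

#' Read a sequence annotation file
#'
#' @param path path to a tab-separated annotation file with columns
#'   `frame_id, x, y, w, h` and no header.
#' @return a data.frame with those five columns and a derived `label` column
#'   (1 when the geometry fields are non-negative, 0 for the -1 sentinel).
#' @export
readAnnotations <- function(path) {
  ann <- read.delim(path, header = FALSE,
                    col.names = c("frame_id", "x", "y", "w", "h"),
                    stringsAsFactors = FALSE)
  geom <- as.matrix(ann[, c("x", "y", "w", "h")])
  allNeg <- apply(geom == -1, 1, all)
  allPos <- ann$x >= 0 & ann$y >= 0 & ann$w >= 1 & ann$h >= 1
  if (any(!allNeg & !allPos))
    stop("AnnotationRecord invariant violated: each record must have all ",
         "geometry fields >= 0 (w, h >= 1) or all equal to -1")
  ann$label <- as.integer(allPos)
  ann
}

#' Load a generated dataset's frame table
#'
#' @param dir dataset directory written by [generateDataset()].
#' @return a list with `manifest` (parsed JSON) and `frames` (a data.frame
#'   with columns `frame_id, sequence, path, label, x, y, w, h`).
#' @export
loadDataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  # jsonlite simplifies the fold list into a data.frame with list columns;
  # normalize back to one plain list per fold
  if (is.data.frame(manifest$folds)) {
    manifest$folds <- lapply(seq_len(nrow(manifest$folds)), function(i) {
      list(foldIndex = manifest$folds$foldIndex[i],
           trainSequences = unlist(manifest$folds$trainSequences[i]),
           testSequences = unlist(manifest$folds$testSequences[i]))
    })
  }
  seqIds <- manifest$sequences$id
  frames <- do.call(rbind, lapply(seqIds, function(sid) {
    ann <- readAnnotations(file.path(dir, sid, "annotations.tsv"))
    ann$sequence <- sid
    ann$path <- file.path(dir, paste0(ann$frame_id, ".png"))
    ann
  }))
  rownames(frames) <- NULL
  list(manifest = manifest,
       frames = frames[, c("frame_id", "sequence", "path", "label",
                           "x", "y", "w", "h")])
}
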