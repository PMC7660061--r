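# Score fusion: MAX, AVERAGE and majority-VOTING combination of the
# two-class probability vectors produced by the ensemble members.
#
# Every argmax tie (within a score vector, between class-wise maxima, or a
# tied vote with no fallback) resolves to the positive class by default —
# the conservative choice for a screening triage tool — and is configurable
# via `tieBreak`.
#
# Note on the voting rule: taken literally, a sign over the sum of
# w_i * argmax(S_i) would annihilate every negative vote (w_i * 0 = 0) and
# reduce to "any positive vote wins". The rule is implemented as the
# majority vote it is described as: the sign of the sum of the member
# weights w_i (+1 for a positive member decision, -1 for a negative one),
# with a tied sum (possible for even ensemble sizes) falling back to the
# AVERAGE rule on the same score vectors.

asScoreMatrix <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores))
    scores <- do.call(rbind, lapply(scores, as.numeric))
  scores <- as.matrix(scores)
  if (ncol(scores) != 2L)
    stop("scores must be two-class vectors (s0, s1)")
  if (nrow(scores) < 1L) stop("at least one score vector is required")
  if (any(scores < -1e-9) || any(scores > 1 + 1e-9))
    stop("ScoreVector invariant violated: probabilities must lie in [0, 1]")
  if (any(abs(rowSums(scores) - 1) > 1e-6))
    stop("ScoreVector invariant violated: components must sum to 1")
  scores
}

argmaxLabel <- function(v, tieBreak) {
  if (v[2] > v[1]) 1L
  else if (v[1] > v[2]) 0L
  else if (tieBreak == "positive") 1L else 0L
}

memberLabels <- function(scores, tieBreak = "positive") {
  apply(scores, 1L, argmaxLabel, tieBreak = tieBreak)
}

newDecision <- function(label, rule, combined = NULL, memberLabels,
                        memberWeights = NULL) {
  structure(list(label = as.integer(label), rule = rule, combined = combined,
                 memberLabels = as.integer(memberLabels),
                 memberWeights = memberWeights),
            class = "EnsembleDecision")
}

#' @export
print.EnsembleDecision <- function(x, ...) {
  cat(sprintf("EnsembleDecision: label %d by %s rule (members: %s)\n",
              x$label, toupper(x$rule), paste(x$memberLabels, collapse = " ")))
  invisible(x)
}

#' MAX combination rule
#'
#' The ensemble label is the class holding the single largest probability
#' entry across all members' score vectors. A tie between the class-wise
#' maxima resolves per `tieBreak`.
#'
#' @param scores an `n x 2` matrix of member score vectors (columns s0, s1),
#'   or a list of length-2 vectors.
#' @param tieBreak "positive" (default) or "negative".
#' @return an `EnsembleDecision` with fields `label`, `rule`,
#'   `memberLabels`.
#' @examples
#' maxRule(rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4)))$label  # 0
#' @export
maxRule <- function(scores, tieBreak = c("positive", "negative")) {
  tieBreak <- match.arg(tieBreak)
  scores <- asScoreMatrix(scores)
  label <- argmaxLabel(c(max(scores[, 1]), max(scores[, 2])), tieBreak)
  newDecision(label, "max", memberLabels = memberLabels(scores, tieBreak))
}

#' AVERAGE combination rule
#'
#' The combined score vector is the component-wise mean of the member
#' vectors; the label is its argmax.
#'
#' @inheritParams maxRule
#' @return an `EnsembleDecision`; `combined` holds the mean score vector.
#' @examples
#' averageRule(rbind(c(0.6, 0.4), c(0.4, 0.6), c(0.3, 0.7)))$label  # 1
#' @export
averageRule <- function(scores, tieBreak = c("positive", "negative")) {
  tieBreak <- match.arg(tieBreak)
  scores <- asScoreMatrix(scores)
  combined <- colMeans(scores)
  names(combined) <- c("s0", "s1")
  newDecision(argmaxLabel(combined, tieBreak), "average", combined = combined,
              memberLabels = memberLabels(scores, tieBreak))
}

#' VOTING combination rule
#'
#' Each member votes with weight +1 when its argmax is class 1 and -1 when
#' it is class 0; the ensemble label is 1 when the vote sum is positive and
#' 0 when negative. A zero sum (possible only for even ensemble sizes) falls
#' back to the AVERAGE rule on the same score vectors.
#'
#' @inheritParams maxRule
#' @return an `EnsembleDecision`; `memberWeights` holds the +1/-1 votes.
#' @examples
#' votingRule(rbind(c(0.1, 0.9), c(0.3, 0.7), c(0.8, 0.2)))$label  # 1
#' @export
votingRule <- function(scores, tieBreak = c("positive", "negative")) {
  tieBreak <- match.arg(tieBreak)
  scores <- asScoreMatrix(scores)
  labels <- memberLabels(scores, tieBreak)
  weights <- ifelse(labels == 1L, 1L, -1L)
  s <- sum(weights)
  if (s == 0L) {
    fb <- averageRule(scores, tieBreak)
    return(newDecision(fb$label, "voting", combined = fb$combined,
                       memberLabels = labels, memberWeights = weights))
  }
  newDecision(if (s > 0L) 1L else 0L, "voting", memberLabels = labels,
              memberWeights = weights)
}

#' Apply a combination rule to per-frame member scores
#'
#' @param scoreArray an `N x n x 2` array (frames x members x classes), or a
#'   list of `n x 2` matrices (one per frame).
#' @param rule "max", "average" or "voting".
#' @param tieBreak tie policy, see [maxRule()].
#' @return an integer vector of N fused labels.
#' @export
fuseLabels <- function(scoreArray, rule = c("max", "average", "voting"),
                       tieBreak = "positive") {
  rule <- match.arg(rule)
  fn <- switch(rule, max = maxRule, average = averageRule,
               voting = votingRule)
  frames <- if (is.list(scoreArray)) scoreArray
            else lapply(seq_len(dim(scoreArray)[1]),
                        function(i) scoreArray[i, , , drop = TRUE])
  vapply(frames, function(m) fn(rbind(m), tieBreak = tieBreak)$label,
         integer(1))
}

#' Continuous fused positive-class score for ROC analysis
#'
#' The decision rules are discrete; for threshold sweeps each rule is given
#' a continuous positive-class score: AVERAGE uses the mean `s1`; MAX uses
#' the `s1` of the member holding the globally largest probability entry;
#' VOTING maps the vote sum onto [0, 1] as `(sum(w) + n) / (2n)`.
#'
#' @inheritParams fuseLabels
#' @return a numeric vector of N scores in [0, 1].
#' @export
fuseScores <- function(scoreArray, rule = c("max", "average", "voting")) {
  rule <- match.arg(rule)
  frames <- if (is.list(scoreArray)) scoreArray
            else lapply(seq_len(dim(scoreArray)[1]),
                        function(i) scoreArray[i, , , drop = TRUE])
  vapply(frames, function(m) {
    m <- asScoreMatrix(rbind(m))
    switch(rule,
      average = mean(m[, 2]),
      max = m[which.max(apply(m, 1, max)), 2],
      voting = {
        w <- ifelse(memberLabels(m) == 1L, 1L, -1L)
        (sum(w) + nrow(m)) / (2 * nrow(m))
      })
  }, numeric(1))
}
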