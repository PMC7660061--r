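# Reference tables from the published two-fold ensemble evaluation on the
# Hamlyn-GI in vivo endoscopy dataset, shipped as plain-text data. They are
# the inputs to the arithmetic-consistency checks: per-sequence image
# counts, per-fold class counts of the patient-disjoint split, and the
# per-fold / average sensitivity-specificity-accuracy rows of the reported
# evaluation (individual classifiers and the three combination rules, with
# preprocessing).

refPath <- function(file) {
  system.file("extdata", file, package = "EndoEnsemble", mustWork = TRUE)
}

#' Per-sequence image counts of the Hamlyn-GI dataset
#'
#' @return a data.frame with columns `sequence` (1-10) and `images`; the
#'   counts sum to the dataset total of 7894 frames.
#' @export
hamlynSequenceCounts <- function() {
  read.delim(refPath("hamlyn_sequence_counts.tsv"))
}

#' Per-fold class counts of the Hamlyn-GI two-fold split
#'
#' Training/testing frame counts without and with a pathological site for
#' the two patient-disjoint folds (fold 2 exchanges fold 1's partitions).
#'
#' @return a data.frame with columns `fold`, `train_without_ps`,
#'   `train_with_ps`, `test_without_ps`, `test_with_ps`.
#' @export
hamlynFoldCounts <- function() {
  read.delim(refPath("hamlyn_fold_counts.tsv"))
}

#' Reference fold metrics of the published Hamlyn-GI evaluation
#'
#' Sensitivity, specificity and accuracy (percent) reported per fold and as
#' the testing-size-weighted two-fold average, for the three individual
#' classifiers and the three combination rules (with preprocessing).
#'
#' @return a data.frame with columns `configuration` ("vgg", "inception",
#'   "densenet", "max", "average", "voting"), `fold` ("1", "2", "average"),
#'   `sens`, `spec`, `accuracy`.
#' @export
hamlynReferenceMetrics <- function() {
  read.delim(refPath("hamlyn_reference_metrics.tsv"),
             colClasses = c(fold = "character"))
}
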