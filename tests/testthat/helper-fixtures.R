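# Shared fixtures: a small synthetic dataset generated once per test run.

smallDatasetDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      d <- file.path(tempdir(), "endoens-fixture")
      if (!dir.exists(d)) generateDataset(4, 6, 0.5, seed = 101, outDir = d)
      dir <<- d
    }
    dir
  }
})

# a deterministic positive frame spec with a known lesion box
positiveSpec <- function(seed = 5, kind = "polyp") {
  frameSpec(64, 64, label = 1, lesionKind = kind,
            lesionBox = cropBox(24, 40, 20, 36), borderWidth = 8L,
            seed = seed)
}

randomScoreSet <- function(n) {
  s1 <- runif(n)
  cbind(1 - s1, s1)
}
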