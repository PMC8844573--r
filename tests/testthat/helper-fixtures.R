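# Shared fixture builders. Everything is generated in code; no files.

discRoi <- function(H, W, r0, c0, rad) {
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  (rr - r0)^2 + (cc - c0)^2 <= rad^2
}

# standard single-cluster beating spec used across contractility tests
stdBeatSpec <- function(duration = 20, beatPeriod = 2, phaseDelay = 0,
                        noiseSd = 0.5, clusters = NULL) {
  if (is.null(clusters))
    clusters <- beatCluster(24, 24, radius = 8, beatPeriod = beatPeriod,
                            phaseDelay = phaseDelay)
  beatSpec(frameRate = 25, duration = duration, imageShape = c(48L, 48L),
           clusters = clusters, noiseSd = noiseSd)
}

# truth doublet widths (s): contraction trace start to relaxation trace end
truthDoubletWidths <- function(truth, frameRate = 25) {
  con <- truth[truth$phase == "contraction", ]
  rel <- truth[truth$phase == "relaxation", ]
  key <- paste(con$cluster, con$beat)
  rel <- rel[match(key, paste(rel$cluster, rel$beat)), ]
  (rel$traceEnd - con$traceStart + 1) / frameRate
}

# bimodal synthetic image with known truth mask
bimodalImage <- function(n = 100L, fgFrac = 0.1, loMean = 20, hiMean = 180,
                         sd = 5, seed = 42) {
  set.seed(seed)
  nFg <- round(n * n * fgFrac)
  img <- matrix(c(rnorm(n * n - nFg, loMean, sd), rnorm(nFg, hiMean, sd)),
                n, n)
  mask <- matrix(c(rep(FALSE, n * n - nFg), rep(TRUE, nFg)), n, n)
  list(image = img, mask = mask)
}
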