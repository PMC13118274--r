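# Random vector pairs with controllable ties and missingness, guaranteed
# non-degenerate under the local perspective (>= 2 points not jointly
# missing, and at least one observed value).
randomMissingPair <- function(n, missFrac = 0.3, ties = TRUE) {
  draw <- function() {
    v <- if (ties && runif(1) < 0.5) {
      as.numeric(sample(seq_len(max(2L, n %/% 3L)), n, replace = TRUE))
    } else {
      runif(n, -2, 5)
    }
    v[runif(n) < missFrac] <- NA_real_
    v
  }
  repeat {
    x <- draw(); y <- draw()
    if (sum(!(is.na(x) & is.na(y))) >= 2 && any(!is.na(c(x, y))))
      return(list(x = x, y = y))
  }
}

# brute-force tau (the rule-enumeration oracle path)
bruteTau <- function(x, y, perspective = "local") {
  suppressWarnings(tauBFromCounts(countPairsBruteforce(x, y, perspective)))
}

# a small feature x sample matrix cohort with a shared profile
smallCohort <- function(nFeatures = 60, nSamples = 5, seed = 1) {
  simLodCohort(nSamples = nSamples, nFeatures = nFeatures, seed = seed)
}

groupsFor <- function(m, labels) {
  stats::setNames(labels, colnames(m))
}
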