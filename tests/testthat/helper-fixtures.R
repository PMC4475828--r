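# shared fixtures: small synthetic communities built in code

testReference <- function(seed = 42, length = 324) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""))
}

threeEcotypeSpecs <- function(nHfs = 3L, nLfs = 2L) {
  lapply(1:3, function(i)
    ecotypeSpec(paste0("E", i), c(58 + 3 * i, 200 * i),
                nicheBreadth = c(2.5, 220), nHfs = nHfs, nLfs = nLfs))
}

# simple exhaustive Needleman-Wunsch with linear gap costs, used as the
# independent alignment oracle on toy sequences
nwOracle <- function(read, ref, match = 2, mismatch = -3, gap = 7) {
  a <- strsplit(read, "", fixed = TRUE)[[1]]
  b <- strsplit(ref, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  S <- matrix(-Inf, n + 1, m + 1)
  S[1, ] <- -gap * (0:m)
  S[, 1] <- -gap * (0:n)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- S[i, j] + if (a[i] == b[j]) match else mismatch
      S[i + 1, j + 1] <- max(sub, S[i, j + 1] - gap, S[i + 1, j] - gap)
    }
  }
  S[n + 1, m + 1]
}

# dense ter Braak CCA oracle: chi-square standardized matrix regressed on
# weighted-standardized predictors, eigenvalues of the fitted cross matrix
ccaOracle <- function(Y, X) {
  Y <- as.matrix(Y)                     # sites x species
  X <- as.matrix(X)                     # sites x predictors
  tot <- sum(Y)
  P <- Y / tot
  r <- rowSums(P); c <- colSums(P)
  Q <- (P - outer(r, c)) / sqrt(outer(r, c))
  # weighted least squares of Q on row-standardized X with weights r
  Xc <- sweep(X, 2, colSums(X * r), "-")   # weighted centring
  Xw <- Xc * sqrt(r)
  H <- Xw %*% solve(crossprod(Xw), t(Xw))
  Qfit <- H %*% Q
  ev <- eigen(crossprod(Qfit), symmetric = TRUE)$values
  list(eig = ev[ev > 1e-12], totalInertia = sum(Q^2),
       constrained = sum(Qfit^2))
}

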