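# Shared cellular Potts test utilities: random states and an independent
# brute-force energy oracle (double loop over all neighbour pairs).

randomCpm <- function(seed, n = 8, nCells = 3) {
  set.seed(seed)
  spin <- matrix(sample(0:nCells, n * n, replace = TRUE), n, n)
  J <- matrix(runif((nCells + 1)^2, 0, 2), nCells + 1)
  J <- (J + t(J)) / 2
  cpmState(spin, J, cellType = rep(1L, nCells),
           targetVolume = rep(10L, nCells), lambdaV = runif(1, 0, 2),
           temperature = 1)
}

bruteH <- function(state) {
  spin <- state@spin
  nr <- nrow(spin); nc <- ncol(spin)
  typeOf <- function(s) if (s == 0) 0L else state@cellType[s]
  H <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (d in list(c(1, 0), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii > nr || jj > nc) next
      a <- spin[i, j]; b <- spin[ii, jj]
      if (a != b) H <- H + state@adhesion[typeOf(a) + 1, typeOf(b) + 1]
    }
  }
  H + state@lambdaV * sum((state@volume - state@targetVolume)^2)
}
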