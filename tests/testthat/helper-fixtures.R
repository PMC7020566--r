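# random symmetric zero-diagonal weight matrix for reader/Kruskal tests
crossprodSym <- function(n) {
  m <- matrix(runif(n * n, -1, 1), n, n)
  s <- (m + t(m)) / 2
  diag(s) <- 0
  s
}
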