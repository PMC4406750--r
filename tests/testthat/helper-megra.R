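# Small-universe configuration used by most module tests; planted structure
# identical in kind to the full-size defaults but fast to generate.
smallConfig <- function(seed = 1L, ...) {
  args <- list(seed = seed, nGenes = 600L, nMethCallable = 550L,
               nExprCallable = 520L, nCatalogReported = 300L,
               nPlantedDmg = 30L, nPlantedDeg = 30L, gwasTraitGenes = 40L,
               plantedPathwaySize = 40L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulationConfig, args)
}

# Exact null pmf of the three-way overlap of independent uniform
# without-replacement draws from a common universe of size n, by exhaustive
# enumeration over subset bitmasks. Independent oracle for permuteOverlap.
exactOverlapPmf <- function(n, draws) {
  stopifnot(n <= 12)
  bitcount <- vapply(0:(2^n - 1), function(x) sum(bitwAnd(x, 2^(0:(n - 1))) > 0), numeric(1))
  masksOf <- function(k) utils::combn(n, k, function(ix) sum(2L^(ix - 1L)))
  m1 <- masksOf(draws[1]); m2 <- masksOf(draws[2]); m3 <- masksOf(draws[3])
  acc <- numeric(min(draws) + 1L)
  for (a in m1) for (b in m2) {
    ab <- bitwAnd(a, b)
    ov <- bitcount[bitwAnd(ab, m3) + 1L]
    tab <- tabulate(ov + 1L, nbins = length(acc))
    acc <- acc + tab
  }
  acc / sum(acc)
}

# Brute-force hypergeometric upper tail from binomial coefficients.
bruteUpperTail <- function(N, K, m, k) {
  ks <- k:min(K, m)
  sum(choose(K, ks) * choose(N - K, m - ks)) / choose(N, m)
}
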