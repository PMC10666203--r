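# Shared fixture bundles, built once per test run.

toyDir <- file.path(tempdir(), "bundle-gaussian")
toyBundle <- makeGaussianToy(toyDir)
toyProblem <- parseProblem(toyBundle$index)

viralDir <- file.path(tempdir(), "bundle-viral")
viralBundle <- makeViralFixture(viralDir, seed = 1)
viralProblem <- parseProblem(viralBundle$index)

# unit-weight distance over the toy's single statistic
toyDistance <- distanceSpec(c(y_obs_t0 = 1), adapt = "none")

# weighted mean / variance with normalised weights
wMean <- function(x, w) sum(w * x)
wVar <- function(x, w) {
  mu <- sum(w * x)
  sum(w * (x - mu)^2) / (1 - sum(w^2))
}
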