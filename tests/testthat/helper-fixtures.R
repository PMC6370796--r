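# Shared fixtures: tiny deterministic blocks and experiments built in
# code at test time.

block2x2 <- function(a11, a12, a21, a22, treatment = "t") {
    treatmentBlock(treatment,
                   matrix(as.integer(c(a11, a21, a12, a22)), 2,
                          dimnames = list(c("g1", "g2"), c("R1", "R2"))))
}

# the two canonical oracle blocks: margins (2,2)/(2,2)
blockShared <- function() block2x2(1, 1, 1, 1)     # beta_obs = 0
blockDisjoint <- function() block2x2(2, 0, 0, 2)   # beta_obs = 0.5 (q = 0)

# random block with Poisson counts, guarded against zero columns
randomBlock <- function(nOtu = 8, nRep = 3, lambda = 4) {
    m <- matrix(rpois(nOtu * nRep, lambda), nOtu,
                dimnames = list(paste0("g", seq_len(nOtu)),
                                paste0("R", seq_len(nRep))))
    m[1, colSums(m) == 0] <- 1L
    treatmentBlock("rand", m)
}

# small replicated experiment: nTreat treatments x nRep replicates
tinyExperiment <- function(nTreat = 3, nRep = 3, nOtu = 20, depth = 500,
                           phi = 1, filterStrength = 1, seed = 42,
                           nSeed = 0) {
    generateExperiment(simulationConfig(
        nOtus = nOtu, lognormalSigma = 1, nTreatments = nTreat,
        nReplicates = nRep, depth = depth,
        filterStrengths = rep(filterStrength, nTreat),
        dispersions = rep(phi, nTreat), seed = seed,
        nSeedReplicates = nSeed))
}

# uniform draws on the simplex (exchangeable, strictly positive)
randomSimplex <- function(n) {
    x <- -log(runif(n))
    x / sum(x)
}
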