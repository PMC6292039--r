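# Small in-code fixtures shared across the suite.

# 3 chromosomes x 10 evenly spaced markers on 90 cM
toyMap <- function(nChrom = 3, nMarkers = 30, chromLength = 90)
  simulateMap(nChrom = nChrom, nMarkers = nMarkers,
              chromLength = chromLength)

toyRils <- function(n = 120, seed = 11, map = toyMap())
  simulateRilGenotypes(map, simConfig(nRil = n, seed = seed))

# single-trait architecture helper
oneLocusArch <- function(trait = "SY", chrom = "C01", pos = 45, a = 1,
                         d = 0, sigmaE = 1, environments = 4,
                         qe = NULL, epistasis = data.frame()) {
  em <- matrix(0, 1, environments,
               dimnames = list(trait, sprintf("E%d", seq_len(environments))))
  qtlArchitecture(loci = data.frame(trait = trait, chrom = chrom,
                                    pos = pos, a = a, d = d),
                  envMeans = em, qe = qe, epistasis = epistasis,
                  sigmaE = sigmaE)
}

# phenotype table straight from a vector of line values (1 env, 1 rep)
phenoFromValues <- function(ids, values, trait = "SY", env = "E1") {
  PhenotypeTable(data.frame(individual = ids, trait = trait,
                            environment = env, replicate = 1L,
                            value = values))
}

# replicate-averaged environment means collapsed to a single scan input
envMeanPheno <- function(pheno) {
  d <- phenoData(pheno)
  d$environment <- "mean"
  m <- aggregate(value ~ individual + trait + environment, d, mean)
  m$replicate <- 1L
  PhenotypeTable(m)
}

extfile <- function(f) system.file("extdata", f, package = "hetqtl")
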