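# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

# moderate pedigreed dataset with full crossover truth and its called
# gametes; dense enough markers that informative-marker gaps are small
stdSim <- function() {
  if (is.null(.fixtures$sim)) {
    cfg <- simConfig(nSires = 4, nDams = 50, offspringPerMating = 3,
                     markersPerChrom = 200, seed = 20)
    .fixtures$sim <- simulateDataset(cfg)
  }
  .fixtures$sim
}

stdGametes <- function() {
  if (is.null(.fixtures$gs)) {
    sim <- stdSim()
    .fixtures$gs <- callGametes(sim$genotypes, sim$pedigree)
  }
  .fixtures$gs
}

# true ACC aligned to a called gamete table
trueAccFor <- function(sim, gametes) {
  tg <- sim$truth$gametes
  setNames(tg$acc, paste(tg$fid, tg$offspring))[
    paste(gametes$fid, gametes$offspring)]
}

# five-individual pedigree: two founders, full sibs x & y, inbred z
tinyPedigree <- function() {
  data.frame(id = c("a", "b", "x", "y", "z"),
             sire = c("0", "0", "a", "a", "x"),
             dam = c("0", "0", "b", "b", "y"),
             sex = c("M", "F", "M", "F", "M"),
             stringsAsFactors = FALSE)
}

# three-generation pedigree with genotypes for family-builder tests:
# founders g1..g4 (+ extra pair g5/g6), FIDs s1 (son of g1xg2) and d1
# (daughter of g3xg4), offspring o1..o3 of s1xd1
famPedigree <- function() {
  data.frame(
    id = c("g1", "g2", "g3", "g4", "g5", "g6", "s1", "d1", "d2",
            "o1", "o2", "o3", "p1", "p2"),
    sire = c("0", "0", "0", "0", "0", "0", "g1", "g3", "g5",
             "s1", "s1", "s1", "s1", "s1"),
    dam = c("0", "0", "0", "0", "0", "0", "g2", "g4", "g6",
            "d1", "d1", "d1", "d2", "d2"),
    sex = c("M", "F", "M", "F", "M", "F", "M", "F", "F",
            "M", "F", "M", "F", "M"),
    stringsAsFactors = FALSE)
}
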