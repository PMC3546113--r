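# Small builders used across test files.

trio <- function(f, m, x, trait = 1, id = "fam") {
  nuclear_family(id, father = f, mother = m,
                 offspring = matrix(x, nrow = 1), traits = trait)
}

dsp <- function(x1, x2, t1 = 1, t2 = 0, id = "fam") {
  nuclear_family(id, offspring = rbind(x1, x2), traits = c(t1, t2))
}

# Brute-force conditional moments of the offspring count given two typed
# parents: enumerate the 2 x 2 equally likely transmissions of each parent's
# two alleles (additive coding).
enumerate_transmissions <- function(f, m) {
  alleles <- function(g) switch(g + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
  af <- alleles(f); am <- alleles(m)
  counts <- as.vector(outer(af, am, `+`))
  list(mean = mean(counts), variance = mean(counts^2) - mean(counts)^2,
       counts = counts)
}

# All parental mating types (unordered pairs of parental genotypes) that can
# produce the observed unordered pair of offspring genotypes, used as the
# independent oracle for the sibpair conditional distribution: for each
# compatible mating type, enumerate the 16 transmission outcomes of two
# offspring and condition on the unordered pair.
sibpair_ordering_probs <- function(pair) {
  target <- sort(as.numeric(pair))
  probs <- c()
  for (f in 0:2) for (m in f:2) {
    e <- enumerate_transmissions(f, m)
    grid <- expand.grid(x1 = as.numeric(e$counts), x2 = as.numeric(e$counts))
    ok <- pmin(grid$x1, grid$x2) == target[1] & pmax(grid$x1, grid$x2) == target[2]
    if (!any(ok)) next
    p1 <- mean(grid$x1[ok] == pair[1] & grid$x2[ok] == pair[2])
    probs <- c(probs, p1)
  }
  probs  # P(first sib has pair[1]) under each compatible mating type
}

# A tiny two-family, three-marker dataset written by hand.
toy_ped_lines <- c(
  "f1 dad 0 0 1 1  1 2  2 2  1 1",
  "f1 mom 0 0 2 1  2 1  1 1  1 2",
  "f1 kid dad mom 1 2  1 2  1 2  1 2",
  "f2 s1 0 0 1 2  1 2  1 1  1 1",
  "f2 s2 0 0 1 1  1 1  1 2  1 1")
toy_map_lines <- c("1 rs1 0 1000", "1 rs2 0 2000", "1 rs3 0 3000")
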