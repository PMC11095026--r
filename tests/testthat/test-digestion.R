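test_that("fragment survival probability follows the piecewise model", {
  expect_identical(fragmentProbability(1, 0), 1)
  expect_equal(fragmentProbability(0.8, 0), 0.64)
  expect_equal(fragmentProbability(0.8, 1), 0.128)
  expect_equal(fragmentProbability(1, 2), 0)
  expect_equal(fragmentProbability(0.5, 0:3), 0.25 * 0.5^(0:3))
  expect_error(fragmentProbability(0, 0), "\\(0, 1\\]")
  expect_error(fragmentProbability(1.2, 0), "\\(0, 1\\]")
  expect_error(fragmentProbability(0.5, -1), "non-negative")
})

test_that("probability is ordered in i and c", {
  for (c_eff in c(0.3, 0.6, 0.9)) {
    p <- fragmentProbability(c_eff, 0:6)
    expect_true(all(diff(p) < 0))
  }
  p0 <- fragmentProbability(seq(0.1, 1, by = 0.1), 0)
  expect_true(all(diff(p0) > 0))
})

test_that("cut-site detection matches the worked examples", {
  g <- as_genomes(c(g1 = "GAATTCAAGAATTC"))
  expect_equal(findCutSites(g, ECO)$position, c(1L, 9L))

  g <- as_genomes(c(g1 = "GCGCGC"))  # overlapping HhaI sites
  expect_equal(findCutSites(g, HHA)$position, c(3L, 5L))

  g <- as_genomes(c(g1 = "AAAA"))
  expect_equal(nrow(findCutSites(g, MSE)), 0L)

  # N in the genome never completes a site
  g <- as_genomes(c(g1 = "GANTTCGAATTC"))
  expect_equal(findCutSites(g, ECO)$position, 7L)
})

test_that("non-palindromic motifs are scanned on both strands", {
  m <- parseMotif("ACG/TT", name = "asym")
  expect_false(m@palindromic)
  # forward site at 0, reverse-complement site (AACGT) at 7
  g <- as_genomes(c(g1 = "ACGTTGGAACGTG"))
  cs <- findCutSites(g, m)
  ora <- oracle_cut_positions(as.character(g[[1]]), "ACGTT", 3L)
  expect_equal(cs$position, ora)
  expect_setequal(cs$strand, c("+", "-"))
})

test_that("fragment enumeration matches the worked examples", {
  params1 <- digestionParams(cut_efficiency = 1, length_min = 1,
                             length_max = 100)
  f <- enumerateFragments(cut_table("c1", c(1L, 9L)), params1)
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$start, f$end, f$i, f$p), c(1, 9, 0, 1))

  params2 <- digestionParams(cut_efficiency = 0.8, length_min = 1,
                             length_max = 100, max_internal = 1)
  f <- enumerateFragments(cut_table("c1", c(1L, 5L, 9L)), params2)
  expect_equal(nrow(f), 3L)
  expect_equal(f[f$i == 0, "p"], c(0.64, 0.64))
  expect_equal(f[f$i == 1, "p"], 0.128)
  expect_equal(unlist(f[f$i == 1, c("start", "end")], use.names = FALSE),
               c(1, 9))

  # ddRAD-strict drops same-enzyme fragments
  sites <- cut_table("c1", c(1L, 9L), enzyme = "EcoRI")
  params3 <- digestionParams(cut_efficiency = 1, length_min = 1,
                             length_max = 100, ddrad_strict = TRUE)
  expect_equal(nrow(enumerateFragments(sites, params3)), 0L)
  # ...but keeps mixed-enzyme ends
  sites2 <- rbind(cut_table("c1", 1L, enzyme = "EcoRI"),
                  cut_table("c1", 9L, enzyme = "MseI"))
  expect_equal(nrow(enumerateFragments(sites2, params3)), 1L)
})

test_that("type IIB digestion emits isolength fragments and honors bounds", {
  # place the recognition instance at a known offset
  inst <- "CGAACGTACTGC"  # matches CGANNNNNNTGC
  pre <- strrep("T", 20)
  g <- as_genomes(c(g1 = paste0(pre, inst, strrep("T", 20))))
  f <- digestTypeIIB(g, BCG, cut_efficiency = 1)
  expect_equal(nrow(f), 1L)
  expect_equal(c(f$start, f$end, f$length), c(20 - 12, 20 + 12 + 12, 36))
  expect_equal(f$p, 1)

  # match too close to the contig start is dropped
  g2 <- as_genomes(c(g1 = paste0(strrep("T", 5), inst, strrep("T", 20))))
  expect_equal(nrow(digestTypeIIB(g2, BCG, 1)), 0L)

  # isolength invariant on random genomes
  set.seed(3)
  g3 <- as_genomes(c(g1 = random_genome_string(20000)))
  f3 <- digestTypeIIB(g3, BCG, 0.9)
  expect_gt(nrow(f3), 1L)
  expect_equal(unique(f3$length), 12L + 12L + 12L)
  expect_equal(unique(f3$p), 0.81)
})

test_that("digestGenome sums probabilities into the length distribution", {
  g <- as_genomes(c(g1 = "GAATTCAAGAATTCAAGAATTCTT"))  # EcoRI cuts 1,9,17
  d1 <- digestGenome(g, ECO, digestionParams(cut_efficiency = 1,
                                             length_min = 1, length_max = 100))
  expect_equal(d1$dist$g1, lengthDistribution(8L, 2))

  d2 <- digestGenome(g, ECO, digestionParams(cut_efficiency = 0.8,
                                             length_min = 1, length_max = 100))
  expect_equal(d2$dist$g1, lengthDistribution(c(8L, 16L), c(1.28, 0.128)))

  g0 <- as_genomes(c(g1 = strrep("A", 50)))
  d0 <- digestGenome(g0, ECO)
  expect_equal(length(d0$dist$g1), 0L)
})

test_that("scan and enumeration agree with the brute-force oracle", {
  set.seed(42)
  for (k in 1:12) {
    s <- random_genome_string(sample(500:3000, 1))
    g <- as_genomes(setNames(s, "g1"))
    for (m in list(ECO, MSE, HHA)) {
      got <- findCutSites(g, m)$position
      want <- oracle_cut_positions(s, m@recognition, m@cutOffset)
      expect_identical(got, as.integer(want))
    }
    sites <- communityCutSites(g, list(ECO, MSE))
    c_eff <- sample(c(0.5, 0.8, 1), 1)
    params <- digestionParams(cut_efficiency = c_eff, length_min = 40,
                              length_max = 600, max_internal = 3)
    f <- enumerateFragments(sites, params)
    ora <- oracle_fragments(sites$position, 40, 600, 3, c_eff)
    expect_equal(nrow(f), nrow(ora))
    if (nrow(f)) {
      o <- order(f$start, f$end)
      expect_equal(f$start[o], ora$start)
      expect_equal(f$end[o], ora$end)
      expect_equal(f$i[o], ora$i)
      expect_equal(f$p[o], ora$p)
    }
  }
})

test_that("complete-digest fragments tile the cut span", {
  set.seed(9)
  s <- random_genome_string(4000)
  g <- as_genomes(c(g1 = s))
  sites <- communityCutSites(g, list(MSE))
  params <- digestionParams(cut_efficiency = 1, length_min = 1,
                            length_max = nchar(s))
  f <- enumerateFragments(sites, params)
  f0 <- f[f$i == 0, ]
  f0 <- f0[order(f0$start), ]
  pos <- sort(unique(sites$position))
  expect_equal(f0$start, pos[-length(pos)])
  expect_equal(f0$end, pos[-1])
  expect_equal(sum(f0$length), max(pos) - min(pos))
})

test_that("palindromic digestion is strand-symmetric", {
  set.seed(13)
  s <- random_genome_string(30000)
  L <- nchar(s)
  g_f <- as_genomes(c(g1 = s))
  g_r <- as_genomes(c(g1 = revComp(s)))
  for (m in list(ECO, HHA)) {
    pf <- findCutSites(g_f, m)$position
    pr <- findCutSites(g_r, m)$position
    expect_gt(length(pf), 0L)
    # a cut at offset o of a width-w site mirrors to L - pos + 2o - w
    shift <- 2L * m@cutOffset - nchar(m@recognition)
    expect_equal(sort(L - pf + shift), pr)
  }
})
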