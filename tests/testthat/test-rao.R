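test_that("Rao alpha matches hand computations", {
  sp <- c("a", "b", "c", "d")
  Dtd <- taxonomicDistance(sp)
  expect_equal(raoAlpha(siteRow(sp, sp), Dtd), 1 - 1 / 4)
  expect_equal(raoAlpha(siteRow(c("a", "b"), sp), Dtd), 0.5)

  # 3 species, d12=1, d13=2, d23=3: alpha = 2(1+2+3)/9
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 1
  d["a", "c"] <- d["c", "a"] <- 2
  d["b", "c"] <- d["c", "b"] <- 3
  Df <- new("FacetDist", distances = d / 3, facet = "functional")
  expect_equal(raoAlpha(siteRow(letters[1:3], letters[1:3]), Df), (4 / 3) / 3)

  zero <- new("FacetDist",
              distances = matrix(0, 2, 2,
                                 dimnames = list(c("a", "b"), c("a", "b"))),
              facet = "functional")
  expect_equal(raoAlpha(siteRow(c("a", "b"), c("a", "b")), zero), 0)
  expect_error(raoAlpha(siteRow("a", sp), Dtd), "fewer than 2")
})

test_that("the Jost correction maps raw Rao to equivalent numbers", {
  expect_equal(jostCorrect(0), 1)
  expect_equal(jostCorrect(0.5), 2)
  expect_equal(jostCorrect(1 - 1 / 7), 7)
  expect_error(jostCorrect(1), "domain")
  x <- seq(0, 0.95, by = 0.05)
  expect_true(all(diff(jostCorrect(x)) > 0))
})

test_that("pairwise beta reproduces the fixed toy conventions", {
  sp <- c("A", "B", "C", "D", "E", "F")
  Dtd <- taxonomicDistance(sp)

  same <- raoBetaPairwise(siteRow(c("A", "B"), sp), siteRow(c("A", "B"), sp),
                          Dtd)
  expect_equal(same$beta, 0)

  # disjoint, equal richness S: gamma_eq = 2S, mean alpha_eq = S, beta = 1/2
  dis <- raoBetaPairwise(siteRow(c("A", "B", "C"), sp),
                         siteRow(c("D", "E", "F"), sp), Dtd)
  expect_equal(dis$gammaEq, 6)
  expect_equal(dis$meanAlphaEq, 3)
  expect_equal(dis$beta, 0.5)

  # {A,B} vs {B,C}: gamma weights (1/4, 1/2, 1/4), raw gamma 5/8,
  # gamma_eq 8/3, mean alpha_eq 2, beta 1/4
  ov <- raoBetaPairwise(siteRow(c("A", "B"), sp), siteRow(c("B", "C"), sp),
                        Dtd)
  expect_equal(ov$gammaRaw, 5 / 8)
  expect_equal(ov$gammaEq, 8 / 3)
  expect_equal(ov$meanAlphaEq, 2)
  expect_equal(ov$beta, 1 / 4)
})

test_that("diversity profiles assemble alphas and betas coherently", {
  ds <- smallDataset()
  Dtd <- taxonomicDistance(colnames(ds$comm))
  prof <- diversityProfile(ds$comm, Dtd)

  # TD identity: corrected alpha is site richness, exactly
  expect_equal(alphaDiversity(prof), rowSums(ds$comm), tolerance = 1e-12,
               ignore_attr = FALSE)

  beta <- betaDiversity(prof)
  n <- nrow(ds$comm)
  expect_equal(sum(lower.tri(beta)), n * (n - 1) / 2)
  expect_equal(beta, t(beta))

  # profile entries match the pairwise routine
  for (pair in list(c(1, 2), c(3, 9), c(5, 17))) {
    direct <- raoBetaPairwise(ds$comm[pair[1], ], ds$comm[pair[2], ], Dtd)
    expect_equal(beta[pair[1], pair[2]], direct$beta, tolerance = 1e-12)
  }

  # equivariance under site permutation
  perm <- sample(n)
  prof2 <- diversityProfile(ds$comm[perm, ], Dtd)
  expect_equal(alphaDiversity(prof2), alphaDiversity(prof)[perm])
  expect_equal(betaDiversity(prof2), beta[perm, perm])

  # single-species sites are rejected by name
  bad <- ds$comm
  bad[3, ] <- 0L; bad[3, 1] <- 1L
  expect_error(diversityProfile(bad, Dtd), rownames(ds$comm)[3])
})

test_that("adding a maximally distant species never lowers alpha", {
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    sp <- paste0("s", seq_len(n + 1))
    d <- matrix(runif(n^2, 0, 0.8), n, n)
    d <- (d + t(d)) / 2; diag(d) <- 0
    dmax <- max(d) + runif(1, 0, 0.2)
    D <- rbind(cbind(d, dmax), dmax)
    diag(D) <- 0
    dimnames(D) <- list(sp, sp)
    Df <- new("FacetDist", distances = D / max(D), facet = "functional")
    before <- raoAlpha(siteRow(sp[1:n], sp), Df)
    after <- raoAlpha(siteRow(sp, sp), Df)
    expect_gte(after, before - 1e-12)
  }
})

test_that("profiles are invariant to positive rescaling of the distances", {
  ds <- smallDataset()
  tr <- ds$tree
  Dpd <- copheneticDistances(tr)
  scaled <- new("FacetDist", distances = distMatrix(Dpd) * 7.3,
                facet = "phylogenetic")
  p1 <- diversityProfile(ds$comm, Dpd)
  p2 <- diversityProfile(ds$comm, scaled)
  expect_equal(alphaDiversity(p1), alphaDiversity(p2), tolerance = 1e-10)
  expect_equal(betaDiversity(p1), betaDiversity(p2), tolerance = 1e-10)

  # facet ordering: with distances rescaled to max 1, 0/1 taxonomic
  # distances dominate elementwise, so TD alpha bounds the other facets
  Dfd <- functionalDistance(pcaReduce(standardizeColumns(
    encodeTraits(ds$traits, defaultCodingMap(ds$traits))), 1.0))
  aTD <- diversityProfile(ds$comm, taxonomicDistance(colnames(ds$comm)))
  aFD <- diversityProfile(ds$comm, Dfd)
  aPD <- diversityProfile(ds$comm, Dpd)
  expect_true(all(alphaDiversity(aFD, corrected = FALSE) <=
                  alphaDiversity(aTD, corrected = FALSE) + 1e-12))
  expect_true(all(alphaDiversity(aPD, corrected = FALSE) <=
                  alphaDiversity(aTD, corrected = FALSE) + 1e-12))
})
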