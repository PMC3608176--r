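test_that("the standard eight-pipeline assignment covers the bundle as specified", {
  asg <- assignPipelines(stdTopology, 8)
  expect_length(asg, 8L)
  expect_identical(asg[[1]]$helices, 1L)
  expect_identical(asg[[8]]$helices, 7L)
  for (k in 2:7) expect_identical(asg[[k]]$helices, c(k - 1L, k))
  # TM1 appears in pipelines 1 and 2 only
  covers <- vapply(asg, function(a) 1L %in% a$helices, logical(1))
  expect_identical(which(covers), c(1L, 2L))
  # the union of assigned loops is every loop region
  expect_setequal(unlist(lapply(asg, `[[`, "loops")),
                  seq_len(nrow(loopRanges(stdTopology))))
  # termini go to the first and last pipelines
  lp <- loopRanges(stdTopology)
  expect_true(lp[asg[[1]]$loops, 1] == 1L)
  expect_true(lp[asg[[8]]$loops, 2] == stdTopology@n)
})

test_that("non-standard pipeline counts still cover all loops with adjacent windows", {
  for (np in c(2, 4, 6, 11)) {
    asg <- assignPipelines(stdTopology, np)
    expect_length(asg, np)
    expect_setequal(unlist(lapply(asg, `[[`, "loops")),
                    seq_len(nrow(loopRanges(stdTopology))))
    for (a in asg) {
      expect_gte(length(a$helices), 1L)
      expect_lte(length(a$helices), 2L)
      if (length(a$helices) == 2L) expect_equal(diff(a$helices), 1L)
    }
  }
  expect_error(assignPipelines(stdTopology, 1), "at least 2")
})

test_that("start selection uses templates first, then the pool, uniformly", {
  t1 <- stdBundle$structure
  t2 <- translateHelix(t1, tmRanges(stdTopology)[1, ], c(1, 0, 0))
  t3 <- translateHelix(t1, tmRanges(stdTopology)[1, ], c(0, 1, 0))
  templates <- list(t1, t2, t3)
  pool <- ElitePool(4)
  expect_error(selectStart(pool, list(), randomStream(1)), "empty")

  # single template, empty pool
  expect_identical(selectStart(pool, list(t2), randomStream(1))@coords,
                   t2@coords)
  # deterministic under the seed
  a <- selectStart(pool, templates, randomStream(3))
  b <- selectStart(pool, templates, randomStream(3))
  expect_identical(a@coords, b@coords)

  # roughly uniform over templates (multinomial three-sigma check)
  rng <- randomStream(10)
  picks <- replicate(3000, {
    s <- selectStart(pool, templates, rng, iteration = 1)
    which(vapply(templates, function(t) identical(t@coords, s@coords),
                 logical(1)))
  })
  expect_lt(max(abs(table(picks) / 3000 - 1 / 3)),
            3 * sqrt((1 / 3) * (2 / 3) / 3000))

  # later iterations draw from a non-empty pool
  pool <- updateElitePool(pool, list(list(structure = t2, energy = 1)))
  s <- selectStart(pool, templates, randomStream(2), iteration = 2)
  expect_identical(s@coords, t2@coords)
})

test_that("the elite pool is bounded, sorted, elitist and tie-stable", {
  pool <- ElitePool(5)
  cands <- lapply(1:10, function(k)
    list(structure = stdBundle$structure, energy = 11 - k,
         provenance = sprintf("c%d", k)))
  pool <- updateElitePool(pool, cands)
  expect_length(pool@entries, 5L)
  expect_equal(vapply(pool@entries, `[[`, numeric(1), "energy"), 1:5)

  # a worse-than-all candidate leaves a full pool unchanged
  before <- pool
  pool <- updateElitePool(pool, list(list(structure = stdBundle$structure,
                                          energy = 99)))
  expect_identical(vapply(pool@entries, `[[`, character(1), "provenance"),
                   vapply(before@entries, `[[`, character(1), "provenance"))

  # ties broken by insertion order
  pool2 <- updateElitePool(ElitePool(1),
                           list(list(structure = stdBundle$structure,
                                     energy = 1, provenance = "first"),
                                list(structure = stdBundle$structure,
                                     energy = 1, provenance = "second")))
  expect_identical(pool2@entries[[1]]$provenance, "first")

  # non-finite energies are never admitted
  pool3 <- updateElitePool(ElitePool(3),
                           list(list(structure = stdBundle$structure,
                                     energy = NaN)))
  expect_length(pool3@entries, 0L)

  # pool minimum is non-increasing across updates
  e <- Inf
  pool4 <- ElitePool(3)
  for (k in c(5, 9, 3, 7, 2)) {
    pool4 <- updateElitePool(pool4, list(list(structure = stdBundle$structure,
                                              energy = k)))
    expect_lte(poolBestEnergy(pool4), e)
    e <- poolBestEnergy(pool4)
  }
})

test_that("helix crossing substitutes only on strict energy decrease", {
  asg <- assignPipelines(stdTopology, 8)
  good <- stdBundle$structure
  mkState <- function(s) TMRefine:::newPipelineState(s, evalEnergy(s, stdCtx))

  # all pipelines identical: nothing to gain, nothing changes
  states <- lapply(1:8, function(i) mkState(good))
  out <- crossHelices(states, asg, stdCtx)
  for (i in 1:8)
    expect_identical(out[[i]]@best@coords, good@coords)

  # recipient with a displaced TM3; a donor holds the clean version
  bad <- translateHelix(good, tmRanges(stdTopology)[3, ], c(4, 2, 1))
  states <- lapply(1:8, function(i) mkState(if (i == 4) bad else good))
  expect_gt(states[[4]]@bestEnergy@total, 0)
  out <- crossHelices(states, asg, stdCtx)
  expect_lt(out[[4]]@bestEnergy@total, states[[4]]@bestEnergy@total)
  # the graft restored TM3 from a donor
  rg <- tmRanges(stdTopology)[3, ]
  expect_identical(out[[4]]@best@coords[TMRefine:::atomRows(rg[1]:rg[2]), ],
                   good@coords[TMRefine:::atomRows(rg[1]:rg[2]), ])
  # non-helix residues unchanged except the re-closed junction loops
  lp <- loopRanges(stdTopology)
  junctionLoops <- TMRefine:::adjacentLoopRows(stdTopology, 3L)
  untouched <- setdiff(seq_len(nResidues(good)),
                       c(rg[1]:rg[2],
                         unlist(lapply(junctionLoops, function(k)
                           lp[k, 1]:lp[k, 2]))))
  expect_identical(out[[4]]@best@coords[TMRefine:::atomRows(untouched), ],
                   bad@coords[TMRefine:::atomRows(untouched), ])
})

test_that("a zero-iteration run scores and returns the templates", {
  t1 <- stdBundle$structure
  t2 <- perturbBundle(stdBundle, 1, 10, 3, randomStream(5))$structure
  fw <- FrameworkConfig(nTemplates = 2, iterations = 0, masterSeed = 1)
  run <- runBundleRefinement(list(t1, t2), stdTopology, stdFrame, fw)
  expect_identical(run@best@coords, t1@coords)   # the ideal bundle scores 0
  expect_length(run@decoys, 2L)
  expect_equal(run@bestEnergy@total, 0)
})

test_that("template/topology mismatches fail before any work", {
  short <- BackboneStructure(stdBundle$structure@coords[1:400, ])
  fw <- FrameworkConfig(nTemplates = 1, iterations = 1, masterSeed = 1)
  expect_error(runBundleRefinement(list(short), stdTopology, stdFrame, fw),
               "match the topology length")
  expect_error(runBundleRefinement(list(stdBundle$structure,
                                        stdBundle$structure),
                                   stdTopology, stdFrame, fw),
               "nTemplates")
})

test_that("framework runs are reproducible and elitist across iterations", {
  tpl <- makeComplementaryTemplates(stdBundle, rng = randomStream(88))
  fw <- FrameworkConfig(nTemplates = 2, iterations = 2, masterSeed = 7)
  run1 <- runBundleRefinement(tpl, stdTopology, stdFrame, fw,
                              cyclesPerStage = 3)
  run2 <- runBundleRefinement(tpl, stdTopology, stdFrame, fw,
                              cyclesPerStage = 3)
  expect_identical(run1@best@coords, run2@best@coords)
  expect_identical(run1@log, run2@log)
  # the pool keeps only improved candidates, sorted
  energies <- vapply(run1@pool@entries, `[[`, numeric(1), "energy")
  expect_true(all(diff(energies) >= 0))
})
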