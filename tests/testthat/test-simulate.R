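test_that("simulation is deterministic and honours the design counts", {
  cfg <- simulationConfig(nGenes = 300, propReproducible = 0.8, seed = 5)
  a <- simulateStudies(cfg)
  b <- simulateStudies(cfg)
  expect_identical(SummarizedExperiment::assay(a$study1, "exprs"),
                   SummarizedExperiment::assay(b$study1, "exprs"))
  expect_identical(a$truth, b$truth)
  expect_equal(sum(a$truth$differential), round(300 * 0.8))
  expect_equal(sum(a$truth$direction == "up"), round(300 * 0.8 * 0.5))
  expect_equal(studyGroups(a$study1), rep(c(1L, 2L), each = 10L))

  big <- simulationConfig(propReproducible = 0.8)
  expect_equal(round(big@nGenes * big@propReproducible), 4000)
})

test_that("null genes produce t-distributed statistics", {
  cfg <- simulationConfig(nGenes = 5000, propReproducible = 0, seed = 19)
  sim <- simulateStudies(cfg)
  expect_true(all(!sim$truth$differential))
  d <- tStatistics(sim$study1)
  ks <- ks.test(d, function(q) pt(q, df = 18))
  expect_gt(ks$p.value, 0.001)
})

test_that("differential genes have group differences near the target effect", {
  cfg <- simulationConfig(nGenes = 4000, propReproducible = 1, seed = 23)
  sim <- simulateStudies(cfg)
  x <- SummarizedExperiment::assay(sim$study1, "exprs")
  grp <- studyGroups(sim$study1)
  diff <- rowMeans(x[, grp == 2L]) - rowMeans(x[, grp == 1L])
  up <- sim$truth$direction == "up"
  expect_equal(mean(diff[up]), 2, tolerance = 0.06)
  expect_equal(mean(diff[!up]), -2, tolerance = 0.06)
})

test_that("evaluation implements the confusion-table arithmetic", {
  truth <- data.frame(gene_id = sprintf("g%02d", 1:10),
                      differential = rep(c(TRUE, FALSE), c(2, 8)),
                      direction = c("up", "down", rep("none", 8)))
  perfect <- data.frame(gene_id = truth$gene_id,
                        call = truth$differential,
                        direction = truth$direction)
  ev <- evaluateCalls(perfect, truth)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$misclassification, 0)
  expect_equal(ev$direction_accuracy, 1)

  allNull <- transform(perfect, call = FALSE, direction = "none")
  ev <- evaluateCalls(allNull, truth)
  expect_equal(ev$sensitivity, 0)
  expect_equal(ev$specificity, 1)
  expect_equal(ev$misclassification, 0.2)

  # arbitrary confusion table against hand arithmetic
  calls <- transform(perfect,
                     call = c(TRUE, FALSE, TRUE, TRUE, rep(FALSE, 6)))
  ev <- evaluateCalls(calls, truth)
  expect_equal(ev$sensitivity, 1 / 2)
  expect_equal(ev$specificity, 6 / 8)
  expect_equal(ev$misclassification, (2 + 1) / 10)

  expect_error(evaluateCalls(transform(perfect, gene_id = paste0(gene_id, "x")),
                             truth), "same gene set")
})

test_that("pure-null evaluation reports sensitivity as missing", {
  truth <- data.frame(gene_id = c("a", "b"), differential = c(FALSE, FALSE),
                      direction = "none")
  calls <- data.frame(gene_id = c("a", "b"), call = c(TRUE, FALSE),
                      direction = c("up", "none"))
  ev <- evaluateCalls(calls, truth)
  expect_true(is.na(ev$sensitivity))
  expect_equal(1 - ev$specificity, 0.5)  # empirical false-call rate
})

test_that("simulation configurations load from YAML with defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("nGenes: 120", "propReproducible: 0.25", "seed: 9"), f)
  cfg <- readSimulationConfig(f)
  expect_equal(cfg@nGenes, 120L)
  expect_equal(cfg@propReproducible, 0.25)
  expect_equal(cfg@seed, 9L)
  expect_equal(cfg@muGamma, 2)  # untouched default
  writeLines("nonsense: 1", f)
  expect_error(readSimulationConfig(f), "unknown configuration key")
})

test_that("the replicate harness is deterministic and summarises both methods", {
  cfg <- simulationConfig(nGenes = 300, propReproducible = 0.5)
  r1 <- suppressMessages(suppressWarnings(
    runSimulationStudy(cfg, alpha = 0.1, nReps = 2, seed = 7,
                       em = emControl(nStarts = 3))))
  r2 <- suppressMessages(suppressWarnings(
    runSimulationStudy(cfg, alpha = 0.1, nReps = 2, seed = 7,
                       em = emControl(nStarts = 3))))
  expect_identical(r1$perRep, r2$perRep)
  expect_setequal(unique(r1$summary$method), c("proposed", "bh"))
  expect_true(all(is.finite(r1$summary$se)))

  one <- suppressMessages(suppressWarnings(
    runSimulationStudy(cfg, alpha = 0.1, nReps = 1, seed = 7,
                       methods = "bh")))
  expect_true(all(is.na(one$summary$se)))
})
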