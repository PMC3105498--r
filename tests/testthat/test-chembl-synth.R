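test_that("the generator is deterministic in its seed", {
  cfg <- chemblSynthConfig(seed = 21L, nMolecules = 15L,
                           activitiesPerTarget = 5L,
                           nIonChannelTargets = 2L)
  a <- serializeRDF(generateChemblStore(cfg)$store)
  b <- serializeRDF(generateChemblStore(cfg)$store)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 22L
  expect_false(identical(a, serializeRDF(generateChemblStore(cfg2)$store)))
})

test_that("an empty molecule set yields an empty extraction", {
  gen <- generateChemblStore(chemblSynthConfig(seed = 3L, nMolecules = 0L,
                                               nIonChannelTargets = 1L))
  expect_equal(nrow(extractQsarDataset(gen$store)), 0L)
})

test_that("extraction row counts follow the configuration", {
  gen <- sharedChemblGen()
  ds <- extractQsarDataset(gen$store, 10885L)
  expect_equal(nrow(ds), gen$groundTruth$config$activitiesPerTarget)
  expect_equal(names(ds), c("act", "ass", "mol", "smiles", "val", "unit",
                            "conf"))
  expect_false(any(is.na(ds)))
})

test_that("SPARQL extraction equals the brute-force record scan", {
  gen <- sharedChemblGen()
  gt <- gen$groundTruth
  # QSAR: IC50 rows of the kinase target, joined by hand over the tables
  ds <- extractQsarDataset(gen$store, 10885L)
  acts <- gt$activities[gt$activities$target == 10885L &
                          gt$activities$type == "IC50", ]
  conf <- gt$assays$confidence[match(acts$assay, gt$assays$id)]
  smiles <- gt$molecules$smiles[match(acts$molecule, gt$molecules$id)]
  oracle <- data.frame(
    act = paste0("http://example.org/chembl/activity/", acts$id),
    smiles = smiles, val = acts$value, unit = acts$unit, conf = conf,
    stringsAsFactors = FALSE)
  keyMine <- sort(paste(ds$act, ds$smiles, ds$val, ds$unit, ds$conf))
  keyOracle <- sort(paste(oracle$act, oracle$smiles, oracle$val,
                          oracle$unit, oracle$conf))
  expect_identical(keyMine, keyOracle)

  # PCM: Ki/IC50 rows of matching level-6 targets
  pcm <- extractPcmDataset(gen$store, "Sodium channel")
  tgt <- gt$targets[grepl("Sodium channel", gt$targets$l6), ]
  acts2 <- gt$activities[gt$activities$target %in% tgt$id &
                           gt$activities$type %in% c("Ki", "IC50"), ]
  expect_equal(nrow(pcm), nrow(acts2))
  smiles2 <- gt$molecules$smiles[match(acts2$molecule, gt$molecules$id)]
  expect_identical(sort(paste(pcm$smiles, pcm$val, pcm$type)),
                   sort(paste(smiles2, acts2$value, acts2$type)))
  expect_true(all(pcm$l6 == "Sodium channel alpha subunit"))
  expect_true(all(pcm$type %in% c("Ki", "IC50")))
  expect_equal(names(pcm), c("target", "type", "pubmed", "l4", "l5", "l6",
                             "smiles", "val", "seq"))
  # filter matching nothing
  expect_equal(nrow(extractPcmDataset(gen$store, "no such channel")), 0L)
})

test_that("unknown targets warn and return an empty dataset", {
  gen <- sharedChemblGen()
  expect_warning(ds <- extractQsarDataset(gen$store, 999999L),
                 "not present")
  expect_equal(nrow(ds), 0L)
})

test_that("activity types list matches a DISTINCT query and the wizard set", {
  gen <- sharedChemblGen()
  types <- listActivityTypes(gen$store, 101107L)
  expect_equal(types, sort(c("IC50", "Inhibition", "Ki app", "Ki",
                             "Activity")))
  # no-activity target
  expect_equal(listActivityTypes(gen$store, 999999L), character(0))
  # equals the direct DISTINCT-type query over the ground-truth table
  gt <- gen$groundTruth
  expect_equal(types,
               sort(unique(gt$activities$type[gt$activities$target ==
                                                101107L])))
})

test_that("qsarMatrix standardizes, weighs and converts units", {
  gen <- sharedChemblGen()
  mm <- qsarMatrix(extractQsarDataset(gen$store, 10885L))
  expect_lt(abs(mean(mm$y)), 1e-10)
  expect_lt(abs(stats::var(mm$y) - 1), 1e-10)
  expect_lt(max(abs(colMeans(mm$X))), 1e-10)
  expect_lt(max(abs(apply(mm$X, 2, stats::sd) - 1)), 1e-10)
  expect_equal(mean(mm$w), 1)

  # hand-built dataset: 1000 nM is -log10(1e-6 M) = 6 before centering
  ds <- data.frame(act = c("a1", "a2"), ass = c("s1", "s2"),
                   mol = c("m1", "m2"), smiles = c("CCO", "CCCCO"),
                   val = c(1000, 10), unit = c("nM", "nM"),
                   conf = c(4, 4), stringsAsFactors = FALSE)
  # two molecules leave some descriptors constant: dropped with a warning
  expect_warning(mm2 <- qsarMatrix(ds), "constant descriptor")
  expect_equal(unname(mm2$y * mm2$yScale + mm2$yCenter), c(6, 8))
  expect_equal(mm2$w, c(1, 1))  # equal confidences give unit weights
  # 1000 nM and 1 uM are the same measurement
  ds3 <- ds; ds3$val[1] <- 1; ds3$unit[1] <- "uM"
  expect_equal(suppressWarnings(qsarMatrix(ds3))$y, mm2$y)
  dsBad <- ds; dsBad$unit[1] <- "mM"
  expect_error(qsarMatrix(dsBad), "unknown unit")
  dsFlat <- ds; dsFlat$val <- c(10, 10)
  expect_error(suppressWarnings(qsarMatrix(dsFlat)), "zero-variance")
})

test_that("generated noise follows the configured confidence map", {
  sim <- simulateWeightedRegression(2000, 4, beta = c(1, -1, 0.5, 0),
                                    noiseBaseSd = 0.8, seed = 31L)
  # residuals against the true (rescaled) coefficients, per stratum
  resid <- sim$y - drop(sim$X %*% sim$beta)
  for (lev in unique(sim$confidence)) {
    i <- sim$confidence == lev
    expect_lt(abs(stats::sd(resid[i]) / sim$noiseSd[i][1] - 1), 0.15)
  }
})

test_that("QSAR datasets export to SD files with activity properties", {
  gen <- sharedChemblGen()
  ds <- extractQsarDataset(gen$store, 10885L)[1:5, ]
  path <- withr::local_tempfile(fileext = ".sdf")
  qsarDatasetToSDF(ds, path)
  lines <- readLines(path)
  expect_equal(sum(lines == "$$$$"), 5L)
  expect_true(any(lines == "> <activity>"))
})
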