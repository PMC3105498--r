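# Seeded synthetic generator of a ChEMBL-shaped RDF store: targets with a
# seven-level classification and protein sequences, assays with confidence
# scores, activities (IC50/Ki/...) with values and units, and molecules
# with SMILES. Activities on the designated QSAR target carry a planted
# structure-activity signal through the registry descriptors, with noise
# whose standard deviation falls with assay confidence; ion-channel targets
# carry a planted bilinear ligand-protein signal for the proteochemometric
# pipeline. The generator returns the ground truth next to the store so
# recovery tests can close the loop.

CHEMBL_RES <- "http://example.org/chembl/"

AMINO_ACIDS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Configuration for the synthetic ChEMBL-like store
#'
#' @param seed integer seed fixing every random draw.
#' @param nMolecules number of distinct molecules minted.
#' @param nIonChannelTargets ion-channel (PCM) targets; the first 8 are
#'   sodium-channel alpha subunits and the rest calcium-channel alpha-1
#'   subunits by level-6 classification (the default 18 distinct proteins
#'   support exactly 17 protein principal components).
#' @param activitiesPerTarget activities generated per target.
#' @param qsarTargetId integer id of the kinase-style QSAR target whose
#'   IC50 activities carry the descriptor-based signal (default 10885,
#'   the running example id).
#' @param wizardTargetId target that receives a few activities of every
#'   type (IC50, Ki, "Ki app", Inhibition, Activity).
#' @param betaTrue planted coefficients on the 5 standardized registry
#'   descriptors (heavyAtomCount, bondCount, ringCount, molecularWeight,
#'   tpsa).
#' @param confidenceLevels assay confidence scores sampled uniformly;
#'   ChEMBL-style small integers.
#' @param noiseBaseSd base noise SD on the -log10 molar scale; an assay at
#'   confidence c draws noise with SD \code{noiseBaseSd / sqrt(c)}, so
#'   confidence-proportional weights are inverse-variance weights.
#' @param pcmNoiseSd noise SD for the bilinear PCM signal (on the unit-
#'   variance signal scale).
#' @param seqLength length of the (pre-aligned) target protein sequences.
#' @return a list of class \code{chemblSynthConfig}.
#' @export
chemblSynthConfig <- function(seed = 1L, nMolecules = 60L,
                              nIonChannelTargets = 18L,
                              activitiesPerTarget = 40L,
                              qsarTargetId = 10885L,
                              wizardTargetId = 101107L,
                              betaTrue = c(0.8, -0.5, 0.4, 0.6, -0.3),
                              confidenceLevels = c(1L, 3L, 9L),
                              noiseBaseSd = 0.6,
                              pcmNoiseSd = 0.2,
                              seqLength = 60L) {
  stopifnot(nMolecules >= 0, nIonChannelTargets >= 0,
            activitiesPerTarget >= 0, length(betaTrue) == 5L,
            all(confidenceLevels > 0), noiseBaseSd >= 0, pcmNoiseSd >= 0)
  structure(as.list(environment()), class = "chemblSynthConfig")
}

qsarDescriptorIds <- function()
  c("heavyAtomCount", "bondCount", "ringCount", "molecularWeight", "tpsa")

#' Random SMILES from the generator's grammar
#'
#' Draws small drug-like structures (alkyl chains, benzene/pyridine rings,
#' saturated carbo-/heterocycles, polar substituents) restricted to
#' chemistry whose implicit-hydrogen and TPSA treatment is standard across
#' toolkits. Uses the current RNG state.
#'
#' @param n how many SMILES.
#' @return character vector of SMILES strings.
#' @export
randomSmiles <- function(n) {
  subs <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "OCC", "N", "NC", "N(C)C",
            "C#N", "C(=O)O", "C(=O)N", "C(=O)C", "CO", "CN", "Cl", "F")
  one <- function() {
    kind <- sample(c("chain", "benzene", "pyridine", "cyclohexane",
                     "thf", "pyrrolidine"), 1L,
                   prob = c(0.3, 0.25, 0.1, 0.15, 0.1, 0.1))
    nsub <- sample(0:2, 1L, prob = c(0.25, 0.5, 0.25))
    ss <- sample(subs, max(nsub, 1L), replace = TRUE)
    branch <- function(k) if (k <= nsub) paste0("(", ss[k], ")") else ""
    switch(kind,
      chain = {
        len <- sample(3:6, 1L)
        core <- strsplit(paste(rep("C", len), collapse = ""), "")[[1]]
        out <- core[1]
        for (i in 2:len) {
          # branches only on interior carbons, at most one each
          out <- paste0(out, if (i <= len - 1L && i - 1L <= nsub)
            branch(i - 1L) else "", core[i])
        }
        out
      },
      benzene = if (nsub == 0L) "c1ccccc1"
                else if (nsub == 1L) paste0("c1ccc(", ss[1], ")cc1")
                else paste0("c1cc(", ss[1], ")ccc1", ss[2]),
      pyridine = if (nsub == 0L) "c1ccncc1"
                 else paste0("c1ccnc(", ss[1], ")c1"),
      cyclohexane = if (nsub == 0L) "C1CCCCC1"
                    else paste0("C1CCC", branch(1), if (nsub == 2L)
                      paste0("C", branch(2)) else "C", "C1"),
      thf = if (nsub == 0L) "C1CCOC1" else paste0("C1CC(", ss[1], ")OC1"),
      pyrrolidine = if (nsub == 0L) "C1CCNC1"
                    else paste0("C1CC(", ss[1], ")NC1"))
  }
  vapply(seq_len(n), function(i) one(), character(1))
}

randomSequence <- function(length, gapRate = 0.02) {
  s <- sample(AMINO_ACIDS, length, replace = TRUE)
  gaps <- stats::runif(length) < gapRate
  s[gaps] <- "-"
  paste(s, collapse = "")
}

targetIRI <- function(id) iri(paste0(CHEMBL_RES, "target/", id))

#' Generate the synthetic ChEMBL-like RDF store
#'
#' @param config a \code{\link{chemblSynthConfig}}.
#' @return list with \code{store} (a \code{TripleStore} that answers the
#'   shipped extraction queries), and \code{groundTruth}: the planted
#'   descriptor coefficients, the confidence-to-noise-SD map, the PCM
#'   coefficient blocks, and the full record tables (targets, molecules,
#'   assays, activities) that back the brute-force extraction oracle.
#' @export
generateChemblStore <- function(config = chemblSynthConfig()) {
  stopifnot(inherits(config, "chemblSynthConfig"))
  set.seed(config$seed)

  # --- record tables -------------------------------------------------------
  nIon <- config$nIonChannelTargets
  ionIds <- if (nIon) 200L + seq_len(nIon) else integer(0)
  ionL6 <- if (nIon) ifelse(seq_len(nIon) <= min(8L, nIon),
                            "Sodium channel alpha subunit",
                            "Calcium channel alpha-1 subunit")
           else character(0)
  targets <- data.frame(
    id = c(config$qsarTargetId, config$wizardTargetId, ionIds),
    title = c("serine/threonine-protein kinase (synthetic)",
              "sialidase (synthetic)",
              if (nIon) paste0(ifelse(grepl("Sodium", ionL6), "sodium",
                                      "calcium"),
                               " channel subunit alpha (synthetic) ", ionIds)
              else character(0)),
    targetType = "SINGLE PROTEIN",
    organism = "Homo sapiens",
    l1 = "Protein", l2 = "Enzyme-or-channel", l3 = "Synthetic family",
    l4 = c("Kinase", "Hydrolase", rep("Voltage-gated ion channel", nIon)),
    l5 = c("Protein kinase", "Glycosidase",
           rep("Voltage-gated cation channel", nIon)),
    l6 = c("CAMK protein kinase", "Exo-alpha-sialidase", ionL6),
    l7 = "-",
    stringsAsFactors = FALSE)
  targets$sequence <- vapply(seq_len(nrow(targets)), function(i)
    randomSequence(config$seqLength), character(1))

  nm <- config$nMolecules
  molecules <- data.frame(id = seq_len(nm),
                          smiles = if (nm) randomSmiles(nm) else character(0),
                          stringsAsFactors = FALSE)

  # descriptor block for the planted signals (standardized over molecules)
  descStd <- NULL
  if (nm >= 2L) {
    desc <- descriptorMatrix(lapply(molecules$smiles, parseSmiles),
                             qsarDescriptorIds())$matrix
    descStd <- scale(desc)
    descStd[, attr(descStd, "scaled:scale") == 0] <- 0
  }

  assays <- data.frame(id = integer(0), target = integer(0),
                       confidence = integer(0))
  activities <- data.frame(id = integer(0), assay = integer(0),
                           molecule = integer(0), target = integer(0),
                           type = character(0), value = numeric(0),
                           unit = character(0), pubmed = integer(0),
                           stringsAsFactors = FALSE)
  nextAssay <- 1L; nextAct <- 1L
  addActivity <- function(targetId, type, molId, conf, y, unit) {
    # y is on the -log10 molar scale; value rendered in the given unit
    molar <- 10^(-y)
    value <- signif(molar / c(nM = 1e-9, uM = 1e-6)[[unit]], 6)
    assays <<- rbind(assays, data.frame(id = nextAssay, target = targetId,
                                        confidence = conf))
    activities <<- rbind(activities, data.frame(
      id = nextAct, assay = nextAssay, molecule = molId, target = targetId,
      type = type, value = value, unit = unit,
      pubmed = sample(10000000:29999999, 1L), stringsAsFactors = FALSE))
    nextAssay <<- nextAssay + 1L; nextAct <<- nextAct + 1L
  }

  noiseSd <- function(conf) config$noiseBaseSd / sqrt(conf)

  # QSAR target: IC50 with descriptor-based signal, mixed units
  if (nm >= 2L && config$activitiesPerTarget > 0L) {
    for (k in seq_len(config$activitiesPerTarget)) {
      molId <- sample(nm, 1L)
      conf <- sample(config$confidenceLevels, 1L)
      y <- 6 + sum(descStd[molId, ] * config$betaTrue) +
        stats::rnorm(1L, sd = noiseSd(conf))
      addActivity(config$qsarTargetId, "IC50", molId, conf, y,
                  if (stats::runif(1) < 0.3) "uM" else "nM")
    }
    # wizard target: a few activities of every type
    for (type in c("IC50", "Inhibition", "Ki app", "Ki", "Activity"))
      addActivity(config$wizardTargetId, type, sample(nm, 1L),
                  sample(config$confidenceLevels, 1L),
                  stats::rnorm(1L, 6, 1), "nM")
  }

  # PCM targets: Ki/IC50 with bilinear ligand x protein signal, nM units
  pcmCoefs <- NULL
  if (nm >= 2L && nIon > 0L && config$activitiesPerTarget > 0L) {
    zs <- zScaleTable()
    protZ <- t(vapply(targets$sequence[targets$id %in% ionIds], function(sq) {
      aa <- strsplit(sq, "")[[1]]
      aa <- aa[aa != "-"]
      colMeans(zs[aa, , drop = FALSE])
    }, numeric(3)))
    protZ <- scale(protZ)
    protZ[, attr(protZ, "scaled:scale") == 0] <- 0
    p <- ncol(descStd); q <- ncol(protZ)
    pcmCoefs <- list(ligand = stats::rnorm(p, 0, 0.5),
                     protein = stats::rnorm(q, 0, 0.5),
                     cross = matrix(stats::rnorm(p * q, 0, 0.4), p, q))
    signalOf <- function(molId, tIdx) {
      dl <- descStd[molId, ]; zp <- protZ[tIdx, ]
      sum(dl * pcmCoefs$ligand) + sum(zp * pcmCoefs$protein) +
        drop(dl %*% pcmCoefs$cross %*% zp)
    }
    # scale the planted signal to unit variance over a reference draw
    ref <- vapply(seq_len(200L), function(i)
      signalOf(sample(nm, 1L), sample(nIon, 1L)), numeric(1))
    sc <- stats::sd(ref); if (sc == 0) sc <- 1
    pcmCoefs$scale <- sc
    for (tIdx in seq_len(nIon)) {
      for (k in seq_len(config$activitiesPerTarget)) {
        molId <- sample(nm, 1L)
        y <- 6 + signalOf(molId, tIdx) / sc +
          stats::rnorm(1L, sd = config$pcmNoiseSd)
        addActivity(ionIds[tIdx], sample(c("Ki", "IC50"), 1L), molId,
                    sample(config$confidenceLevels, 1L), y, "nM")
      }
    }
  }

  # --- records to triples --------------------------------------------------
  s <- character(0); p <- character(0); o <- character(0)
  say <- function(su, pr, ob) {
    s[length(s) + 1L] <<- su; p[length(p) + 1L] <<- pr; o[length(o) + 1L] <<- ob
  }
  for (i in seq_len(nrow(targets))) {
    t <- targetIRI(targets$id[i])
    say(t, rdfTypeIRI(), chemblIRI("Target"))
    say(t, dcTitleIRI(), literal(targets$title[i]))
    say(t, chemblIRI("targetType"), literal(targets$targetType[i]))
    say(t, chemblIRI("organism"), literal(targets$organism[i]))
    for (lev in 1:7)
      say(t, chemblIRI(paste0("classL", lev)),
          literal(targets[[paste0("l", lev)]][i]))
    say(t, chemblIRI("sequence"), literal(targets$sequence[i]))
  }
  for (i in seq_len(nrow(molecules))) {
    m <- iri(paste0(CHEMBL_RES, "molecule/", molecules$id[i]))
    say(m, rdfTypeIRI(), chemblIRI("Molecule"))
    say(m, chemblIRI("smiles"), literal(molecules$smiles[i]))
  }
  for (i in seq_len(nrow(assays))) {
    a <- iri(paste0(CHEMBL_RES, "assay/", assays$id[i]))
    say(a, rdfTypeIRI(), chemblIRI("Assay"))
    say(a, chemblIRI("hasConfidence"), literal(as.integer(assays$confidence[i])))
    say(a, chemblIRI("forTarget"), targetIRI(assays$target[i]))
  }
  for (i in seq_len(nrow(activities))) {
    act <- iri(paste0(CHEMBL_RES, "activity/", activities$id[i]))
    say(act, rdfTypeIRI(), chemblIRI("Activity"))
    say(act, chemblIRI("type"), literal(activities$type[i]))
    say(act, chemblIRI("onAssay"),
        iri(paste0(CHEMBL_RES, "assay/", activities$assay[i])))
    say(act, chemblIRI("forMolecule"),
        iri(paste0(CHEMBL_RES, "molecule/", activities$molecule[i])))
    say(act, chemblIRI("standardValue"), decimalLiteral(activities$value[i]))
    say(act, chemblIRI("standardUnit"), literal(activities$unit[i]))
    say(act, chemblIRI("pubmedId"), literal(as.integer(activities$pubmed[i])))
  }
  store <- tripleStore(s, p, o, prefixes = chemrdfPrefixes())
  list(store = store,
       groundTruth = list(
         betaTrue = config$betaTrue,
         noiseSdByConfidence = stats::setNames(
           noiseSd(config$confidenceLevels),
           as.character(config$confidenceLevels)),
         pcmCoefs = pcmCoefs,
         targets = targets, molecules = molecules, assays = assays,
         activities = activities, config = config))
}

queryAsset <- function(name) {
  path <- system.file("extdata", "queries", name, package = "chemrdf")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "queries", name)  # pre-install use
  paste(readLines(path, warn = FALSE), collapse = "\n")
}

#' The shipped QSAR extraction query (seven projected variables)
#'
#' @param targetId integer target id substituted into the query.
#' @param activityType activity type string (default IC50).
#' @return SPARQL SELECT text projecting act, ass, mol, smiles, val, unit,
#'   conf.
#' @export
qsarQueryText <- function(targetId = 10885L, activityType = "IC50") {
  q <- queryAsset("qsar_ic50.rq")
  q <- gsub("{TARGET}", as.character(targetId), q, fixed = TRUE)
  gsub("{TYPE}", activityType, q, fixed = TRUE)
}

#' The shipped proteochemometric extraction query (nine projected
#' variables)
#'
#' @param level6Filter regular expression matched against the level-6
#'   target classification (e.g. "Sodium channel").
#' @return SPARQL SELECT text projecting target, type, pubmed, l4, l5, l6,
#'   smiles, val, seq; only Ki and IC50 activities pass its type filter.
#' @export
pcmQueryText <- function(level6Filter = "Sodium channel") {
  gsub("{L6}", level6Filter, queryAsset("pcm_channels.rq"), fixed = TRUE)
}

#' Extract a QSAR data set from a ChEMBL-like store
#'
#' Runs the shipped seven-variable extraction query through the package's
#' SPARQL engine.
#'
#' @param store the synthetic (or any vocabulary-compatible) store.
#' @param targetId integer target id.
#' @param activityType activity type (default IC50).
#' @return data.frame of class \code{qsarDataset} with exactly the columns
#'   act, ass, mol, smiles, val (numeric), unit, conf (numeric); zero rows
#'   (with a warning) when the target is unknown.
#' @export
extractQsarDataset <- function(store, targetId = 10885L,
                               activityType = "IC50") {
  known <- any(store@triples$subject == targetIRI(targetId) &
                 store@triples$predicate == rdfTypeIRI())
  if (!known)
    warning("target ", targetId, " not present in store; returning 0 rows")
  res <- query(store, qsarQueryText(targetId, activityType))
  df <- as.data.frame(res)
  df$val <- as.numeric(df$val)
  df$conf <- as.numeric(df$conf)
  rownames(df) <- NULL
  class(df) <- c("qsarDataset", "data.frame")
  df
}

#' Extract a proteochemometric data set from a ChEMBL-like store
#'
#' Runs the shipped nine-variable query: Ki/IC50 activities against
#' targets whose level-6 classification matches the filter.
#'
#' @param store the store.
#' @param level6Filter regular expression on the level-6 classification.
#' @return data.frame of class \code{pcmDataset} with exactly the columns
#'   target, type, pubmed, l4, l5, l6, smiles, val (numeric, nM), seq.
#' @export
extractPcmDataset <- function(store, level6Filter = "channel") {
  df <- as.data.frame(query(store, pcmQueryText(level6Filter)))
  df$val <- as.numeric(df$val)
  rownames(df) <- NULL
  class(df) <- c("pcmDataset", "data.frame")
  df
}

#' Distinct activity types recorded for a target
#'
#' @param store the store.
#' @param targetId integer target id.
#' @return sorted character vector of type names (possibly empty).
#' @export
listActivityTypes <- function(store, targetId) {
  q <- paste0(
    "PREFIX chembl: <", CHEMBL_NS, ">\n",
    "SELECT DISTINCT ?type WHERE {\n",
    "  ?act chembl:type ?type ; chembl:onAssay ?ass .\n",
    "  ?ass chembl:forTarget <", CHEMBL_RES, "target/", targetId, "> .\n}")
  res <- as.data.frame(query(store, q))
  sort(res$type)
}

#' Model matrices from a QSAR data set
#'
#' Converts activities to the -log10 molar scale, autoscales response and
#' descriptor columns, and turns assay confidences into observation
#' weights averaging one.
#'
#' @param dataset a \code{qsarDataset} (or any data.frame with smiles,
#'   val, unit, conf columns).
#' @param descriptorIds registry descriptor ids for the X block.
#' @return list: \code{X} (n x p, centered/unit variance; constant columns
#'   dropped with a warning), \code{y} (centered/unit variance -log10
#'   molar activity), \code{w} (confidence / mean confidence),
#'   \code{center}/\code{scale} constants and the descriptor metadata.
#' @export
qsarMatrix <- function(dataset, descriptorIds = qsarDescriptorIds()) {
  stopifnot(nrow(dataset) >= 2L)
  unitScale <- c(nM = 1e-9, uM = 1e-6)
  if (!all(dataset$unit %in% names(unitScale)))
    stop("unknown unit(s): ",
         paste(setdiff(unique(dataset$unit), names(unitScale)), collapse = ", "))
  molar <- dataset$val * unname(unitScale[dataset$unit])
  ylog <- -log10(molar)
  if (stats::sd(ylog) == 0) stop("zero-variance response after transform")
  y <- as.vector(scale(ylog))
  dm <- descriptorMatrix(lapply(dataset$smiles, parseSmiles), descriptorIds)
  X <- dm$matrix
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant descriptor column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Xs <- scale(X)
  w <- dataset$conf / mean(dataset$conf)
  list(X = Xs, y = y, w = w,
       yCenter = mean(ylog), yScale = stats::sd(ylog),
       metadata = dm$metadata[dm$metadata$id %in% colnames(X), , drop = FALSE])
}

#' Simulate weighted-regression data with confidence-dependent noise
#'
#' The direct (matrix-level) counterpart of the RDF-store generator's
#' planted signal: standardized Gaussian descriptors, a known coefficient
#' vector, assay confidences drawn from a small set of levels, and noise
#' with SD \code{noiseBaseSd / sqrt(confidence)}; weights are confidences
#' normalized to mean one. Set \code{heteroscedastic = FALSE} for
#' homoscedastic noise at \code{noiseBaseSd} with the same weight vector.
#'
#' @param n,p problem size.
#' @param beta true coefficients (default drawn N(0,1)).
#' @param confidenceLevels sampled uniformly per observation.
#' @param noiseBaseSd base noise SD.
#' @param heteroscedastic whether noise SD varies with confidence.
#' @param seed optional seed (uses current RNG state when NULL).
#' @return list X, y (standardized), w, beta, confidence, noiseSd.
#' @export
simulateWeightedRegression <- function(n, p, beta = NULL,
                                       confidenceLevels = c(1L, 3L, 9L),
                                       noiseBaseSd = 0.6,
                                       heteroscedastic = TRUE,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(beta)) beta <- stats::rnorm(p)
  stopifnot(length(beta) == p)
  X <- matrix(stats::rnorm(n * p), n, p)
  X <- scale(X)
  conf <- sample(confidenceLevels, n, replace = TRUE)
  sdv <- if (heteroscedastic) noiseBaseSd / sqrt(conf)
         else rep(noiseBaseSd, n)
  yraw <- drop(X %*% beta) + stats::rnorm(n, sd = sdv)
  ysc <- stats::sd(yraw)
  list(X = X, y = drop(scale(yraw)), w = conf / mean(conf),
       beta = beta / ysc, confidence = conf, noiseSd = sdv / ysc)
}

#' Export a QSAR data set as an SD file with activity properties
#'
#' Mirrors the dataset-assembly step that serializes extracted structures
#' into an MDL SD file with the activity scores as properties.
#'
#' @param dataset a \code{qsarDataset}.
#' @param path output SD file path.
#' @export
qsarDatasetToSDF <- function(dataset, path) {
  mols <- lapply(seq_len(nrow(dataset)), function(i)
    parseSmiles(dataset$smiles[i], name = basename(dataset$mol[i])))
  props <- lapply(seq_len(nrow(dataset)), function(i)
    c(activity = dataset$val[i], unit = dataset$unit[i],
      confidence = dataset$conf[i]))
  writeSDF(mols, path, properties = props)
}
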