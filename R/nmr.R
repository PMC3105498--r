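# NMR spectra as RDF, and dereplication against a reference-spectrum
# store by chemical-shift peak matching. "Near" is an explicit tolerance
# (default 0.5 ppm for 13C-style shifts); the similarity score of a query
# against a database spectrum is the fraction of query peaks that find a
# one-to-one greedy nearest-neighbour partner within tolerance.

#' Serialize a Spectrum to RDF
#'
#' The spectrum resource links its molecule and one resource per peak,
#' each carrying the shift as an xsd:decimal literal in ppm (and the
#' intensity when known).
#'
#' @param s a \code{\link{spectrum13C}}.
#' @return a \code{TripleStore}.
#' @export
spectrumToRDF <- function(s) {
  spec <- iri(s@id)
  su <- character(0); pr <- character(0); ob <- character(0)
  say <- function(a, b, c) {
    su[length(su) + 1L] <<- a; pr[length(pr) + 1L] <<- b
    ob[length(ob) + 1L] <<- c
  }
  say(spec, rdfTypeIRI(), nmrIRI("Spectrum"))
  say(spec, nmrIRI("aboutMolecule"), iri(s@moleculeRef))
  say(spec, nmrIRI("nucleus"), literal(s@nucleus))
  pk <- s@peaks
  for (k in seq_len(nrow(pk))) {
    p <- iri(paste0(s@id, "/peak", k))
    say(spec, nmrIRI("hasPeak"), p)
    say(p, rdfTypeIRI(), nmrIRI("Peak"))
    say(p, nmrIRI("shift"), decimalLiteral(pk$shift[k]))
    if (!is.na(pk$intensity[k]))
      say(p, nmrIRI("intensity"), decimalLiteral(pk$intensity[k]))
  }
  tripleStore(su, pr, ob, prefixes = chemrdfPrefixes())
}

#' Read a Spectrum back from RDF
#'
#' @param store a \code{TripleStore}.
#' @param spectrumIRI IRI text of the spectrum resource.
#' @return a \code{Spectrum}; a peak resource without a shift is a
#'   structural error.
#' @export
spectrumFromRDF <- function(store, spectrumIRI) {
  spec <- iri(spectrumIRI)
  tr <- store@triples
  if (!any(tr$subject == spec & tr$predicate == rdfTypeIRI() &
             tr$object == nmrIRI("Spectrum")))
    stop("no nmr:Spectrum resource at <", spectrumIRI, ">")
  molRef <- storeObjects(store, spec, nmrIRI("aboutMolecule"))
  nucleus <- storeObjects(store, spec, nmrIRI("nucleus"))
  peakIRIs <- storeObjects(store, spec, nmrIRI("hasPeak"))
  shifts <- intensities <- numeric(length(peakIRIs))
  for (k in seq_along(peakIRIs)) {
    sh <- storeObjects(store, peakIRIs[k], nmrIRI("shift"))
    if (!length(sh))
      stop("peak ", peakIRIs[k], " has no nmr:shift value")
    shifts[k] <- as.numeric(literalValue(sh[1]))
    iv <- storeObjects(store, peakIRIs[k], nmrIRI("intensity"))
    intensities[k] <- if (length(iv)) as.numeric(literalValue(iv[1]))
                      else NA_real_
  }
  spectrum13C(spectrumIRI,
              if (length(molRef)) iriValue(molRef[1]) else NA_character_,
              shifts, intensities,
              nucleus = if (length(nucleus)) literalValue(nucleus[1])
                        else "13C")
}

allSpectraIRIs <- function(store) {
  tr <- store@triples
  iriValue(tr$subject[tr$predicate == rdfTypeIRI() &
                        tr$object == nmrIRI("Spectrum")])
}

#' Find molecules with a peak near a shift
#'
#' @param store an RDF store of spectra.
#' @param shift query chemical shift in ppm.
#' @param tol tolerance in ppm (default 0.5); a peak matches when
#'   |peak - shift| <= tol.
#' @return data.frame (molecule, bestDeviation), deduplicated over
#'   molecules and sorted by smallest deviation.
#' @export
findMoleculesWithPeakNear <- function(store, shift, tol = 0.5) {
  stopifnot(tol >= 0)
  hits <- data.frame(molecule = character(0), bestDeviation = numeric(0),
                     stringsAsFactors = FALSE)
  for (sid in allSpectraIRIs(store)) {
    s <- spectrumFromRDF(store, sid)
    dev <- abs(s@peaks$shift - shift)
    if (any(dev <= tol))
      hits <- rbind(hits, data.frame(molecule = s@moleculeRef,
                                     bestDeviation = min(dev),
                                     stringsAsFactors = FALSE))
  }
  if (!nrow(hits)) return(hits)
  best <- stats::aggregate(bestDeviation ~ molecule, hits, min)
  best[order(best$bestDeviation, best$molecule), , drop = FALSE]
}

# greedy one-to-one matching of query shifts to a peak list
greedyMatch <- function(queryShifts, dbShifts, tol) {
  used <- logical(length(dbShifts))
  pairs <- data.frame(query = numeric(0), db = numeric(0))
  for (qs in queryShifts) {
    dev <- abs(dbShifts - qs)
    dev[used] <- Inf
    j <- which.min(dev)
    if (length(j) && is.finite(dev[j]) && dev[j] <= tol) {
      used[j] <- TRUE
      pairs <- rbind(pairs, data.frame(query = qs, db = dbShifts[j]))
    }
  }
  pairs
}

#' Dereplicate a query spectrum against a reference store
#'
#' Every query peak is greedily matched to the nearest unused peak of each
#' database spectrum within tolerance (one-to-one). The score is the
#' matched fraction of query peaks; results are ranked by score
#' descending, ties by mean absolute deviation of the matched pairs
#' ascending, then by spectrum id.
#'
#' @param queryShifts numeric vector of query peak shifts (ppm), nonempty.
#' @param store reference-spectrum RDF store.
#' @param tol tolerance in ppm (default 0.5).
#' @return data.frame: spectrum, molecule, score, nMatched, meanAbsDev
#'   (NA when nothing matched), one row per database spectrum, ranked.
#' @export
matchSpectrum <- function(queryShifts, store, tol = 0.5) {
  stopifnot(length(queryShifts) >= 1L, tol >= 0)
  ids <- allSpectraIRIs(store)
  rows <- lapply(ids, function(sid) {
    s <- spectrumFromRDF(store, sid)
    pairs <- greedyMatch(queryShifts, s@peaks$shift, tol)
    data.frame(spectrum = sid, molecule = s@moleculeRef,
               score = nrow(pairs) / length(queryShifts),
               nMatched = nrow(pairs),
               meanAbsDev = if (nrow(pairs))
                 mean(abs(pairs$query - pairs$db)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(spectrum = character(0), molecule = character(0),
                      score = numeric(0), nMatched = integer(0),
                      meanAbsDev = numeric(0)))
  dev <- ifelse(is.na(out$meanAbsDev), Inf, out$meanAbsDev)
  out <- out[order(-out$score, dev, out$spectrum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a seeded synthetic reference-spectrum store
#'
#' Spectra are drawn over a stated shift range with a guaranteed minimum
#' separation between any two peaks in the database, so that
#' self-dereplication at a tolerance below half the separation is
#' unambiguous by construction.
#'
#' @param nMolecules number of reference molecules/spectra.
#' @param peaksRange integer range c(min, max) of peaks per spectrum.
#' @param seed RNG seed.
#' @param shiftRange chemical-shift range in ppm (default 0-220,
#'   13C-style).
#' @param minSeparation minimum distance between any two database peaks
#'   (default 1.2 ppm, i.e. > 2x the default 0.5 tolerance).
#' @return list: store (a \code{TripleStore}), groundTruth (data.frame
#'   spectrum, molecule, shifts list-column).
#' @export
generateSpectraDb <- function(nMolecules, peaksRange = c(3L, 8L), seed = 1L,
                              shiftRange = c(0, 220), minSeparation = 1.2) {
  stopifnot(nMolecules >= 0, peaksRange[1] >= 1L,
            peaksRange[2] >= peaksRange[1], minSeparation > 0)
  set.seed(seed)
  # a jittered grid with spacing > minSeparation guarantees separation
  spacing <- minSeparation * 1.5
  grid <- seq(shiftRange[1] + spacing, shiftRange[2] - spacing, by = spacing)
  nPeaks <- sample(peaksRange[1]:peaksRange[2], nMolecules, replace = TRUE)
  if (sum(nPeaks) > length(grid))
    stop("shift range too narrow for ", sum(nPeaks), " separated peaks")
  slots <- sample(grid, sum(nPeaks))
  slots <- slots + stats::runif(length(slots), -0.1, 0.1) * minSeparation
  stores <- vector("list", nMolecules)
  gt <- vector("list", nMolecules)
  off <- 0L
  for (i in seq_len(nMolecules)) {
    shifts <- round(sort(slots[off + seq_len(nPeaks[i])]), 3)
    off <- off + nPeaks[i]
    sid <- paste0("http://example.org/nmr/spectrum/", i)
    mid <- paste0("http://example.org/nmr/molecule/", i)
    stores[[i]] <- spectrumToRDF(spectrum13C(sid, mid, shifts))
    gt[[i]] <- data.frame(spectrum = sid, molecule = mid,
                          shifts = I(list(shifts)))
  }
  store <- tripleStore(prefixes = chemrdfPrefixes())
  for (st in stores)
    store <- addTriples(store, st@triples$subject, st@triples$predicate,
                        st@triples$object)
  list(store = store,
       groundTruth = if (nMolecules) do.call(rbind, gt)
                     else data.frame(spectrum = character(0),
                                     molecule = character(0)))
}
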