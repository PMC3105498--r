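#' Test two triple stores for graph isomorphism
#'
#' Two stores are isomorphic when a bijection between their blank nodes
#' makes the triple sets identical; ground (blank-free) triples must match
#' exactly. The bijection is found by exhaustive backtracking, which is
#' intended for small graphs (serialization round-trip fixtures); more than
#' \code{maxBlanks} blank nodes per store is an error.
#'
#' @param a,b \code{TripleStore} objects (prefix maps are ignored; they are
#'   serialization sugar, not graph content).
#' @param maxBlanks safety cap on the exhaustive search.
#' @return TRUE or FALSE.
#' @export
isomorphic <- function(a, b, maxBlanks = 10L) {
  ta <- a@triples; tb <- b@triples
  if (nrow(ta) != nrow(tb)) return(FALSE)
  blanksOf <- function(tr)
    unique(c(tr$subject[isTermBlank(tr$subject)],
             tr$object[isTermBlank(tr$object)]))
  ba <- blanksOf(ta); bb <- blanksOf(tb)
  if (length(ba) != length(bb)) return(FALSE)
  keyset <- function(tr) sort(paste(tr$subject, tr$predicate, tr$object,
                                    sep = "\r"))
  if (!length(ba)) return(identical(keyset(ta), keyset(tb)))
  if (length(ba) > maxBlanks)
    stop("isomorphism search capped at ", maxBlanks, " blank nodes; got ",
         length(ba))
  ground <- function(tr) {
    g <- !isTermBlank(tr$subject) & !isTermBlank(tr$object)
    tr[g, , drop = FALSE]
  }
  if (!identical(keyset(ground(ta)), keyset(ground(tb)))) return(FALSE)

  # cheap pruning signature: how often a blank occurs per position/predicate
  sig <- function(tr, bl) {
    s <- tr[tr$subject == bl, ]
    o <- tr[tr$object == bl, ]
    paste(nrow(s), nrow(o),
          paste(sort(s$predicate), collapse = ","),
          paste(sort(o$predicate), collapse = ","))
  }
  sa <- unname(vapply(ba, sig, character(1), tr = ta))
  sb <- unname(vapply(bb, sig, character(1), tr = tb))
  if (!identical(sort(sa), sort(sb))) return(FALSE)

  kb <- keyset(tb)
  recurse <- function(i, mapping, used) {
    if (i > length(ba)) {
      # map in one pass over the original columns so that label swaps
      # between the two stores cannot cascade
      tr <- ta
      ms <- match(ta$subject, ba); mo <- match(ta$object, ba)
      tr$subject <- ifelse(is.na(ms), ta$subject, mapping[ms])
      tr$object <- ifelse(is.na(mo), ta$object, mapping[mo])
      return(identical(keyset(tr), kb))
    }
    for (cand in bb[!used & sb == sa[i]]) {
      used2 <- used; used2[bb == cand] <- TRUE
      m2 <- mapping; m2[i] <- cand
      if (recurse(i + 1L, m2, used2)) return(TRUE)
    }
    FALSE
  }
  recurse(1L, character(length(ba)), logical(length(bb)))
}
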