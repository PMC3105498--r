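# SMILES parsing for the organic subset.
#
# Grammar: organic-subset atoms (B C N O P S F Cl Br I), aromatic lowercase
# (b c n o p s), bracket atoms with an explicit hydrogen count and formal
# charge, bond symbols - = # :, branches, dot disconnections, and ring
# closures 1-9 / %nn. Stereochemistry, isotopes and atom maps are out of
# scope and rejected. Implicit hydrogens on non-bracket atoms are filled
# from standard valences (B 3, C 4, N 3, O 2, P 3, S 2, halogens 1); an
# aromatic bond counts 1.5 toward the used valence and the remainder is
# rounded down, which gives each benzene carbon one hydrogen.

STANDARD_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

smilesError <- function(msg, token, pos) {
  stop("SMILES parse error at position ", pos, " ('", token, "'): ", msg,
       call. = FALSE)
}

#' Parse a SMILES string into a Molecule
#'
#' @param smiles SMILES text in the supported grammar (see Details).
#' @param name optional molecule name annotation.
#' @return a \code{\link{molecule}} with implicit hydrogen counts filled in.
#' @details Bracket atoms take their hydrogen count literally (default 0)
#'   and may carry a formal charge; non-bracket atoms get implicit
#'   hydrogens from standard valences. Lowercase atoms are flagged
#'   aromatic, and bonds between two aromatic atoms default to aromatic
#'   order. Conflicting bond symbols on the two ends of a ring closure are
#'   an error.
#' @examples
#' m <- parseSmiles("C[OH2+]")
#' atomCount(m); bondCount(m)
#' @export
parseSmiles <- function(smiles, name = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  el <- character(0); chg <- integer(0); impH <- integer(0)
  arom <- logical(0); bracketH <- integer(0)  # -1 = not a bracket atom
  b1 <- integer(0); b2 <- integer(0); bord <- character(0)

  i <- 1L
  prev <- NA_integer_          # index of attachment atom
  stack <- integer(0)          # branch stack
  pendingBond <- NA_character_ # explicit bond symbol awaiting next atom
  rings <- list()              # closure digit -> list(atom, bond)

  addAtom <- function(element, aromatic, charge = 0L, hcount = -1L) {
    el[length(el) + 1L] <<- element
    chg[length(chg) + 1L] <<- charge
    impH[length(impH) + 1L] <<- 0L
    arom[length(arom) + 1L] <<- aromatic
    bracketH[length(bracketH) + 1L] <<- hcount
    length(el)
  }
  addBond <- function(a, b, order) {
    b1[length(b1) + 1L] <<- a
    b2[length(b2) + 1L] <<- b
    bord[length(bord) + 1L] <<- order
  }
  bondFromSymbol <- function(sym, a, b) {
    if (!is.na(sym))
      switch(sym, "-" = "single", "=" = "double", "#" = "triple",
             ":" = "aromatic")
    else if (arom[a] && arom[b]) "aromatic" else "single"
  }
  connect <- function(new) {
    if (!is.na(prev)) addBond(prev, new, bondFromSymbol(pendingBond, prev, new))
    pendingBond <<- NA_character_
    prev <<- new
  }
  ringBond <- function(digit, pos) {
    key <- as.character(digit)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pendingBond)
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      sym <- if (!is.na(open$bond) && !is.na(pendingBond)) {
        if (open$bond != pendingBond)
          smilesError("conflicting bond orders on ring closure", digit, pos)
        open$bond
      } else if (!is.na(open$bond)) open$bond else pendingBond
      addBond(open$atom, prev, bondFromSymbol(sym, open$atom, prev))
    }
    pendingBond <<- NA_character_
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) smilesError("branch before any atom", ch, i)
      stack <- c(stack, prev); i <- i + 1L; next
    }
    if (ch == ")") {
      if (!length(stack)) smilesError("unbalanced parentheses", ch, i)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "=", "#", ":")) {
      pendingBond <- ch; i <- i + 1L; next
    }
    if (ch == ".") {
      prev <- NA_integer_; pendingBond <- NA_character_; i <- i + 1L; next
    }
    if (ch %in% as.character(0:9)) {
      if (is.na(prev)) smilesError("ring closure before any atom", ch, i)
      ringBond(ch, i); i <- i + 1L; next
    }
    if (ch == "%") {
      if (i + 2L > n || !all(chars[i + 1:2] %in% as.character(0:9)))
        smilesError("'%' requires two digits", ch, i)
      ringBond(paste0(chars[i + 1L], chars[i + 2L]), i)
      i <- i + 3L; next
    }
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) smilesError("unterminated bracket atom", "[", i)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regexec("^([A-Za-z][a-z]?)(H[0-9]*)?(\\+{1,2}|-{1,2}|\\+[0-9]|-[0-9])?$",
                   body)[[1]]
      if (m[1] == -1)
        smilesError("unsupported bracket atom (stereo/isotope/atom map?)",
                    body, i)
      g <- regmatches(body, list(m))[[1]]
      sym <- g[2]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      elem <- if (aromatic) toupper(sym) else sym
      if (!elem %in% SUPPORTED_ELEMENTS)
        smilesError("unknown element", sym, i)
      hc <- if (is.na(g[3]) || g[3] == "") 0L
            else if (g[3] == "H") 1L
            else as.integer(substr(g[3], 2L, nchar(g[3])))
      charge <- 0L
      cs <- g[4]
      if (!is.na(cs) && nzchar(cs)) {
        charge <- if (cs %in% c("+", "++", "-", "--")) {
          as.integer(nchar(cs)) * (if (startsWith(cs, "+")) 1L else -1L)
        } else {
          as.integer(substr(cs, 2L, 2L)) * (if (startsWith(cs, "+")) 1L else -1L)
        }
      }
      connect(addAtom(elem, aromatic, charge, hc))
      i <- j + 1L; next
    }
    # organic subset atom, two-letter halogens first
    two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      connect(addAtom(two, FALSE)); i <- i + 2L; next
    }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      connect(addAtom(ch, FALSE)); i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      connect(addAtom(toupper(ch), TRUE)); i <- i + 1L; next
    }
    smilesError("unknown element or token", ch, i)
  }
  if (length(stack)) smilesError("unbalanced parentheses", "(", n)
  if (length(rings)) smilesError("unmatched ring closure", names(rings)[1], n)

  # implicit hydrogens: bracket atoms literal, organic-subset from valence
  usedValence <- numeric(length(el))
  if (length(b1)) {
    w <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)[bord]
    for (k in seq_along(b1)) {
      usedValence[b1[k]] <- usedValence[b1[k]] + w[k]
      usedValence[b2[k]] <- usedValence[b2[k]] + w[k]
    }
  }
  for (a in seq_along(el)) {
    if (bracketH[a] >= 0L) {
      impH[a] <- bracketH[a]
    } else {
      impH[a] <- max(0L, as.integer(floor(STANDARD_VALENCE[[el[a]]] -
                                          usedValence[a])))
    }
  }
  molecule(atoms = data.frame(element = el, charge = chg, implicitH = impH,
                              aromatic = arom, stringsAsFactors = FALSE),
           bonds = data.frame(atom1 = b1, atom2 = b2, order = bord,
                              stringsAsFactors = FALSE),
           name = name, smiles = smiles)
}
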