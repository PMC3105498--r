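# Prefix helpers over the package vocabularies (constants live in
# AAA-constants.R; inst/extdata/vocabulary.ttl documents the full set).

#' Default namespace prefix map for package output
#'
#' @return named character vector suitable for \code{\link{tripleStore}}'s
#'   \code{prefixes} argument.
#' @export
chemrdfPrefixes <- function() {
  c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD, dc = DC_NS,
    cdk = CDK_NS, bodo = BODO_NS, chembl = CHEMBL_NS, nmr = NMR_NS,
    sdb = SDB_NS)
}

cdkIRI <- function(local) iri(paste0(CDK_NS, local))
bodoIRI <- function(local) iri(paste0(BODO_NS, local))
chemblIRI <- function(local) iri(paste0(CHEMBL_NS, local))
nmrIRI <- function(local) iri(paste0(NMR_NS, local))
rdfTypeIRI <- function() iri(paste0(RDF_NS, "type"))
dcTitleIRI <- function() iri(paste0(DC_NS, "title"))
owlSameAsIRI <- function() iri(paste0(OWL_NS, "sameAs"))
rdfsSeeAlsoIRI <- function() iri(paste0(RDFS_NS, "seeAlso"))
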