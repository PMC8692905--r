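#' @describeIn LigandReceptorDB-class secreted (ligand-capable) genes.
#' @param x an object.
#' @export
setGeneric("secretedGenes", function(x) standardGeneric("secretedGenes"))

#' @describeIn LigandReceptorDB-class membrane receptor genes.
#' @export
setGeneric("receptorGenes", function(x) standardGeneric("receptorGenes"))

#' @describeIn LigandReceptorDB-class directed ligand-receptor pair table.
#' @export
setGeneric("lrPairs", function(x) standardGeneric("lrPairs"))

#' @describeIn TrajectoryAssignment-class named per-cell pseudotime.
#' @export
setGeneric("pseudotime", function(x) standardGeneric("pseudotime"))

#' @describeIn TrajectoryAssignment-class named per-cell state factor.
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @describeIn TrajectoryAssignment-class the two pseudotime cut points.
#' @export
setGeneric("cutpoints", function(x) standardGeneric("cutpoints"))

#' @describeIn GroundTruth-class cluster -> planted marker genes.
#' @export
setGeneric("plantedMarkers", function(x) standardGeneric("plantedMarkers"))

#' @describeIn GroundTruth-class planted ligand-receptor pair table.
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' @describeIn GroundTruth-class state -> planted trajectory program genes.
#' @export
setGeneric("plantedStateGenes", function(x) standardGeneric("plantedStateGenes"))

#' @describeIn GroundTruth-class ligand -> GO terms shared with the
#'   AD-enriched program.
#' @export
setGeneric("sharedTerms", function(x) standardGeneric("sharedTerms"))

#' @describeIn GroundTruth-class latent severity and state of receiver cells.
#' @export
setGeneric("cellStates", function(x) standardGeneric("cellStates"))

#' @export
setMethod("secretedGenes", "LigandReceptorDB", function(x) x@secretedGenes)
#' @export
setMethod("receptorGenes", "LigandReceptorDB", function(x) x@receptorGenes)
#' @export
setMethod("lrPairs", "LigandReceptorDB", function(x) x@pairs)

#' @export
setMethod("pseudotime", "TrajectoryAssignment",
          function(x) stats::setNames(x@pseudotime, x@cellIds))
#' @export
setMethod("stateLabels", "TrajectoryAssignment",
          function(x) stats::setNames(x@state, x@cellIds))
#' @export
setMethod("cutpoints", "TrajectoryAssignment", function(x) x@cutpoints)

#' @export
setMethod("plantedMarkers", "GroundTruth", function(x) x@plantedMarkers)
#' @export
setMethod("plantedPairs", "GroundTruth", function(x) x@plantedPairs)
#' @export
setMethod("plantedStateGenes", "GroundTruth", function(x) x@plantedStateGenes)
#' @export
setMethod("sharedTerms", "GroundTruth", function(x) x@sharedTerms)
#' @export
setMethod("cellStates", "GroundTruth", function(x) x@cellStates)

#' Ligand-receptor database constructor
#'
#' @param secreted character vector of secreted genes.
#' @param receptors character vector of receptor genes.
#' @param pairs data.frame with columns \code{ligand} and \code{receptor};
#'   duplicates are dropped.
#' @return A validated [LigandReceptorDB-class] object.
#' @examples
#' ligandReceptorDB(c("SEC1"), c("REC1"),
#'                  data.frame(ligand = "SEC1", receptor = "REC1"))
#' @export
ligandReceptorDB <- function(secreted, receptors, pairs) {
    pairs <- unique(as.data.frame(pairs)[, c("ligand", "receptor")])
    rownames(pairs) <- NULL
    new("LigandReceptorDB", secretedGenes = as.character(secreted),
        receptorGenes = as.character(receptors), pairs = pairs)
}
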