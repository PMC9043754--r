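#' @rdname SubjectTimeSeries-class
#' @param subjectId subject identifier.
#' @param group group label, \code{"positive"} or \code{"negative"}.
#' @param data numeric matrix, timepoints x components.
#' @return \code{SubjectTimeSeries()} returns a validated object.
#' @examples
#' sts <- SubjectTimeSeries("s1", "positive", matrix(rnorm(40), 10, 4))
#' dim(tsData(sts))
#' @export
SubjectTimeSeries <- function(subjectId, group, data) {
  new("SubjectTimeSeries", subjectId = as.character(subjectId),
      group = as.character(group), data = as.matrix(data))
}

#' @rdname WindowSpec-class
#' @param length window length in timepoints.
#' @param step window step in timepoints.
#' @export
WindowSpec <- function(length, step = 1L) {
  new("WindowSpec", length = as.integer(length), step = as.integer(step))
}

#' Accessors for hofhnet objects
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "SubjectTimeSeries", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "Hypernetwork", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))
#' @rdname accessors
#' @export
setMethod("groupLabel", "SubjectTimeSeries", function(x) x@group)

#' @rdname accessors
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))
#' @rdname accessors
#' @export
setMethod("tsData", "SubjectTimeSeries", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))
#' @rdname accessors
#' @export
setMethod("relValues", "RelevantSeries", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("nConnections", function(x) standardGeneric("nConnections"))
#' @rdname accessors
#' @export
setMethod("nConnections", "RelevantSeries", function(x) ncol(x@values))
#' @rdname accessors
#' @export
setMethod("nConnections", "Hypernetwork", function(x) x@nNodes)

#' @rdname accessors
#' @export
setGeneric("hyperedges", function(x) standardGeneric("hyperedges"))
#' @rdname accessors
#' @export
setMethod("hyperedges", "Hypernetwork", function(x) x@hyperedges)

#' @rdname accessors
#' @export
setGeneric("groupAssignments", function(x) standardGeneric("groupAssignments"))
#' @rdname accessors
#' @export
setMethod("groupAssignments", "ConnectionGrouping", function(x) x@assignments)

#' @rdname accessors
#' @export
setGeneric("medoids", function(x) standardGeneric("medoids"))
#' @rdname accessors
#' @export
setMethod("medoids", "ConnectionGrouping", function(x) x@medoids)

#' @rdname accessors
#' @export
setGeneric("clusterCost", function(x) standardGeneric("clusterCost"))
#' @rdname accessors
#' @export
setMethod("clusterCost", "ConnectionGrouping", function(x) x@cost)

#' @rdname accessors
#' @export
setGeneric("patterns", function(x) standardGeneric("patterns"))
#' @rdname accessors
#' @export
setMethod("patterns", "DiscriminativeSet", function(x) x@patterns)

#' @rdname accessors
#' @export
setGeneric("fusedKernel", function(x) standardGeneric("fusedKernel"))
#' @rdname accessors
#' @export
setMethod("fusedKernel", "KernelBundle", function(x) x@fused)

#' @rdname accessors
#' @export
setGeneric("fusionWeights", function(x) standardGeneric("fusionWeights"))
#' @rdname accessors
#' @export
setMethod("fusionWeights", "KernelBundle", function(x) x@mu)
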