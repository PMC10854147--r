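#' @rdname GeneSetCollection-class
#' @param x a \linkS4class{GeneSetCollection}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setDescriptions", function(x) standardGeneric("setDescriptions"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("emptySets", function(x) standardGeneric("emptySets"))

#' @rdname SimilarityMatrix-class
#' @param x a \linkS4class{SimilarityMatrix}.
#' @export
setGeneric("simMeasure", function(x) standardGeneric("simMeasure"))

#' @rdname ThemePartition-class
#' @param x a \linkS4class{ThemePartition}.
#' @export
setGeneric("themeMembership", function(x) standardGeneric("themeMembership"))

#' @rdname ThemePartition-class
#' @export
setGeneric("themeTable", function(x) standardGeneric("themeTable"))

#' @rdname ThemePartition-class
#' @export
setGeneric("nThemes", function(x) standardGeneric("nThemes"))
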