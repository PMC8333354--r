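#' Re-exported generics
#'
#' \code{metadata} from S4Vectors and \code{assay} from
#' SummarizedExperiment, so the containers can be inspected without
#' attaching the Bioconductor infrastructure packages.
#'
#' @importFrom S4Vectors metadata
#' @export
#' @name reexports
#' @aliases metadata
#' @keywords internal
S4Vectors::metadata

#' @importFrom SummarizedExperiment assay
#' @export
#' @rdname reexports
#' @aliases assay
SummarizedExperiment::assay
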