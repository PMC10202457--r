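# Re-exports of the container generics users (and the test suite) need to
# work with CellTraceSet objects without attaching the Bioconductor stack.

#' @importFrom SummarizedExperiment assay
#' @export
SummarizedExperiment::assay

#' @importFrom SummarizedExperiment assay<-
#' @export
SummarizedExperiment::`assay<-`

#' @importFrom SummarizedExperiment assayNames
#' @export
SummarizedExperiment::assayNames

#' @importFrom SummarizedExperiment rowData
#' @export
SummarizedExperiment::rowData

#' @importFrom SummarizedExperiment rowData<-
#' @export
SummarizedExperiment::`rowData<-`

#' @importFrom SummarizedExperiment colData
#' @export
SummarizedExperiment::colData

#' @export
S4Vectors::metadata

#' @export
S4Vectors::`metadata<-`
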