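## data.table is used via :: with [.data.table semantics
.datatable.aware <- TRUE

#' @importFrom data.table data.table :=
#' @importFrom stats phyper rnorm runif setNames pt cor sd
#' @importFrom utils read.delim write.table
NULL
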