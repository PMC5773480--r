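#' @useDynLib sceG4, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table :=
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(".N", ".", "cell_id", "chrom", "density",
                         "baseline", "density_ratio", "copy_state",
                         "start", "N"))
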