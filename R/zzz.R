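#' @keywords internal
#' @import data.table
"_PACKAGE"

.datatable.aware <- TRUE

utils::globalVariables(c(
  "p", "q", "w", "g", "prob", ".", "d1", "d2", "d3", "d4", "d5", "d6",
  "d7", "d8", "d9", "lost", "pix", "dep", "cat_", "pc", "key_", "mask",
  "oid", "event", "frame", "row_", "col_", "energy", "cluster", "size",
  "threshold", "counts", "n_single", "n_multiple", "r0", "sigma_e", "ncc",
  "value", "N", "pix_1", "pix_2", "dep_1", "dep_2", "phat", "n"
))
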