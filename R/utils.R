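# Fast data.frame constructor for hot paths: skips name deparsing and
# checks; columns must be equal-length atomic vectors.
quick_df <- function(...) {
  lst <- list(...)
  structure(lst, class = "data.frame",
            row.names = .set_row_names(length(lst[[1]])))
}
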