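#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Abort with a formatted message
#' @noRd
gp_stop <- function(...) stop(sprintf(...), call. = FALSE)

#' @noRd
gp_warn <- function(...) warning(sprintf(...), call. = FALSE)

#' Empty data frame with given column names/types
#' @noRd
empty_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(t) vector(t, 0L)),
                stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a delimited file with no factor conversion, tolerating empty files
#' @noRd
read_tsv_plain <- function(path, sep = "\t", header = TRUE) {
  if (!file.exists(path)) gp_stop("file not found: %s", path)
  if (file.size(path) == 0L) return(NULL)
  utils::read.table(path, sep = sep, header = header, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, fill = FALSE, strip.white = FALSE)
}

#' @noRd
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}
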