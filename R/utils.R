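# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
norm_chrom <- function(chrom) sub("^chr", "", as.character(chrom))

# Stop with a typed condition so callers/tests can distinguish error classes.
stop_typed <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "isdreg_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || any(!is.finite(x)) || any(!lo_ok) || any(!hi_ok)) {
    stop_typed("domain_error", "%s must lie in %s0,1%s", name,
               if (open_left) "(" else "[", if (open_right) ")" else "]")
  }
  invisible(x)
}

# Commented provenance header written at the top of every pipeline table.
output_header <- function(build = "hg19") {
  sprintf("# isdreg %s; build=%s",
          as.character(utils::packageVersion("isdreg")), build)
}

write_tsv_commented <- function(df, path, build = "hg19") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(output_header(build), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
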