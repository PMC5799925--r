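## Internal logging: messages go to stderr so stdout stays clean for reports.

gi_log <- function(..., level = "INFO") {
  if (isTRUE(getOption("phyloGI.quiet", FALSE))) return(invisible(NULL))
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(..., collapse = "")))
  invisible(NULL)
}

gi_warn <- function(...) {
  warning(paste0(...), call. = FALSE)
}

## Deterministic unordered pair key: smaller gene id first.
pair_key <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(g1 = a, g2 = b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
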