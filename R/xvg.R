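#' Read and write two-column XVG curves
#'
#' Grace-style XVG files as written by common MD analysis tools: lines
#' starting with `#` or `@` are metadata, the rest whitespace-separated
#' numeric columns.
#'
#' @param file Path to the file.
#' @return `read_xvg()` returns a data frame of the numeric columns.
#' @export
read_xvg <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))
  if (!any(keep)) stop(sprintf("no data rows in '%s'", file), call. = FALSE)
  con <- textConnection(lines[keep])
  on.exit(close(con))
  utils::read.table(con, header = FALSE)
}

#' @rdname read_xvg
#' @param x Data frame or matrix of numeric columns.
#' @param title,xaxis,yaxis Metadata strings written as `@` records.
#' @export
write_xvg <- function(x, file, title = "", xaxis = "", yaxis = "") {
  hdr <- c(sprintf("@    title \"%s\"", title),
           sprintf("@    xaxis label \"%s\"", xaxis),
           sprintf("@    yaxis label \"%s\"", yaxis))
  body <- apply(as.matrix(x), 1, function(row)
    paste(sprintf("%.10g", row), collapse = "  "))
  writeLines(c(hdr, body), file)
  invisible(file)
}
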