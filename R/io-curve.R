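# Two-column text scattering curves: Q (nm^-1) then I (arbitrary units).
# Comment lines start with '#'; extra columns (e.g. experimental errors) are
# preserved as an attribute but unused.

#' Read an experimental scattering curve
#'
#' Reads a whitespace-separated text file whose first column is Q (nm^-1) and
#' second column is intensity. Lines starting with `#` and blank lines are
#' skipped; rows are sorted by Q; duplicate Q values are rejected. Any extra
#' columns are kept in the `"extra"` attribute.
#'
#' @param path path to the curve file (at least 2 rows and 2 columns).
#' @param kind curve provenance label, default `"experimental"`.
#' @return a [scatter_curve()].
#' @export
read_experimental_curve <- function(path, kind = "experimental") {
  if (!file.exists(path)) stop("read_experimental_curve: file not found: ",
                               path)
  df <- tryCatch(
    read.table(path, header = FALSE, comment.char = "#",
               blank.lines.skip = TRUE, stringsAsFactors = FALSE),
    error = function(e) stop("read_experimental_curve: cannot parse '", path,
                             "': ", conditionMessage(e)))
  if (ncol(df) < 2L)
    stop("read_experimental_curve: need at least 2 columns, got ", ncol(df))
  if (nrow(df) < 2L)
    stop("read_experimental_curve: need at least 2 data rows, got ", nrow(df))
  if (!all(vapply(df[1:2], is.numeric, logical(1))))
    stop("read_experimental_curve: non-numeric payload in first two columns")
  ord <- order(df[[1]])
  df <- df[ord, , drop = FALSE]
  if (anyDuplicated(df[[1]]))
    stop("read_experimental_curve: duplicate Q values in ", path)
  cur <- scatter_curve(df[[1]], df[[2]], kind = kind, source = path)
  if (ncol(df) > 2L) attr(cur, "extra") <- df[, -(1:2), drop = FALSE]
  cur
}

#' Write a scattering curve as two-column text
#'
#' Output format is readable by [read_experimental_curve()]: a `#` header line
#' followed by `Q I` pairs.
#'
#' @param curve a [scatter_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scatter_curve"))
  lines <- c(sprintf("# Q(nm^-1)  I(arb) [%s%s]", curve$kind,
                     if (curve$smeared) ", smeared" else ""),
             sprintf("%.8e  %.8e", curve$q, curve$i))
  writeLines(lines, path)
  invisible(path)
}
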