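#' Read a GMT gene-set file
#'
#' GMT is tab-delimited: set name, description, then member gene ids.
#'
#' @param path file path.
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("read_gmt: line(s) ", paste(which(bad), collapse = ", "),
         " have fewer than 3 fields")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Write a gene-set collection as GMT
#'
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names).
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (any(lengths(sets) == 0L))
    stop("write_gmt: empty gene sets cannot be written")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
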