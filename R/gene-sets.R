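#' Read a GMT gene-set library
#'
#' Parses the tab-separated GMT format (one line per term:
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}). Lines with fewer
#' than three fields are skipped with a warning; terms whose gene list is
#' empty after removing blank fields are dropped with a warning; duplicate
#' term names get a numeric suffix (second \code{"NAME"} becomes
#' \code{"NAME_2"}). Gene symbols are uppercased so matching against
#' expression data is case-insensitive.
#'
#' @param path GMT file.
#' @param name library name stored on the object; defaults to the file
#'   name without extension.
#' @return An object of class \code{stroi_gene_sets}: a list with
#'   \code{name} and \code{terms} (named list of character gene vectors).
#' @export
read_gmt <- function(path, name = NULL) {
  if (!file.exists(path)) stopf("GMT file does not exist: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("GMT file is empty: %s", path)

  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3L
  if (any(short)) {
    warnf("skipping %d GMT line(s) with fewer than 3 fields", sum(short))
    fields <- fields[!short]
  }
  term_names <- vapply(fields, `[[`, "", 1L)
  genes <- lapply(fields, function(f) {
    g <- unique(toupper(f[-(1:2)]))
    g[nzchar(g)]
  })
  empty <- lengths(genes) == 0L
  if (any(empty)) {
    warnf("dropping %d GMT term(s) with empty gene lists: %s",
          sum(empty), paste(utils::head(term_names[empty], 3), collapse = ", "))
    term_names <- term_names[!empty]
    genes <- genes[!empty]
  }
  if (length(genes) == 0L) stopf("GMT file contains no usable terms: %s", path)
  names(genes) <- dedup_suffix(term_names)
  gene_set_library(genes, name = name %||% tools::file_path_sans_ext(basename(path)))
}

#' Construct a gene-set library from a named list
#'
#' @param terms named list; each element a non-empty character vector of
#'   gene symbols (uppercased on construction).
#' @param name library name.
#' @return A \code{stroi_gene_sets} object.
#' @export
gene_set_library <- function(terms, name = "library") {
  if (length(terms) == 0L || is.null(names(terms)))
    stopf("terms must be a non-empty named list")
  if (any(lengths(terms) == 0L)) stopf("term gene sets must be non-empty")
  terms <- lapply(terms, function(g) unique(toupper(as.character(g))))
  structure(list(name = name, terms = terms), class = "stroi_gene_sets")
}

#' @export
print.stroi_gene_sets <- function(x, ...) {
  sz <- lengths(x$terms)
  cat(sprintf("<stroi_gene_sets> '%s': %d terms (sizes %d..%d)\n",
              x$name, length(x$terms), min(sz), max(sz)))
  invisible(x)
}

#' Write a gene-set library to GMT
#' @param library a \code{stroi_gene_sets} object.
#' @param path output file.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$terms), function(nm) {
    paste(c(nm, "na", library$terms[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
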