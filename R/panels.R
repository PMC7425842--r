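#' STR marker panels
#'
#' An `str_panel` is an ordered set of autosomal STR marker names. Two
#' built-in panels mirror the two generations of commercial typing kits most
#' relevant to relationship testing: a 15-marker panel of the kind used by
#' second-generation kits (the 13 CODIS core loci plus two extra markers) and
#' a 21-marker panel of the kind used by current expanded-core kits.
#'
#' @param name panel label.
#' @param markers character vector of unique marker names.
#' @return An object of class `str_panel` with fields `name` and `markers`.
#' @examples
#' str_panel("toy", c("L1", "L2"))
#' @export
str_panel <- function(name, markers) {
  markers <- as.character(markers)
  if (length(markers) < 1L) {
    stop("a panel needs at least one marker", call. = FALSE)
  }
  if (anyDuplicated(markers)) {
    stop("duplicated marker names: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = as.character(name)[1], markers = markers),
            class = "str_panel")
}

#' @export
print.str_panel <- function(x, ...) {
  cat("STR panel '", x$name, "' with ", length(x$markers), " markers:\n",
      sep = "")
  cat(" ", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

# Autosomal marker name sets of the two kit generations.  The labels are
# cosmetic; downstream arithmetic depends only on the marker count.
.identifiler15 <- c(
  "CSF1PO", "D2S1338", "D3S1358", "D5S818", "D7S820", "D8S1179",
  "D13S317", "D16S539", "D18S51", "D19S433", "D21S11", "FGA",
  "TH01", "TPOX", "vWA"
)
.globalfiler21 <- c(
  .identifiler15,
  "D1S1656", "D2S441", "D10S1248", "D12S391", "D22S1045", "SE33"
)

#' Built-in STR panels
#'
#' @param name `"identifiler15"` (15 autosomal markers, second-generation
#'   kit) or `"globalfiler21"` (21 autosomal markers, expanded-core kit).
#' @return An [str_panel].
#' @examples
#' length(builtin_panel("identifiler15")$markers) # 15
#' length(builtin_panel("globalfiler21")$markers) # 21
#' @export
builtin_panel <- function(name = c("identifiler15", "globalfiler21")) {
  name <- match.arg(name)
  switch(name,
    identifiler15 = str_panel("identifiler15", .identifiler15),
    globalfiler21 = str_panel("globalfiler21", .globalfiler21)
  )
}

#' Read / write a panel definition
#'
#' Panels are serialized as JSON or YAML objects `{name, markers: [...]}`;
#' the format is chosen from the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path file path.
#' @return `read_panel()` returns an [str_panel]; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(obj$name) || is.null(obj$markers)) {
    stop("panel file must contain fields 'name' and 'markers': ", path,
         call. = FALSE)
  }
  str_panel(obj$name, unlist(obj$markers))
}

#' @rdname read_panel
#' @param panel an [str_panel].
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "str_panel"))
  obj <- list(name = panel$name, markers = panel$markers)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
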