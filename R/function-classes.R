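#' Function-class score tables
#'
#' SNPs are categorised by their position and predicted effect relative to a
#' gene, following the dbSNP function classification. Each class carries an
#' integer score reflecting how likely a variant of that class is to alter the
#' encoded amino-acid sequence: the three amino-acid-altering classes
#' (missense, frameshift, stop_gain) carry the table maximum of 20, and the
#' remaining classes are ranked below it down to intergenic at 0.
#'
#' @return `default_score_table()` returns a named integer vector mapping each
#'   recognised function class to its score component.
#' @examples
#' default_score_table()
#' class_score("missense")
#' @export
default_score_table <- function() {
  c(
    missense    = 20L,
    frameshift  = 20L,
    stop_gain   = 20L,
    splice_site = 15L,
    synonymous  = 10L,
    utr         = 8L,
    intron      = 5L,
    near_gene   = 3L,
    intergenic  = 0L
  )
}

#' @rdname default_score_table
#' @return `function_classes()` returns the class names in rank order.
#' @export
function_classes <- function() names(default_score_table())

# classes whose variants sit inside a gene body ([start, end] containment)
genic_classes <- function() {
  c("missense", "frameshift", "stop_gain", "splice_site", "synonymous",
    "utr", "intron")
}

#' @rdname default_score_table
#' @param fc character vector of function-class names.
#' @param table named integer score table; defaults to [default_score_table()].
#' @return `class_score()` returns the integer score component for each class.
#' @export
class_score <- function(fc, table = default_score_table()) {
  stopifnot(is.character(fc), length(fc) >= 1L)
  unknown <- setdiff(unique(fc), names(table))
  if (length(unknown) > 0L) {
    stop("unknown function class(es): ", paste(unknown, collapse = ", "))
  }
  unname(table[fc])
}

#' Read a user-supplied function-class score table
#'
#' The file is plain `key = value` text (one class per line, `#` comments
#' allowed). All nine function classes must be present, scores must be
#' non-negative integers, and the amino-acid-altering classes must share the
#' table maximum so that the class component preserves its ranking semantics.
#'
#' @param path path to the key=value file.
#' @return named integer vector, ordered as [function_classes()].
#' @export
read_score_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed score-table line: ", lines[bad][1L])
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- suppressWarnings(as.integer(trimws(vapply(kv, `[[`, character(1), 2L))))
  if (anyNA(vals) || any(vals < 0L)) stop("score-table values must be non-negative integers")
  names(vals) <- keys
  missing <- setdiff(function_classes(), keys)
  if (length(missing) > 0L) {
    stop("score table missing class(es): ", paste(missing, collapse = ", "))
  }
  vals <- vals[function_classes()]
  aa <- c("missense", "frameshift", "stop_gain")
  if (any(vals[aa] != max(vals))) {
    stop("amino-acid-altering classes must carry the table maximum")
  }
  vals
}
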