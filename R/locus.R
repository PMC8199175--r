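#' Parse genomic locus strings
#'
#' Loci are written as `"<chrom><strand>:<start>-<end>"`, e.g.
#' `"chr14+:101056233-101056255"`. The minus strand may appear as the ASCII
#' hyphen `-` or the Unicode minus `−`; published tables mix the two.
#' Coordinates are 1-based and inclusive.
#'
#' @param x Character vector of locus strings.
#' @return A tibble with columns `chrom`, `strand` (`"+"` or `"-"`, ASCII),
#'   `start`, `end`.
#' @export
#' @examples
#' parse_locus("chr14+:101056233-101056255")
parse_locus <- function(x) {
  pat <- "^(\\S+?)([+\\-−]):([0-9]+)-([0-9]+)$"
  ok <- stringr::str_detect(x, pat)
  if (any(!ok)) {
    abort(paste0("Unparseable locus string(s): ",
                 paste(x[!ok], collapse = ", ")),
          class = "oncofetal_format_error")
  }
  m <- stringr::str_match(x, pat)
  strand <- ifelse(m[, 3] == "−", "-", m[, 3])
  start <- as.numeric(m[, 4])
  end <- as.numeric(m[, 5])
  if (any(start > end)) {
    abort(paste0("Locus start exceeds end: ",
                 paste(x[start > end], collapse = ", ")),
          class = "oncofetal_format_error")
  }
  if (any(start < 1)) {
    abort("Locus coordinates are 1-based; start must be >= 1.",
          class = "oncofetal_format_error")
  }
  tibble(chrom = m[, 2], strand = strand, start = start, end = end)
}

#' Format loci back to strings
#'
#' Inverse of [parse_locus()]; always emits the ASCII minus for the reverse
#' strand, so `parse_locus(format_locus(x))` round-trips.
#'
#' @param loci A tibble with columns `chrom`, `strand`, `start`, `end`.
#' @return Character vector of locus strings.
#' @export
format_locus <- function(loci) {
  sprintf("%s%s:%d-%d", loci$chrom, loci$strand,
          as.integer(loci$start), as.integer(loci$end))
}

#' Read a miRNA annotation table
#'
#' @param path TSV with columns `mirna_id` and `locus` (locus string dialect
#'   accepted by [parse_locus()]).
#' @return A tibble `mirna_id`, `locus`, `chrom`, `strand`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    locus = readr::col_character()
  ), progress = FALSE)
  dplyr::bind_cols(ann, parse_locus(ann$locus))
}
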