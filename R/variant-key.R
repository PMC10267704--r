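#' Parse compact variant identifiers
#'
#' A variant key is the compact string `"<chrom>:<pos><REF>><ALT>"` (for
#' example `"chr20:1546854GC>GCC"`) that uniquely identifies one alternate
#' allele at one genomic site in VCF-style 1-based, anchored-base
#' representation. Whitespace inside the string is tolerated on input and
#' removed; alleles are upper-cased.
#'
#' @param x Character vector of variant key strings.
#' @return A data frame with columns `chrom`, `pos` (integer, 1-based),
#'   `ref` and `alt` (uppercase A/C/G/T strings), one row per input key.
#' @examples
#' parse_variant_key("chr20:1546854GC>GCC")
#' @seealso [format_variant_key()], [normalize_variant_keys()]
#' @export
parse_variant_key <- function(x) {
  if (!is.character(x) || length(x) == 0L) {
    stop("variant keys must be a non-empty character vector", call. = FALSE)
  }
  x0 <- gsub("[[:space:]]+", "", x)
  m <- regmatches(x0, regexec("^([^:]+):([0-9]+)([ACGTacgt]+)>([ACGTacgt]+)$", x0))
  bad <- vapply(m, length, integer(1L)) != 5L
  if (any(bad)) {
    stop("malformed variant key: ", paste(x[bad], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    chrom = vapply(m, `[[`, character(1L), 2L),
    pos   = as.integer(vapply(m, `[[`, character(1L), 3L)),
    ref   = toupper(vapply(m, `[[`, character(1L), 4L)),
    alt   = toupper(vapply(m, `[[`, character(1L), 5L)),
    stringsAsFactors = FALSE
  )
  validate_variant_key(out)
  out
}

#' Serialize variant keys
#'
#' Inverse of [parse_variant_key()]: formats chrom/pos/ref/alt as the compact
#' `"chrom:posREF>ALT"` identifier. Parsing and re-serializing a well-formed
#' key reproduces it exactly.
#'
#' @param chrom Chromosome names, or a data frame with columns
#'   `chrom`, `pos`, `ref`, `alt` (the other arguments are then ignored).
#' @param pos 1-based positions.
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of keys.
#' @export
format_variant_key <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  if (is.data.frame(chrom)) {
    d <- chrom
    chrom <- d$chrom; pos <- d$pos; ref <- d$ref; alt <- d$alt
  }
  paste0(chrom, ":", pos, toupper(ref), ">", toupper(alt))
}

validate_variant_key <- function(d) {
  ok_allele <- function(a) nzchar(a) & grepl("^[ACGT]+$", a)
  if (any(is.na(d$pos)) || any(d$pos < 1L)) {
    stop("variant position must be a 1-based integer", call. = FALSE)
  }
  if (!all(ok_allele(d$ref)) || !all(ok_allele(d$alt))) {
    stop("ref/alt must be non-empty A/C/G/T strings", call. = FALSE)
  }
  if (any(d$ref == d$alt)) {
    stop("ref and alt allele must differ", call. = FALSE)
  }
  invisible(d)
}

#' Trim redundant shared bases from indel representations
#'
#' Canonicalizes variant records by removing bases shared between REF and ALT:
#' first the common suffix, then the common prefix (advancing `pos`), always
#' keeping at least one base in each allele. This collapses equivalent
#' right-padded spellings of the same indel (e.g. `GC>GCC` and `G>GC` at the
#' same anchor) onto one representation. Keys are *not* trimmed automatically
#' on input, so printed identifiers round-trip verbatim; apply this function
#' explicitly when deduplicating call sets from heterogeneous sources.
#' Left-alignment across repeat tracts would additionally require the
#' reference sequence and is out of scope.
#'
#' @param d Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return The data frame with trimmed `pos`, `ref`, `alt`.
#' @export
normalize_variant_keys <- function(d) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(d)))
  for (i in seq_len(nrow(d))) {
    r <- strsplit(d$ref[i], "", fixed = TRUE)[[1L]]
    a <- strsplit(d$alt[i], "", fixed = TRUE)[[1L]]
    while (length(r) > 1L && length(a) > 1L && r[length(r)] == a[length(a)]) {
      r <- r[-length(r)]; a <- a[-length(a)]
    }
    p <- d$pos[i]
    while (length(r) > 1L && length(a) > 1L && r[1L] == a[1L]) {
      r <- r[-1L]; a <- a[-1L]; p <- p + 1L
    }
    d$ref[i] <- paste(r, collapse = ""); d$alt[i] <- paste(a, collapse = "")
    d$pos[i] <- p
  }
  validate_variant_key(d)
  d
}
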