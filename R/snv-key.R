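#' Parse SNV identifiers
#'
#' An SNV locus is identified by chromosome, 1-based position, reference
#' allele and alternate allele. The canonical string form is
#' `"chrom:pos:ref>alt"` (e.g. `"17:48895725:C>T"`); the underscore dialect
#' `"chrom:pos_ref>alt"` is accepted on input and normalized to the
#' canonical form. Multiallelic sites are distinct keys (same `chrom:pos`,
#' different `alt`).
#'
#' @param x character vector of SNV identifiers in either dialect.
#' @return A data.frame with columns `chrom` (character), `pos` (integer,
#'   >= 1), `ref`, `alt` (single uppercase bases, `ref != alt`) and `snv_id`
#'   (the canonical form).
#' @examples
#' parse_snv_id(c("17:48895725:C>T", "Y:2865219_C>T"))
#' @export
parse_snv_id <- function(x) {
  x <- as.character(x)
  m <- regmatches(x, regexec("^(.+):([0-9]+)[:_]([ACGT])>([ACGT])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) {
    stop("unparseable SNV identifier: '", x[which(bad)[1]],
         "' (expected chrom:pos:ref>alt or chrom:pos_ref>alt)")
  }
  chrom <- vapply(m, `[[`, "", 2L)
  pos <- as.integer(vapply(m, `[[`, "", 3L))
  ref <- vapply(m, `[[`, "", 4L)
  alt <- vapply(m, `[[`, "", 5L)
  make_snv_key(chrom, pos, ref, alt)
}

#' Build canonical SNV keys from components
#'
#' @param chrom chromosome name (kept verbatim, e.g. `"17"`, `"chrX"`).
#' @param pos 1-based genomic position, positive integer.
#' @param ref,alt single uppercase bases A/C/G/T with `ref != alt`.
#' @return data.frame as in [parse_snv_id()].
#' @export
make_snv_key <- function(chrom, pos, ref, alt) {
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  ref <- as.character(ref)
  alt <- as.character(alt)
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("SNV position must be a positive (1-based) integer")
  }
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases)) {
    stop("ref and alt must be single uppercase bases A/C/G/T")
  }
  if (any(ref == alt)) {
    i <- which(ref == alt)[1]
    stop("ref and alt alleles must differ (got ", chrom[i], ":", pos[i],
         " ", ref[i], ">", alt[i], ")")
  }
  data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    snv_id = paste0(chrom, ":", pos, ":", ref, ">", alt),
    stringsAsFactors = FALSE
  )
}

#' Format SNV keys as canonical identifier strings
#'
#' @param keys data.frame with columns chrom, pos, ref, alt (or a ready
#'   `snv_id` column, which is returned as-is).
#' @return character vector `"chrom:pos:ref>alt"`.
#' @export
format_snv_id <- function(keys) {
  if (!is.null(keys$snv_id)) return(as.character(keys$snv_id))
  paste0(keys$chrom, ":", keys$pos, ":", keys$ref, ">", keys$alt)
}
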