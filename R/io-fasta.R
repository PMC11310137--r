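#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased on read and restricted to the `{A,C,G,T,N}`
#' alphabet; the first whitespace-delimited token of each header becomes the
#' record `name`, the remainder its `desc`.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A tibble with columns `name`, `desc`, `seq`, one row per record,
#'   in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1 test", "ACGT", "ACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  name <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seq <- toupper(as.character(ss))
  fa <- tibble::tibble(name = name, desc = desc, seq = unname(seq))
  validate_fasta(fa, path)
  fa
}

validate_fasta <- function(fa, label = "fasta") {
  if (any(fa$name == "" | is.na(fa$name)))
    stop("empty record id in ", label, call. = FALSE)
  if (any(nchar(fa$seq) == 0))
    stop("empty sequence for record ",
         fa$name[which(nchar(fa$seq) == 0)[1]], " in ", label, call. = FALSE)
  bad <- grepl("[^ACGTN]", fa$seq)
  if (any(bad))
    stop("sequence for record ", fa$name[which(bad)[1]],
         " contains characters outside {A,C,G,T,N} in ", label, call. = FALSE)
  invisible(fa)
}

#' Construct a sequence tibble
#'
#' @param name Character vector of record ids.
#' @param seq Character vector of sequences (uppercased, `{A,C,G,T,N}`).
#' @param desc Optional descriptions.
#' @return A validated tibble with columns `name`, `desc`, `seq`.
#' @export
fasta_tbl <- function(name, seq, desc = "") {
  fa <- tibble::tibble(name = as.character(name), desc = desc,
                       seq = toupper(as.character(seq)))
  validate_fasta(fa)
  fa
}

#' Write a sequence tibble to FASTA
#'
#' @param fa A tibble as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(fa, path, width = 60L) {
  validate_fasta(fa)
  ss <- Biostrings::BStringSet(setNames(fa$seq, ifelse(
    fa$desc == "", fa$name, paste(fa$name, fa$desc))))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Reverse-complement a DNA string
#'
#' `N` maps to `N`.
#'
#' @param x Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}
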