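#' Read a PAF alignment file
#'
#' Parses the 12 mandatory tab-separated PAF columns plus trailing SAM-style
#' typed tags. Coordinates are 0-based half-open, target coordinates always
#' on the forward strand (PAF convention). A `cs:Z:` difference string, when
#' present, is exposed in its own `cs` column; all tags are also retained
#' verbatim in `tags`.
#'
#' @param path Path to a PAF file.
#' @return A tibble with columns `qname`, `qlen`, `qstart`, `qend`, `strand`,
#'   `tname`, `tlen`, `tstart`, `tend`, `nmatch`, `alen`, `mapq`, `cs`,
#'   `tags`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("PAF file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty PAF file: ", path)
    return(empty_paf())
  }
  recs <- lapply(seq_along(lines), function(i) parse_paf_line(lines[[i]], i))
  paf <- dplyr::bind_rows(recs)
  validate_paf(paf)
  paf
}

empty_paf <- function() {
  tibble::tibble(qname = character(), qlen = integer(), qstart = integer(),
                 qend = integer(), strand = character(), tname = character(),
                 tlen = integer(), tstart = integer(), tend = integer(),
                 nmatch = integer(), alen = integer(), mapq = integer(),
                 cs = character(), tags = character())
}

parse_paf_line <- function(line, lineno) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 12)
    stop("PAF line ", lineno, ": fewer than 12 columns", call. = FALSE)
  ints <- suppressWarnings(as.integer(f[c(2:4, 7:12)]))
  if (anyNA(ints))
    stop("PAF line ", lineno, ": non-integer coordinate field", call. = FALSE)
  if (!f[5] %in% c("+", "-"))
    stop("PAF line ", lineno, ": strand must be + or -", call. = FALSE)
  tags <- if (length(f) > 12) f[13:length(f)] else character()
  cs <- NA_character_
  cs_hit <- grepl("^cs:Z:", tags)
  if (any(cs_hit)) cs <- sub("^cs:Z:", "", tags[which(cs_hit)[1]])
  tibble::tibble(
    qname = f[1], qlen = ints[1], qstart = ints[2], qend = ints[3],
    strand = f[5], tname = f[6], tlen = ints[4], tstart = ints[5],
    tend = ints[6], nmatch = ints[7], alen = ints[8], mapq = ints[9],
    cs = cs, tags = paste(tags, collapse = "\t"))
}

validate_paf <- function(paf) {
  bad <- which(!(paf$qstart >= 0 & paf$qstart < paf$qend &
                   paf$qend <= paf$qlen))
  if (length(bad))
    stop("PAF line ", bad[1], ": invalid query interval", call. = FALSE)
  bad <- which(!(paf$tstart >= 0 & paf$tstart < paf$tend &
                   paf$tend <= paf$tlen))
  if (length(bad))
    stop("PAF line ", bad[1], ": invalid target interval", call. = FALSE)
  bad <- which(paf$nmatch > paf$alen)
  if (length(bad))
    stop("PAF line ", bad[1], ": n_match exceeds alignment length",
         call. = FALSE)
  bad <- which(paf$mapq < 0 | paf$mapq > 255)
  if (length(bad))
    stop("PAF line ", bad[1], ": mapq outside [0, 255]", call. = FALSE)
  invisible(paf)
}

#' Write a PAF tibble to file
#'
#' @param paf A tibble as returned by [read_paf()] or [align_assemblies()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  tags <- paf$tags
  if (is.null(tags)) tags <- rep("", nrow(paf))
  # ensure the cs column is represented in the tag fields exactly once
  need_cs <- !is.na(paf$cs) & !grepl("(^|\t)cs:Z:", tags)
  tags[need_cs] <- ifelse(nzchar(tags[need_cs]),
                          paste0(tags[need_cs], "\tcs:Z:", paf$cs[need_cs]),
                          paste0("cs:Z:", paf$cs[need_cs]))
  core <- paste(paf$qname, paf$qlen, paf$qstart, paf$qend, paf$strand,
                paf$tname, paf$tlen, paf$tstart, paf$tend, paf$nmatch,
                paf$alen, paf$mapq, sep = "\t")
  out <- ifelse(nzchar(tags), paste(core, tags, sep = "\t"), core)
  writeLines(out, path)
  invisible(path)
}
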