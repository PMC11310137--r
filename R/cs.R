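#' Parse a minimap2 short-form cs difference string
#'
#' Supported operators: `:N` (match run), `*xy` (single-base substitution,
#' reference base then query base), `+seq` (insertion, query-only bases) and
#' `-seq` (deletion, target-only bases). Consecutive `*` operations are
#' merged into one substitution run so that a run of mismatched bases counts
#' as a single event for downstream length thresholding.
#'
#' @param cs A cs string (without the `cs:Z:` prefix).
#' @return A tibble with columns `kind` (`match`, `substitution`,
#'   `insertion`, `deletion`), `length`, `ref_seq` (target bases consumed,
#'   uppercase; empty for insertions) and `alt_seq` (query bases produced;
#'   empty for deletions).
#' @examples
#' parse_cs(":10*ac:5")
#' parse_cs(":3-ac:2+g:4")
#' @export
parse_cs <- function(cs) {
  stopifnot(is.character(cs), length(cs) == 1)
  if (is.na(cs) || cs == "") return(empty_cs_ops())
  m <- gregexpr(":[0-9]+|\\*[A-Za-z]{2}|\\+[A-Za-z]+|-[A-Za-z]+", cs)[[1]]
  tokens <- regmatches(cs, list(m))[[1]]
  if (length(tokens) == 0 || sum(attr(m, "match.length")) != nchar(cs))
    stop("malformed cs string near: ",
         substr(cs, find_cs_gap(m, cs), nchar(cs)), call. = FALSE)
  op <- substr(tokens, 1, 1)
  body <- substring(tokens, 2)
  kind <- c(":" = "match", "*" = "substitution",
            "+" = "insertion", "-" = "deletion")[op]
  len <- ifelse(op == ":", suppressWarnings(as.integer(body)),
                ifelse(op == "*", 1L, nchar(body)))
  if (any(op == ":" & len == 0))
    stop("zero-length match run in cs string", call. = FALSE)
  ref <- ifelse(op == "*", toupper(substr(body, 1, 1)),
                ifelse(op == "-", toupper(body), ""))
  alt <- ifelse(op == "*", toupper(substr(body, 2, 2)),
                ifelse(op == "+", toupper(body), ""))
  ops <- tibble::tibble(kind = unname(kind), length = len,
                        ref_seq = ref, alt_seq = alt)
  merge_substitution_runs(ops)
}

find_cs_gap <- function(m, cs) {
  if (m[1] == -1) return(1L)
  covered <- rep(FALSE, nchar(cs))
  for (i in seq_along(m))
    covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
  if (all(covered)) 1L else which(!covered)[1]
}

empty_cs_ops <- function() {
  tibble::tibble(kind = character(), length = integer(),
                 ref_seq = character(), alt_seq = character())
}

merge_substitution_runs <- function(ops) {
  if (nrow(ops) < 2) return(ops)
  is_sub <- ops$kind == "substitution"
  grp <- cumsum(!(is_sub & dplyr::lag(is_sub, default = FALSE)))
  ops |>
    dplyr::mutate(.grp = grp) |>
    dplyr::summarise(kind = .data$kind[1],
                     length = sum(.data$length),
                     ref_seq = paste(.data$ref_seq, collapse = ""),
                     alt_seq = paste(.data$alt_seq, collapse = ""),
                     .by = ".grp") |>
    dplyr::select(-".grp")
}

#' Target and query lengths consumed by a cs operation table
#'
#' Matches and substitutions consume both sides, deletions consume only the
#' target, insertions only the query; the two sums reconstruct the aligned
#' interval lengths of the source PAF record.
#'
#' @param ops A tibble from [parse_cs()].
#' @return A list with elements `target` and `query` (integer bp).
#' @export
cs_consumed <- function(ops) {
  tgt <- sum(ops$length[ops$kind %in% c("match", "substitution", "deletion")])
  qry <- sum(ops$length[ops$kind %in% c("match", "substitution", "insertion")])
  list(target = as.integer(tgt), query = as.integer(qry))
}
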