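#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mixing result
#'
#' Returns the full edit table, one row per substitution/indel event
#' examined, with its `status` (`applied`, `skipped_threshold`,
#' `skipped_N`).
#'
#' @param x An `hb_mix` object from [mix_assemblies()].
#' @param ... Unused.
#' @return A tibble of edits.
#' @export
tidy.hb_mix <- function(x, ...) {
  x$edits
}

#' One-row summary of a mixing result
#'
#' @param x An `hb_mix` object.
#' @param ... Unused.
#' @return A one-row tibble with edit counts and length accounting.
#' @export
glance.hb_mix <- function(x, ...) {
  g <- x$report$global
  tibble::tibble(n_contigs = nrow(x$assembly),
                 considered = g$considered, applied = g$applied,
                 skipped_threshold = g$skipped_threshold,
                 skipped_N = g$skipped_N,
                 bases_removed = g$bases_removed,
                 bases_inserted = g$bases_inserted,
                 net_length_change = g$net_length_change)
}

#' Tidy a screening result
#'
#' @param x An `hb_screen` object from [screen_alignments()].
#' @param ... Unused.
#' @return The block tibble with per-block `status` and the winning chain
#'   score of each scaffold.
#' @export
tidy.hb_screen <- function(x, ...) {
  x$blocks
}

#' One-row-per-scaffold summary of a screening result
#'
#' @param x An `hb_screen` object.
#' @param ... Unused.
#' @return The per-scaffold chain table.
#' @export
glance.hb_screen <- function(x, ...) {
  x$chains
}
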