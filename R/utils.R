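#' @useDynLib graphsv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (alphabet ACGTN).
#' @return Character vector of reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

## Sides of a bidirected node: left side = 2*id - 1, right side = 2*id.
side_id <- function(node_id, end) {
  2L * as.integer(node_id) - as.integer(end != "right")
}

side_node <- function(side) as.integer((side + 1L) %/% 2L)

side_is_right <- function(side) side %% 2L == 0L

side_end <- function(side) ifelse(side_is_right(side), "right", "left")

## The opposite side of the same node (x' in the snarl definition).
side_opp <- function(side) side + ifelse(side %% 2L == 1L, 1L, -1L)

edge_key <- function(s1, s2) {
  paste0(pmin(s1, s2), "-", pmax(s1, s2))
}

## Edges traversed by a walk given as oriented steps.  Step i exits its node
## at the right side when forward, left side when reverse; step i+1 is entered
## at the left side when forward, right side when reverse.
walk_edge_sides <- function(node_id, rev) {
  n <- length(node_id)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  exit <- ifelse(rev[-n], side_id(node_id[-n], "left"), side_id(node_id[-n], "right"))
  enter <- ifelse(rev[-1L], side_id(node_id[-1L], "right"), side_id(node_id[-1L], "left"))
  cbind(exit, enter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_graphsv <- function(...) stop(..., call. = FALSE)
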