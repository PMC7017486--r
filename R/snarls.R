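#' Construct a node side
#'
#' @param node_id Node id.
#' @param end `"left"` or `"right"`.
#' @return Integer side id (left side of node `i` is `2*i - 1`, right is `2*i`).
#' @export
side <- function(node_id, end = c("right", "left")) {
  end <- match.arg(end)
  side_id(as.integer(node_id), end)
}

n_sides <- function(g) 2L * length(g$node_seq)

## Adjacency degree of every side.
side_degrees <- function(g) {
  deg <- integer(n_sides(g))
  tab <- tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = n_sides(g))
  tab
}

## Reference-path coordinate of a side (NA for off-reference nodes):
## the breakpoint position the side sits on.
side_ref_coord <- function(g, s) {
  nd <- side_node(s)
  off <- g$node_offset[nd]
  ifelse(is.na(off), NA_integer_, off + ifelse(side_is_right(s), g$node_len[nd], 0L))
}

#' Test whether a pair of sides bounds a snarl
#'
#' A pair of sides `{x, y}` bounds a snarl when (separation) removing all
#' edges incident to the opposite sides `x'` and `y'` disconnects the side
#' graph, leaving a component `X` that contains `x` and `y` and communicates
#' with the rest of the graph only through `x` and `y`; and (minimality)
#' no side `z` in `X` forms a separable pair with `x`, and likewise for `y`.
#'
#' @param g A `variation_graph`.
#' @param x,y Integer side ids (see [side()]).
#' @return List with `is_snarl`, `separable`, and `component` (the side ids of
#'   `X`; empty when not separable) and `nodes` (node ids of `X`).
#' @export
is_snarl <- function(g, x, y) {
  ns <- n_sides(g)
  if (x < 1L || x > ns || y < 1L || y > ns) {
    stop_graphsv("side ", max(x, y), " is not a side of this graph")
  }
  comp <- cpp_separable(ns, g$edges, as.integer(x), as.integer(y))
  sep <- length(comp) > 0L
  minimal <- FALSE
  if (sep) {
    minimal <- TRUE
    for (z in setdiff(comp, c(x, y))) {
      if (length(cpp_separable(ns, g$edges, as.integer(x), as.integer(z))) > 0L ||
          length(cpp_separable(ns, g$edges, as.integer(z), as.integer(y))) > 0L) {
        minimal <- FALSE
        break
      }
    }
  }
  list(is_snarl = sep && minimal, separable = sep, component = comp,
       nodes = sort(unique(side_node(comp))))
}

#' Find all snarls of a variation graph
#'
#' Definition-driven search: candidate boundary sides are pruned to sides
#' adjacent to a branching edge (adjacency degree >= 2), plus trivial snarls
#' between mutually single-edged adjacent sides; for small graphs every side
#' pair is tested exhaustively. Each snarl is reported once in canonical
#' orientation (boundary with the smaller reference coordinate first) with
#' one level of nesting recorded through `parent`.
#'
#' @param g A `variation_graph`.
#' @param exhaustive Force (or forbid) testing of all side pairs; default:
#'   exhaustive when the graph has at most 200 sides.
#' @return List of snarl records (`start`, `end`, `component`,
#'   `contained_node_ids`, `contig`, `ref_start`, `ref_end`, `parent`).
#' @export
find_snarls <- function(g, exhaustive = NULL) {
  ns <- n_sides(g)
  if (is.null(exhaustive)) exhaustive <- ns <= 200L
  deg <- side_degrees(g)

  pairs <- NULL
  trivial <- NULL
  if (exhaustive) {
    all_sides <- seq_len(ns)
    pairs <- t(utils::combn(all_sides, 2L))
    pairs <- pairs[side_node(pairs[, 1L]) != side_node(pairs[, 2L]), , drop = FALSE]
  } else {
    ## mutual degree-1 adjacent side pairs are exactly the trivial snarls
    cand <- which(deg >= 2L)
    d1 <- deg[g$edges[, 1L]] == 1L & deg[g$edges[, 2L]] == 1L
    trivial <- g$edges[d1, , drop = FALSE]
    if (length(cand) >= 2L) {
      pairs <- t(utils::combn(cand, 2L))
      pairs <- pairs[side_node(pairs[, 1L]) != side_node(pairs[, 2L]), , drop = FALSE]
    } else {
      pairs <- matrix(integer(0), ncol = 2L)
    }
  }

  sep_flags <- if (nrow(pairs)) cpp_sep_pairs(ns, g$edges, pairs) else logical(0)
  sep_env <- new.env(parent = emptyenv())
  pkey <- function(a, b) paste0(min(a, b), "-", max(a, b))
  for (i in seq_len(nrow(pairs))) {
    assign(pkey(pairs[i, 1L], pairs[i, 2L]), sep_flags[i], envir = sep_env)
  }
  sep_memo <- function(a, b) {
    k <- pkey(a, b)
    v <- get0(k, envir = sep_env)
    if (is.null(v)) {
      v <- length(cpp_separable(ns, g$edges, as.integer(a), as.integer(b))) > 0L
      assign(k, v, envir = sep_env)
    }
    v
  }

  sep_pairs <- pairs[sep_flags, , drop = FALSE]
  snarls <- list()
  add_snarl <- function(x, y, comp) {
    cx <- side_ref_coord(g, x); cy <- side_ref_coord(g, y)
    flip <- if (!is.na(cx) && !is.na(cy)) {
      cy < cx || (cy == cx && y < x)
    } else if (is.na(cx) && !is.na(cy)) TRUE else y < x
    if (flip) { tmp <- x; x <- y; y <- tmp; tmp <- cx; cx <- cy; cy <- tmp }
    snarls[[length(snarls) + 1L]] <<- list(
      start = x, end = y, component = comp,
      contained_node_ids = setdiff(sort(unique(side_node(comp))),
                                   c(side_node(x), side_node(y))),
      contig = if (!is.na(cx) && !is.na(cy) &&
                   identical(g$node_contig[side_node(x)], g$node_contig[side_node(y)]))
        g$node_contig[side_node(x)] else NA_character_,
      ref_start = cx, ref_end = cy, parent = NA_integer_)
  }

  for (i in seq_len(nrow(sep_pairs))) {
    x <- sep_pairs[i, 1L]; y <- sep_pairs[i, 2L]
    comp <- cpp_separable(ns, g$edges, as.integer(x), as.integer(y))
    zs <- setdiff(comp, c(x, y))
    ## scan branching candidates first: a non-minimal pair is refuted quickly
    zs <- zs[order(-deg[zs])]
    minimal <- TRUE
    for (z in zs) {
      if (sep_memo(x, z) || sep_memo(z, y)) { minimal <- FALSE; break }
    }
    if (minimal) add_snarl(x, y, comp)
  }
  if (!is.null(trivial)) {
    for (i in seq_len(nrow(trivial))) {
      add_snarl(trivial[i, 1L], trivial[i, 2L], c(trivial[i, 1L], trivial[i, 2L]))
    }
  }

  ## nesting (parent = smallest strictly-containing snarl, by component sets)
  if (length(snarls) > 1L) {
    sizes <- vapply(snarls, function(s) length(s$component), integer(1))
    for (i in seq_along(snarls)) {
      cont <- which(vapply(seq_along(snarls), function(j) {
        j != i && sizes[j] > sizes[i] &&
          all(snarls[[i]]$component %in% snarls[[j]]$component)
      }, logical(1)))
      if (length(cont)) {
        snarls[[i]]$parent <- cont[which.min(sizes[cont])]
      }
    }
  }
  snarls
}

#' Select top-level reference-anchored snarls
#'
#' Keeps snarls whose two boundary nodes both lie on a reference path and
#' that are not contained in another snarl, and annotates each with its
#' 0-based half-open reference interval and the ids of the VCF variants
#' whose breakpoint interval falls within it.
#'
#' @param g A `variation_graph`.
#' @param snarls Output of [find_snarls()].
#' @return Filtered, annotated list of snarls (field `contained_variant_ids`).
#' @export
top_level_reference_snarls <- function(g, snarls) {
  keep <- vapply(snarls, function(s) {
    !is.na(s$contig) && is.na(s$parent) &&
      !is.na(s$ref_start) && !is.na(s$ref_end)
  }, logical(1))
  out <- snarls[keep]
  lapply(out, function(s) {
    a <- s$ref_start; b <- s$ref_end
    ids <- vapply(g$variants, function(v) {
      if (v$contig == s$contig && v$rs >= a && v$re <= b) v$id else NA_character_
    }, character(1))
    s$contained_variant_ids <- ids[!is.na(ids)]
    s
  })
}

#' Snarl report table
#'
#' @param g A `variation_graph`.
#' @param snarls Output of [top_level_reference_snarls()].
#' @return A `data.table` with contig, interval, variant and child counts.
#' @export
snarl_report <- function(g, snarls) {
  data.table::data.table(
    contig = vapply(snarls, `[[`, character(1), "contig"),
    start = vapply(snarls, `[[`, integer(1), "ref_start"),
    end = vapply(snarls, `[[`, integer(1), "ref_end"),
    n_variants = vapply(snarls, function(s)
      length(s$contained_variant_ids %||% character(0)), integer(1)),
    n_nodes = vapply(snarls, function(s) length(s$contained_node_ids), integer(1))
  )
}
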