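## Independent brute-force snarl oracle, written directly from the
## definitional criteria in plain R (no shared code with the package's C++
## search): vertices are node sides connected by node-traversal edges and
## adjacency edges; a pair {x, y} is separable when removing every edge
## incident to x' and y' leaves a component X containing x and y whose only
## boundary sides are x and y; it is a snarl when additionally no side z of
## X makes {x, z} or {z, y} separable.

oracle_adj <- function(g) {
  ns <- 2L * length(g$node_seq)
  adj <- vector("list", ns)
  for (j in seq_len(nrow(g$edges))) {
    a <- g$edges[j, 1]; b <- g$edges[j, 2]
    adj[[a]] <- c(adj[[a]], b)
    if (a != b) adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

oracle_separable <- function(adj, ns, x, y) {
  if (((x + 1) %/% 2) == ((y + 1) %/% 2)) return(NULL)
  opp <- function(s) if (s %% 2 == 1) s + 1L else s - 1L
  xo <- opp(x); yo <- opp(y)
  seen <- logical(ns)
  seen[x] <- TRUE
  stack <- x
  comp <- integer(0)
  ok <- TRUE
  while (length(stack)) {
    s <- stack[length(stack)]
    stack <- stack[-length(stack)]
    comp <- c(comp, s)
    t <- opp(s)
    if (s != xo && s != yo && t != xo && t != yo && !seen[t]) {
      seen[t] <- TRUE
      stack <- c(stack, t)
    }
    has_adj <- FALSE
    for (u in adj[[s]]) {
      if (s == xo || s == yo || u == xo || u == yo) next
      has_adj <- TRUE
      if (!seen[u]) {
        seen[u] <- TRUE
        stack <- c(stack, u)
      }
    }
    if (!has_adj && s != x && s != y) ok <- FALSE
  }
  if (ok && seen[y]) comp else NULL
}

## Exhaustive snarl enumeration over all side pairs; returns a character
## vector of canonical "min-max" side pair keys.
oracle_find_snarls <- function(g) {
  ns <- 2L * length(g$node_seq)
  adj <- oracle_adj(g)
  sep <- matrix(FALSE, ns, ns)
  comps <- list()
  for (x in seq_len(ns - 1L)) {
    for (y in (x + 1L):ns) {
      cc <- oracle_separable(adj, ns, x, y)
      if (!is.null(cc)) {
        sep[x, y] <- sep[y, x] <- TRUE
        comps[[paste0(x, "-", y)]] <- cc
      }
    }
  }
  out <- character(0)
  for (key in names(comps)) {
    xy <- as.integer(strsplit(key, "-")[[1]])
    x <- xy[1]; y <- xy[2]
    minimal <- TRUE
    for (z in setdiff(comps[[key]], xy)) {
      if (sep[min(x, z), max(x, z)] || sep[min(z, y), max(z, y)]) {
        minimal <- FALSE
        break
      }
    }
    if (minimal) out <- c(out, key)
  }
  sort(out)
}

snarl_pair_keys <- function(snarls) {
  sort(vapply(snarls, function(s) {
    paste0(min(s$start, s$end), "-", max(s$start, s$end))
  }, character(1)))
}
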