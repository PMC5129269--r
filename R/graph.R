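#' Dependency graph of a model
#'
#' Splits the declared dependencies into *instantaneous* edges (inputs read
#' by auxiliary, rate and lookup equations within a time step) and
#' *integration* edges (rate into stock, input into delay state), which only
#' take effect when the state advances. Stocks, delay outputs and constants
#' are therefore sources of the instantaneous subgraph.
#'
#' @param model an [sd_model()].
#' @return an object of class `dependency_graph` with elements `nodes`,
#'   `instantaneous_edges` and `integration_edges` (two-column `from`/`to`
#'   data frames).
#' @export
build_dependency_graph <- function(model) {
  stopifnot(inherits(model, "sd_model"))
  nodes <- names(model$variables)
  inst <- list(); integ <- list()
  for (v in model$variables) {
    missing <- setdiff(v$dependencies, nodes)
    if (length(missing))
      stop("variable '", v$name, "' depends on undeclared variable(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (!length(v$dependencies)) next
    edges <- data.frame(from = v$dependencies, to = v$name,
                        stringsAsFactors = FALSE)
    if (v$role %in% c("stock", "delay")) integ[[v$name]] <- edges
    else inst[[v$name]] <- edges
  }
  empty <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  structure(
    list(nodes = nodes,
         instantaneous_edges = if (length(inst)) do.call(rbind, c(inst, make.row.names = FALSE)) else empty,
         integration_edges = if (length(integ)) do.call(rbind, c(integ, make.row.names = FALSE)) else empty),
    class = "dependency_graph")
}

#' @export
print.dependency_graph <- function(x, ...) {
  cat("<dependency_graph> ", length(x$nodes), " nodes, ",
      nrow(x$instantaneous_edges), " instantaneous and ",
      nrow(x$integration_edges), " integration edges\n", sep = "")
  invisible(x)
}

# adjacency list from an edge data frame, keyed by `from`
.adjacency <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (k in seq_len(nrow(edges)))
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
  lapply(adj, unique)
}

# locate one directed cycle by DFS, for error reporting
.find_cycle <- function(nodes, adj) {
  state <- stats::setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  path <- character(0)
  result <- NULL
  visit <- function(u) {
    if (!is.null(result)) return()
    state[u] <<- 1L
    path <<- c(path, u)
    for (w in adj[[u]]) {
      if (!is.null(result)) return()
      if (state[w] == 1L) {
        result <<- path[seq(match(w, path), length(path))]
        return()
      }
      if (state[w] == 0L) visit(w)
    }
    state[u] <<- 2L
    path <<- path[-length(path)]
  }
  for (u in nodes) if (state[u] == 0L) visit(u)
  result
}

#' Deterministic evaluation order for the instantaneous subgraph
#'
#' Topological sort of the instantaneous dependency subgraph covering every
#' model variable; stocks, constants and delay outputs (no instantaneous
#' in-edges) come first. Ties are broken alphabetically so the order — and
#' hence every simulated trajectory — is reproducible bit for bit.
#'
#' @param graph a [build_dependency_graph()] result.
#' @return character vector of variable names in evaluation order.
#' @export
instantaneous_order <- function(graph) {
  stopifnot(inherits(graph, "dependency_graph"))
  nodes <- sort(graph$nodes)
  edges <- graph$instantaneous_edges
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(edges$to)
  indeg[names(tab)] <- as.integer(tab)
  adj <- .adjacency(nodes, edges)
  order <- character(0)
  ready <- sort(nodes[indeg == 0L])
  while (length(ready)) {
    u <- ready[1L]; ready <- ready[-1L]
    order <- c(order, u)
    for (w in adj[[u]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- sort(c(ready, w))
    }
  }
  if (length(order) < length(nodes)) {
    rest <- setdiff(nodes, order)
    sub <- edges[edges$from %in% rest & edges$to %in% rest, ]
    cyc <- .find_cycle(rest, .adjacency(rest, sub))
    stop("instantaneous dependency cycle among: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  order
}

#' Enumerate feedback loops
#'
#' Returns every elementary cycle of the combined dependency graph
#' (instantaneous plus integration edges) exactly once, up to rotation. Each
#' cycle is reported starting from its alphabetically smallest member.
#'
#' With `collapse_delays = TRUE` each first-order delay node is contracted
#' onto its input before enumeration: a delay only retards a causal link, so
#' the contracted view matches how loops are usually read off a causal-loop
#' diagram (e.g. job satisfaction acting on job performance through a delayed
#' copy is reported as the direct link).
#'
#' @param graph a [build_dependency_graph()] result.
#' @param collapse_delays contract delay states onto their inputs before
#'   enumerating. Requires `delay_inputs`.
#' @param delay_inputs named character vector mapping each delay variable to
#'   its input variable (see [delay_inputs()]); only used when collapsing.
#' @return list of character vectors, each an elementary cycle in causal
#'   order (the edge from the last member back to the first closes the loop),
#'   sorted by length then lexicographically.
#' @export
enumerate_feedback_loops <- function(graph, collapse_delays = FALSE,
                                     delay_inputs = NULL) {
  stopifnot(inherits(graph, "dependency_graph"))
  edges <- rbind(graph$instantaneous_edges, graph$integration_edges)
  nodes <- sort(graph$nodes)
  if (collapse_delays) {
    if (is.null(delay_inputs))
      stop("`delay_inputs` is required when `collapse_delays = TRUE`", call. = FALSE)
    for (d in names(delay_inputs)) {
      src <- delay_inputs[[d]]
      edges$from[edges$from == d] <- src
      edges <- edges[edges$to != d, ]
    }
    edges <- unique(edges[edges$from != edges$to, ])
    nodes <- setdiff(nodes, names(delay_inputs))
  }
  adj <- .adjacency(nodes, edges)
  adj <- lapply(adj, sort)
  loops <- list()
  # rooted DFS: cycles through root r using only nodes >= r, so each
  # elementary cycle is found exactly once, anchored at its smallest member
  for (r in nodes) {
    path <- r
    onpath <- stats::setNames(logical(length(nodes)), nodes)
    onpath[r] <- TRUE
    dfs <- function(u) {
      for (w in adj[[u]]) {
        if (w < r) next
        if (w == r) {
          loops[[length(loops) + 1L]] <<- path
        } else if (!onpath[w]) {
          onpath[w] <<- TRUE
          path <<- c(path, w)
          dfs(w)
          path <<- path[-length(path)]
          onpath[w] <<- FALSE
        }
      }
    }
    dfs(r)
  }
  keys <- vapply(loops, function(l) paste(l, collapse = "\r"), character(1))
  loops[order(lengths(loops), keys)]
}

#' Delay-to-input map of a model
#'
#' @param model an [sd_model()].
#' @return named character vector mapping each delay variable to the
#'   variable it delays.
#' @export
delay_inputs <- function(model) {
  stopifnot(inherits(model, "sd_model"))
  delays <- Filter(function(v) v$role == "delay", model$variables)
  stats::setNames(vapply(delays, `[[`, character(1), "input"),
                  vapply(delays, `[[`, character(1), "name"))
}

#' Is a loop present in an enumeration, up to rotation?
#'
#' @param loops list of cycles as returned by [enumerate_feedback_loops()].
#' @param loop character vector naming one cycle in causal order.
#' @return `TRUE` if `loop` equals one of `loops` up to rotation.
#' @export
has_loop <- function(loops, loop) {
  canon <- function(l) {
    i <- which(l == min(l))[1L]
    paste(c(l[seq(i, length(l))], l[seq_len(i - 1L)]), collapse = "\r")
  }
  canon(loop) %in% vapply(loops, canon, character(1))
}
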