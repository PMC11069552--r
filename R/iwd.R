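#' Construct a soil-weighted graph for water-drop search
#'
#' @param edges data.frame with columns \code{from}, \code{to}, \code{cost}
#'   (positive reals); parallel edges are not allowed.
#' @param source,sink node ids; the sink must be reachable from the source.
#' @return list of class \code{"iwd_graph"} with an adjacency index and a
#'   per-edge soil vector (unset until \code{\link{init_soil}}).
#' @export
iwd_graph <- function(edges, source, sink) {
  stopifnot(is.data.frame(edges),
            all(c("from", "to", "cost") %in% names(edges)))
  edges$from <- as.character(edges$from); edges$to <- as.character(edges$to)
  if (any(edges$cost <= 0)) stop("edge costs must be positive")
  if (anyDuplicated(edges[, c("from", "to")]))
    stop("parallel edges are not allowed")
  nodes <- sort(unique(c(edges$from, edges$to)))
  if (!source %in% nodes || !sink %in% nodes)
    stop("source/sink must be graph nodes")
  # breadth-first reachability check
  seen <- source; frontier <- source
  while (length(frontier)) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  if (!sink %in% seen)
    stop("sink '", sink, "' is not reachable from source '", source, "'")
  adj <- split(seq_len(nrow(edges)), edges$from)
  structure(list(nodes = nodes, edges = edges, soil = rep(NA_real_,
                 nrow(edges)), adj = adj, source = source, sink = sink),
            class = "iwd_graph")
}

#' @export
print.iwd_graph <- function(x, ...) {
  cat("Water-drop graph:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges;", x$source, "->", x$sink, "\n")
  invisible(x)
}

#' Configure the water-drop search
#'
#' Defaults follow the conventional settings of the water-drops literature:
#' velocity-update parameters \code{p_u = 1, q_u = 0.01, o_u = 1}, initial
#' soil 1000 on every edge, initial drop velocity 4, local soil-update rate
#' \code{g_y = 0.9}, global reinforcement rate \code{g_m = 0.9}, 20 drops,
#' 50 iterations.
#'
#' @param n_drops drops released per iteration.
#' @param max_iterations iterations.
#' @param p_u,q_u,o_u velocity/soil kinetics parameters (\code{q_u > 0}).
#' @param initial_soil soil placed on every edge by \code{\link{init_soil}}.
#' @param initial_velocity starting velocity of each drop.
#' @param local_soil_rate \code{g_y} in (0,1).
#' @param global_soil_rate \code{g_m}.
#' @param epsilon_prob small constant in the edge-preference function.
#' @param classic_global_update if \code{TRUE}, the global update also
#'   subtracts the best drop's carried soil (the classical variant); by
#'   default the best path's soil is simply amplified by \code{1 + g_m},
#'   which reinforces because repeated local updates drive good-path soils
#'   negative.
#' @param seed integer seed.
#' @return a list of class \code{"iwd_config"}.
#' @export
iwd_config <- function(n_drops = 20, max_iterations = 50,
                       p_u = 1, q_u = 0.01, o_u = 1,
                       initial_soil = 1000, initial_velocity = 4,
                       local_soil_rate = 0.9, global_soil_rate = 0.9,
                       epsilon_prob = 5, classic_global_update = FALSE,
                       seed = 1L) {
  stopifnot(q_u > 0, local_soil_rate > 0, local_soil_rate < 1,
            n_drops >= 1, max_iterations >= 1)
  structure(list(n_drops = n_drops, max_iterations = max_iterations,
                 p_u = p_u, q_u = q_u, o_u = o_u,
                 initial_soil = initial_soil,
                 initial_velocity = initial_velocity,
                 local_soil_rate = local_soil_rate,
                 global_soil_rate = global_soil_rate,
                 epsilon_prob = epsilon_prob,
                 classic_global_update = classic_global_update,
                 seed = as.integer(seed)),
            class = "iwd_config")
}

#' Reset every edge's soil to the initial value
#' @param graph an \code{\link{iwd_graph}}.
#' @param config an \code{\link{iwd_config}}.
#' @return the graph with \code{soil} set on every edge.
#' @export
init_soil <- function(graph, config) {
  graph$soil <- rep(config$initial_soil, nrow(graph$edges))
  graph
}

#' Transition probabilities of a drop over unvisited neighbours
#'
#' Preference for low-soil edges: \code{p(j) = Fit(soil(i,j)) / sum_k
#' Fit(soil(i,k))} with \code{Fit(s) = 1 / (epsilon + shift(s))}, where the
#' candidate soils are shifted by their minimum whenever that minimum is
#' negative, keeping the arguments positive after local updates erode soil
#' below zero.
#'
#' @param soils soil values of the candidate edges.
#' @param config an \code{\link{iwd_config}}.
#' @return probability vector over candidates (sums to 1).
#' @export
transition_probability <- function(soils, config) {
  if (!length(soils)) stop("dead end: no unvisited candidates")
  mn <- min(soils)
  shifted <- if (mn < 0) soils - mn else soils
  fit <- 1 / (config$epsilon_prob + shifted)
  fit / sum(fit)
}

#' Velocity update after traversing an edge
#'
#' \code{v' = v + p_u / (q_u + o_u * soil^2)}.
#'
#' @param velocity current velocity.
#' @param soil soil of the traversed edge.
#' @param config an \code{\link{iwd_config}}.
#' @return updated velocity.
#' @export
update_velocity <- function(velocity, soil, config) {
  velocity + config$p_u / (config$q_u + config$o_u * soil^2)
}

#' Soil carried off an edge by a drop
#'
#' \code{delta = p_u / (q_u + o_u * T^2)} with travel time
#' \code{T = cost / max(velocity, 1e-6)}.
#'
#' @param cost edge cost.
#' @param velocity drop velocity (after its update on this edge).
#' @param config an \code{\link{iwd_config}}.
#' @return the soil increment (always positive).
#' @export
soil_delta <- function(cost, velocity, config) {
  tt <- cost / max(velocity, 1e-6)
  config$p_u / (config$q_u + config$o_u * tt^2)
}

#' Local soil update on a traversed edge
#'
#' \code{soil' = (1 - g_y) * soil - g_y * delta}; the drop's carried soil
#' increases by \code{delta}.
#'
#' @param soil current edge soil.
#' @param delta \code{\link{soil_delta}} value.
#' @param config an \code{\link{iwd_config}}.
#' @return updated edge soil.
#' @export
local_soil_update <- function(soil, delta, config) {
  (1 - config$local_soil_rate) * soil - config$local_soil_rate * delta
}

#' Pick the iteration-best path
#'
#' Arg-max of the quality function over completed paths; ties broken toward
#' the lexicographically smaller node sequence.
#'
#' @param paths list of node-id vectors (source to sink).
#' @param qualities quality value per path (higher is better).
#' @return index of the best path.
#' @export
iteration_best_path <- function(paths, qualities) {
  if (!length(paths)) stop("no completed paths")
  best <- max(qualities)
  cand <- which(qualities == best)
  if (length(cand) == 1) return(cand)
  keys <- vapply(paths[cand], paste, character(1), collapse = "\x01")
  cand[order(keys)[1]]
}

#' Global soil reinforcement of the best path
#'
#' Every edge on the best path gets \code{soil <- (1 + g_m) * soil}; with
#' \code{classic_global_update}, \code{g_m * carried / (path length - 1)} is
#' additionally subtracted.
#'
#' @param graph an \code{\link{iwd_graph}} with soil set.
#' @param path node-id vector of the best path.
#' @param config an \code{\link{iwd_config}}.
#' @param carried soil carried by the best drop (classical variant only).
#' @return the updated graph.
#' @export
global_soil_reinforce <- function(graph, path, config, carried = 0) {
  for (k in seq_len(length(path) - 1L)) {
    e <- which(graph$edges$from == path[k] & graph$edges$to == path[k + 1L])
    if (!length(e)) stop("path edge ", path[k], "->", path[k + 1L],
                         " not in graph")
    graph$soil[e] <- (1 + config$global_soil_rate) * graph$soil[e]
    if (config$classic_global_update)
      graph$soil[e] <- graph$soil[e] -
        config$global_soil_rate * carried / max(1L, length(path) - 1L)
  }
  graph
}

#' Intelligent water drops search for the best source-sink path
#'
#' Each iteration releases \code{n_drops} drops at the source; every drop
#' walks to the sink choosing unvisited neighbours with soil-preference
#' probabilities, accelerating and eroding soil as it goes. The
#' iteration-best path is reinforced globally, and the overall best path
#' (by quality) is tracked across iterations.
#'
#' @param graph an \code{\link{iwd_graph}}.
#' @param config an \code{\link{iwd_config}}.
#' @param quality function from a node-id path to a quality value (higher is
#'   better); default \code{1 / total path cost}.
#' @return list of class \code{"iwd_result"}: \code{best_path},
#'   \code{best_quality}, \code{history} (best-so-far quality per
#'   iteration, non-decreasing), \code{iteration_best} (per-iteration best
#'   quality or NA when no drop completed).
#' @export
iwd_optimize <- function(graph, config = iwd_config(), quality = NULL) {
  stopifnot(inherits(graph, "iwd_graph"), inherits(config, "iwd_config"))
  path_cost <- function(path) {
    s <- 0
    for (k in seq_len(length(path) - 1L)) {
      e <- which(graph$edges$from == path[k] & graph$edges$to == path[k + 1L])
      s <- s + graph$edges$cost[e]
    }
    s
  }
  quality <- quality %||% function(path) 1 / path_cost(path)
  graph <- init_soil(graph, config)
  with_seed(config$seed, {
    best_path <- NULL; best_q <- -Inf
    history <- numeric(config$max_iterations)
    it_best <- rep(NA_real_, config$max_iterations)
    for (it in seq_len(config$max_iterations)) {
      done_paths <- list(); done_carried <- numeric(0)
      for (dr in seq_len(config$n_drops)) {
        node <- graph$source
        visited <- node
        vel <- config$initial_velocity
        carried <- 0
        ok <- TRUE
        while (node != graph$sink) {
          out <- graph$adj[[node]]
          out <- out[!(graph$edges$to[out] %in% visited)]
          if (!length(out)) { ok <- FALSE; break }   # dead end, drop discarded
          pr <- transition_probability(graph$soil[out], config)
          e <- out[sample.int(length(out), 1, prob = pr)]
          vel <- update_velocity(vel, graph$soil[e], config)
          dlt <- soil_delta(graph$edges$cost[e], vel, config)
          graph$soil[e] <- local_soil_update(graph$soil[e], dlt, config)
          carried <- carried + dlt
          node <- graph$edges$to[e]
          visited <- c(visited, node)
        }
        if (ok) {
          done_paths[[length(done_paths) + 1L]] <- visited
          done_carried <- c(done_carried, carried)
        }
      }
      if (length(done_paths)) {
        qs <- vapply(done_paths, quality, numeric(1))
        bi <- iteration_best_path(done_paths, qs)
        graph <- global_soil_reinforce(graph, done_paths[[bi]], config,
                                       carried = done_carried[bi])
        it_best[it] <- qs[bi]
        if (qs[bi] > best_q) { best_q <- qs[bi]; best_path <- done_paths[[bi]] }
      }
      history[it] <- best_q
    }
    if (is.null(best_path))
      stop("no drop ever reached the sink")
    structure(list(best_path = best_path, best_quality = best_q,
                   history = history, iteration_best = it_best),
              class = "iwd_result")
  })
}

#' @export
print.iwd_result <- function(x, ...) {
  cat("Water-drop search: best quality",
      format(x$best_quality, digits = 5), "via path",
      paste(x$best_path, collapse = " -> "), "\n")
  invisible(x)
}

#' Enumerate all simple source-sink paths (oracle helper)
#'
#' Exhaustive depth-first enumeration; intended for small graphs in tests
#' and as the brute-force reference for the search.
#'
#' @param graph an \code{\link{iwd_graph}}.
#' @return list of node-id paths.
#' @export
enumerate_paths <- function(graph) {
  out <- list()
  walk <- function(node, path) {
    if (node == graph$sink) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (e in graph$adj[[node]]) {
      nxt <- graph$edges$to[e]
      if (!(nxt %in% path)) walk(nxt, c(path, nxt))
    }
  }
  walk(graph$source, graph$source)
  out
}

#' Tune hyper-parameters over candidate grids by water-drop search
#'
#' Builds a layered graph — source, one layer per hyper-parameter with a
#' node per candidate value, full bipartite links between consecutive
#' layers, then the sink — and searches it with
#' \code{\link{iwd_optimize}}. A path selects one value per grid; its
#' quality is the validation score of that configuration, evaluated once
#' and cached.
#'
#' @param grids named list of candidate-value vectors.
#' @param evaluate function taking a named list of values, returning a
#'   validation score (higher is better); failures score \code{-Inf}.
#' @param config an \code{\link{iwd_config}}.
#' @return list with \code{best} (named list of chosen values),
#'   \code{best_score}, \code{evaluations} (configurations actually
#'   evaluated), \code{result} (the \code{iwd_result}).
#' @export
tune_loss_parameter <- function(grids, evaluate, config = iwd_config()) {
  stopifnot(length(grids) >= 1, all(lengths(grids) >= 1))
  if (is.null(names(grids)) || any(names(grids) == ""))
    stop("grids must be named")
  layers <- names(grids)
  node_id <- function(l, k) sprintf("L%d.%d", l, k)
  edges <- list()
  prev <- "src"
  for (l in seq_along(layers)) {
    cur <- vapply(seq_along(grids[[l]]), function(k) node_id(l, k),
                  character(1))
    edges[[l]] <- expand.grid(from = prev, to = cur,
                              stringsAsFactors = FALSE)
    prev <- cur
  }
  edges[[length(edges) + 1L]] <- data.frame(from = prev, to = "snk",
                                            stringsAsFactors = FALSE)
  edges <- do.call(rbind, edges)
  edges$cost <- 1
  graph <- iwd_graph(edges, "src", "snk")
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  decode <- function(path) {
    inner <- path[-c(1, length(path))]
    idx <- as.integer(sub("^L\\d+\\.", "", inner))
    stats::setNames(lapply(seq_along(layers),
                           function(l) grids[[l]][idx[l]]), layers)
  }
  quality <- function(path) {
    key <- paste(path, collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- tryCatch(evaluate(decode(path)), error = function(e) {
      warning("configuration failed: ", conditionMessage(e)); -Inf
    })
    n_eval <<- n_eval + 1L
    cache[[key]] <- v
    v
  }
  res <- iwd_optimize(graph, config, quality)
  list(best = decode(res$best_path), best_score = res$best_quality,
       evaluations = n_eval, result = res)
}
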