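# Planarity testing via Demoucron's vertex-addition algorithm.
#
# A graph is planar iff each biconnected component is planar; each
# component is tested by growing a planar embedding from an initial cycle,
# repeatedly embedding a path of some bridge into an admissible face.
# Demoucron's greedy face choice is correct when the bridge with the
# fewest admissible faces is processed first. Intended for the small
# graphs this package produces; complexity is quadratic.

#' Test whether a graph is planar
#'
#' @param g an igraph object, or a two-column edge matrix/data frame.
#' @return logical scalar.
#' @examples
#' is_planar_graph(igraph::make_full_graph(4)) # TRUE
#' is_planar_graph(igraph::make_full_graph(5)) # FALSE (K5)
#' @export
is_planar_graph <- function(g) {
  if (!igraph::is_igraph(g)) {
    el <- as.matrix(g)
    g <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                                     directed = FALSE)
  }
  g <- igraph::simplify(igraph::as_undirected(g))
  if (igraph::ecount(g) == 0) return(TRUE)
  bic <- igraph::biconnected_components(g)
  for (comp_edges in bic$component_edges) {
    sub <- igraph::subgraph_from_edges(g, comp_edges, delete.vertices = TRUE)
    if (!demoucron_planar(sub)) return(FALSE)
  }
  TRUE
}

demoucron_planar <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n < 5 || m < 9) return(TRUE)     # K5 and K3,3 need >= 9 edges
  if (m > 3 * n - 6) return(FALSE)
  adj <- lapply(igraph::as_adj_list(g), as.integer)

  edge_key <- function(u, v) paste(min(u, v), max(u, v))
  all_edges <- igraph::as_edgelist(g, names = FALSE)
  n_edges <- nrow(all_edges)

  cyc <- find_cycle(adj)
  if (is.null(cyc)) return(TRUE)        # acyclic: trivially planar

  embedded_v <- logical(n)
  embedded_v[cyc] <- TRUE
  embedded_e <- new.env(parent = emptyenv())
  k <- length(cyc)
  for (i in seq_len(k)) {
    assign(edge_key(cyc[i], cyc[i %% k + 1]), TRUE, envir = embedded_e)
  }
  faces <- list(cyc, rev(cyc))
  n_embedded <- k

  while (n_embedded < n_edges) {
    frags <- find_fragments(adj, all_edges, embedded_v, embedded_e)
    if (length(frags) == 0) break
    # admissible faces per fragment
    best <- NULL
    best_faces <- NULL
    for (fr in frags) {
      adm <- which(vapply(faces,
                          function(f) all(fr$attach %in% f), TRUE))
      if (length(adm) == 0) return(FALSE)
      if (is.null(best) || length(adm) < length(best_faces)) {
        best <- fr
        best_faces <- adm
        if (length(adm) == 1) break
      }
    }
    path <- fragment_path(best, adj, embedded_v)
    a <- path[1]
    b <- path[length(path)]
    mid <- path[-c(1, length(path))]
    # embed path
    embedded_v[mid] <- TRUE
    for (i in seq_len(length(path) - 1)) {
      assign(edge_key(path[i], path[i + 1]), TRUE, envir = embedded_e)
    }
    n_embedded <- n_embedded + length(path) - 1
    # split the chosen face along the path
    fi <- best_faces[1]
    f <- faces[[fi]]
    ia <- match(a, f)
    ib <- match(b, f)
    if (ia <= ib) {
      seg1 <- f[ia:ib]
      seg2 <- c(f[ib:length(f)], f[seq_len(ia)])
    } else {
      seg1 <- c(f[ia:length(f)], f[seq_len(ib)])
      seg2 <- f[ib:ia]
    }
    faces[[fi]] <- c(seg1, rev(mid))
    faces[[length(faces) + 1]] <- c(seg2, mid)
  }
  TRUE
}

# DFS for any cycle; returns the cycle's vertices in order, or NULL.
find_cycle <- function(adj) {
  n <- length(adj)
  parent <- integer(n)
  state <- integer(n) # 0 unseen, 1 active, 2 done
  for (root in seq_len(n)) {
    if (state[root] != 0) next
    stack <- root
    parent[root] <- 0L
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      if (state[v] == 0) state[v] <- 1L
      nxt <- 0L
      for (u in adj[[v]]) {
        if (u == parent[v]) next
        if (state[u] == 1L) {
          # back edge v-u: recover cycle u .. v
          cyc <- v
          w <- v
          while (w != u) {
            w <- parent[w]
            cyc <- c(cyc, w)
          }
          return(cyc)
        }
        if (state[u] == 0L) {
          nxt <- u
          break
        }
      }
      if (nxt > 0L) {
        parent[nxt] <- v
        stack <- c(stack, nxt)
      } else {
        state[v] <- 2L
        stack <- stack[-length(stack)]
      }
    }
  }
  NULL
}

# Bridges (fragments) of the graph relative to the embedded subgraph.
find_fragments <- function(adj, all_edges, embedded_v, embedded_e) {
  n <- length(adj)
  edge_key <- function(u, v) paste(min(u, v), max(u, v))
  frags <- list()
  # single non-embedded edges joining two embedded vertices
  for (r in seq_len(nrow(all_edges))) {
    u <- all_edges[r, 1]; v <- all_edges[r, 2]
    if (embedded_v[u] && embedded_v[v] &&
        !exists(edge_key(u, v), envir = embedded_e)) {
      frags[[length(frags) + 1]] <-
        list(attach = c(u, v), internal = integer(0))
    }
  }
  # components of the non-embedded vertices plus their attachments
  seen <- logical(n)
  for (s in seq_len(n)) {
    if (embedded_v[s] || seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (u in adj[[v]]) {
        if (!embedded_v[u] && !seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    attach <- unique(unlist(lapply(comp, function(v) {
      adj[[v]][embedded_v[adj[[v]]]]
    })))
    frags[[length(frags) + 1]] <- list(attach = attach, internal = comp)
  }
  frags
}

# A path through the fragment between two attachment vertices.
fragment_path <- function(fr, adj, embedded_v) {
  if (length(fr$internal) == 0) return(fr$attach[1:2])
  internal <- fr$internal
  a <- fr$attach[1]
  # BFS from a through internal vertices to any other attachment
  start <- intersect(adj[[a]], internal)
  prev <- integer(length(adj))
  seen <- logical(length(adj))
  queue <- start
  seen[start] <- TRUE
  prev[start] <- a
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) {
      if (u != a && embedded_v[u] && u %in% fr$attach) {
        # found endpoint b = u; reconstruct
        path <- c(u, v)
        w <- v
        while (prev[w] != a) {
          w <- prev[w]
          path <- c(path, w)
        }
        return(rev(c(path, a)))
      }
      if (!embedded_v[u] && !seen[u] && u %in% internal) {
        seen[u] <- TRUE
        prev[u] <- v
        queue <- c(queue, u)
      }
    }
  }
  rlang::abort("internal error: fragment path not found")
}
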