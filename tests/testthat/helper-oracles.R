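# Hand-written graph oracles, independent of the igraph-backed implementation.

# breadth-first shortest-path distances from `from` on an undirected edge list
bfs_undirected_dist <- function(S, edges, from) {
  adj <- vector("list", S)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  dist <- rep(NA_integer_, S)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# directed BFS distance from every node to the nearest node in `targets`,
# following edges consumer -> resource
bfs_directed_to <- function(S, edges, targets) {
  out <- rep(NA_integer_, S)
  for (v in seq_len(S)) {
    dist <- rep(NA_integer_, S)
    dist[v] <- 0L
    frontier <- v
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (u in frontier) {
        succ <- edges[edges[, 1L] == u, 2L]
        for (w in succ) {
          if (is.na(dist[w])) {
            dist[w] <- dist[u] + 1L
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    d <- dist[targets]
    out[v] <- if (all(is.na(d))) NA_integer_ else min(d, na.rm = TRUE)
  }
  out
}

# trophic levels by definition: 1 for producers, else 1 + shortest directed
# path to any producer
oracle_trophic_levels <- function(S, edges) {
  producers <- setdiff(seq_len(S), unique(edges[, 1L]))
  if (length(producers) == 0L) return(NULL)
  d <- bfs_directed_to(S, edges, producers)
  if (anyNA(d)) return(NULL)
  1L + d
}

# mean undirected shortest-path length over all unordered pairs (NA if any
# pair is unreachable)
oracle_mean_path_length <- function(S, edges) {
  tot <- 0
  npairs <- 0L
  for (v in seq_len(S)) {
    d <- bfs_undirected_dist(S, edges, v)
    others <- setdiff(seq_len(S), v)
    if (anyNA(d[others])) return(NA_real_)
    tot <- tot + sum(d[others])
    npairs <- npairs + length(others)
  }
  tot / npairs
}

oracle_is_connected <- function(S, edges) {
  if (S == 1L) return(TRUE)
  !anyNA(bfs_undirected_dist(S, edges, 1L))
}

# all digraphs without self-loops on n nodes, as edge-list matrices
enumerate_digraphs <- function(n) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- as.matrix(pairs[pairs$from != pairs$to, ])
  m <- nrow(pairs)
  lapply(0:(2^m - 1L), function(mask) {
    sel <- bitwAnd(rep(mask, m), bitwShiftL(1L, seq_len(m) - 1L)) != 0L
    pairs[sel, , drop = FALSE]
  })
}

random_digraph <- function(n, p) {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- as.matrix(pairs[pairs$from != pairs$to, ])
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

edges_to_web <- function(S, edges) {
  structure(list(S = as.integer(S),
                 links = data.frame(consumer = as.integer(edges[, 1L]),
                                    resource = as.integer(edges[, 2L])),
                 niche = rep(NA_real_, S), target_C = NA_real_, seed = NULL),
            class = "food_web")
}

# hand-assembled community from explicit parameter tables
make_community <- function(species, links, B_star, tims = NULL) {
  web <- edges_to_web(nrow(species),
                      cbind(links$consumer, links$resource))
  structure(list(web = web, species = species, links = links,
                 B_star = B_star, tims = tims),
            class = "community")
}

# small producer-consumer pair with an optional third modifier species
chain_community <- function(K1 = 5, a = 0.2, e = 0.1, r2 = -0.05, K2 = 500) {
  species <- data.frame(M = c(1, 16), r = c(1, r2), K = c(K1, K2),
                        m = c(0, 0), level = c(1L, 2L))
  links <- data.frame(resource = 1L, consumer = 2L, a = a, e = e, omega = 1)
  # algebraic interior equilibrium of the 2x2 linear system
  A <- rbind(c(1 / K1, a), c(-e * a, 1 / K2))
  Bstar <- solve(A, c(1, r2))
  make_community(species, links, Bstar)
}
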