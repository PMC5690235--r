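# Independent brute-force oracles. These deliberately share no code with
# the package internals: the Dijkstra oracle relaxes an explicit edge
# list to a fixed point, the accumulation oracle counts upstream sets by
# path-following, and the Strahler oracle is a direct recursion on the
# textbook rules.

# Internal entry points exercised directly in low-level tests.
flow_accum_cpp <- emocaccess:::flow_accum_cpp
strahler_cpp <- emocaccess:::strahler_cpp
cost_distance_cpp <- emocaccess:::cost_distance_cpp

# Neighbour enumeration must match the documented convention.
NBR <- cbind(dr = c(0, 1, 1, 1, 0, -1, -1, -1),
             dc = c(1, 1, 0, -1, -1, -1, 0, 1))

# Shortest travel time by label-correcting relaxation over the explicit
# edge list; pace in min/m, non-finite = barrier.
dijkstra_oracle <- function(pace, sources, cellsize) {
  nr <- nrow(pace); nc <- ncol(pace)
  tt <- matrix(Inf, nr, nc)
  for (i in seq_len(nrow(sources))) tt[sources$row[i], sources$col[i]] <- 0
  edges <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!is.finite(pace[r, c])) next
    for (k in 1:8) {
      rr <- r + NBR[k, 1]; cc <- c + NBR[k, 2]
      if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
      if (!is.finite(pace[rr, cc])) next
      d <- if (NBR[k, 1] != 0 && NBR[k, 2] != 0) sqrt(2) * cellsize else cellsize
      edges[[length(edges) + 1L]] <-
        c(r, c, rr, cc, d * (pace[r, c] + pace[rr, cc]) / 2)
    }
  }
  repeat {
    changed <- FALSE
    for (e in edges) {
      cand <- tt[e[1], e[2]] + e[5]
      if (cand < tt[e[3], e[4]] - 1e-15) {
        tt[e[3], e[4]] <- cand
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  tt
}

# Contributing area by path-following: cell j contributes to i if the
# D8 path from j passes through i. dir uses codes 0 (sink) / 1..8.
accum_oracle <- function(dir) {
  nr <- nrow(dir); nc <- ncol(dir)
  acc <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    cr <- r; cc <- c
    for (step in seq_len(nr * nc + 1L)) {
      acc[cr, cc] <- acc[cr, cc] + 1
      d <- dir[cr, cc]
      if (d == 0) break
      cr2 <- cr + NBR[d, 1]; cc2 <- cc + NBR[d, 2]
      cr <- cr2; cc <- cc2
    }
  }
  acc
}

# Direct recursive Strahler ordering of stream cells.
strahler_oracle <- function(dir, acc, threshold) {
  nr <- nrow(dir); nc <- ncol(dir)
  ord_of <- function(r, c) {
    inflow <- integer(0)
    for (k in 1:8) {
      rr <- r + NBR[k, 1]; cc <- c + NBR[k, 2]
      if (rr < 1 || cc < 1 || rr > nr || cc > nc) next
      d <- dir[rr, cc]
      if (d > 0 && rr + NBR[d, 1] == r && cc + NBR[d, 2] == c &&
          acc[rr, cc] >= threshold)
        inflow <- c(inflow, ord_of(rr, cc))
    }
    if (length(inflow) == 0) return(1L)
    m <- max(inflow)
    if (sum(inflow == m) >= 2) m + 1L else m
  }
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    if (acc[r, c] >= threshold) out[r, c] <- ord_of(r, c)
  out
}

# Random pace grid with a sprinkling of barrier cells; guarantees at
# least one traversable cell.
random_pace <- function(n, seed, barrier_frac = 0.15) {
  set.seed(seed)
  p <- matrix(stats::runif(n * n, 0.001, 0.05), n, n)
  p[stats::runif(n * n) < barrier_frac] <- Inf
  if (!any(is.finite(p))) p[1, 1] <- 0.02
  p
}

# A hand-laid flow-direction grid: a vertical stream down column `col`
# fed so that accumulation passes `threshold` from the first cell.
# Codes: 3 = south, 1 = east, 5 = west.
make_confluence <- function() {
  # 7 x 7: two headwater streams (columns 2 and 6) flowing south, joining
  # at row 4 into column 4 via east/west flow, then continuing south.
  dir <- matrix(0L, 7, 7)
  dir[1:3, 2] <- 3L   # west tributary flows south
  dir[1:3, 6] <- 3L   # east tributary flows south
  dir[4, 2] <- 1L; dir[4, 3] <- 1L   # west arm turns east
  dir[4, 6] <- 5L; dir[4, 5] <- 5L   # east arm turns west
  dir[4:6, 4] <- 3L                  # combined stream south
  dir
}
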