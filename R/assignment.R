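#' Solve the linear assignment problem
#'
#' Minimum-cost perfect matching on a square cost matrix (Jonker-Volgonant
#' style shortest augmenting path with potentials, O(n^3)). Deterministic:
#' ties are resolved by matrix order.
#'
#' @param cost a square numeric matrix of finite costs.
#' @return an integer vector `m` with `m[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 1) return(1L)
  # columns indexed 0..n stored at offset +1; p[j+1] = row assigned to col j
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      free <- which(!used[2:(n + 1)])
      cur <- cost[i0, free] - u[i0 + 1] - v[free + 1]
      upd <- cur < minv[free + 1]
      if (any(upd)) {
        minv[free[upd] + 1] <- cur[upd]
        way[free[upd] + 1] <- j0
      }
      k <- which.min(minv[free + 1])
      delta <- minv[free[k] + 1]; j1 <- free[k]
      us <- which(used)
      u[p[us] + 1] <- u[p[us] + 1] + delta
      v[us] <- v[us] - delta
      minv[!used] <- minv[!used] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) match[p[j + 1]] <- j
  match
}

# Match one set of track endpoints to one set of detections, minimizing the
# total squared displacement over feasible pairs (distance <= budget) with a
# per-node unmatched penalty of budget^2. Any feasible link is preferred
# over leaving both ends unmatched, so the matching has maximum cardinality
# among feasible edges and, among those, minimum total squared displacement.
# Returns an integer vector: for each track, the matched detection index or
# NA.
match_pairs <- function(tx, ty, dx, dy, budget) {
  nT <- length(tx); nD <- length(dx)
  if (nT == 0 || nD == 0) return(rep(NA_integer_, nT))
  d2 <- outer(tx, dx, "-")^2 + outer(ty, dy, "-")^2
  B <- budget^2
  LARGE <- 4 * B + 1
  n <- nT + nD
  M <- matrix(0, n, n)
  M[seq_len(nT), seq_len(nD)] <- ifelse(d2 <= B, d2, LARGE)
  M[seq_len(nT), nD + seq_len(nT)] <- LARGE
  M[cbind(seq_len(nT), nD + seq_len(nT))] <- B
  M[nT + seq_len(nD), seq_len(nD)] <- LARGE
  M[cbind(nT + seq_len(nD), seq_len(nD))] <- B
  m <- solve_assignment(M)
  out <- rep(NA_integer_, nT)
  for (i in seq_len(nT)) {
    j <- m[i]
    if (j <= nD && d2[i, j] <= B) out[i] <- j
  }
  out
}

# Total cost of a matching under the match_pairs objective; used by the
# linker to report per-frame-pair costs comparable to an exhaustive oracle.
matching_cost <- function(tx, ty, dx, dy, budget, match) {
  B <- budget^2
  cost <- 0
  for (i in seq_along(match)) {
    j <- match[i]
    cost <- cost + if (is.na(j)) B else (tx[i] - dx[j])^2 + (ty[i] - dy[j])^2
  }
  cost + B * (length(dx) - sum(!is.na(match)))
}
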