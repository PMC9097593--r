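# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and direct evaluation.

# All permutations of a vector (small n only).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# Brute-force minimum assignment cost of a square matrix.
brute_assignment_cost <- function(M) {
  n <- nrow(M)
  min(vapply(all_perms(seq_len(n)),
             function(p) sum(M[cbind(seq_len(n), p)]), 0))
}

# Brute-force optimal track/detection matching under the linker's objective:
# sum of squared displacements of linked pairs plus budget^2 per unmatched
# node on either side; links farther than `budget` are forbidden. Enumerates
# every injective partial matching.
brute_match_cost <- function(tx, ty, dx, dy, budget) {
  nT <- length(tx); nD <- length(dx)
  B <- budget^2
  best <- Inf
  assign_rec <- function(i, used, cost) {
    if (cost >= best) return()
    if (i > nT) {
      total <- cost + B * sum(!used)
      if (total < best) best <<- total
      return()
    }
    assign_rec(i + 1, used, cost + B)  # track i unmatched
    for (j in which(!used)) {
      d2 <- (tx[i] - dx[j])^2 + (ty[i] - dy[j])^2
      if (d2 <= B) {
        used[j] <- TRUE
        assign_rec(i + 1, used, cost + d2)
        used[j] <- FALSE
      }
    }
  }
  assign_rec(1, rep(FALSE, nD), 0)
  best
}

# Exhaustive Mann-Whitney: enumerate all C(n, na) splits of the pooled
# sample, compute U (ties counted one half) for each, and derive the
# two-sided p as 2 * min(P(U <= u), P(U >= u)), capped at 1.
brute_mwu <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  u_of <- function(av, bv) {
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  u_obs <- u_of(a, b)
  splits <- combn(n, na)
  us <- apply(splits, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  list(U = u_obs,
       p = min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps))))
}

# Direct O(n^2) mean filter with replicate borders over a circular
# neighbourhood (independent of the package's FFT path).
naive_disk_mean <- function(img, radius) {
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- matrix(0, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    rr <- pmin(pmax(r + offs$dr, 1), H)
    cc <- pmin(pmax(c + offs$dc, 1), W)
    out[r, c] <- mean(img[cbind(rr, cc)])
  }
  out
}

# A clean isolated Gaussian spot frame for localization tests.
gaussian_spot_frame <- function(H, W, cx, cy, sigma = 2, peak = 1,
                                noise_sd = 0, seed = NULL) {
  xs <- 0:(W - 1); ys <- 0:(H - 1)
  f <- peak * exp(-outer((ys - cy)^2, (xs - cx)^2, "+") / (2 * sigma^2))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    f <- f + matrix(rnorm(H * W, 0, noise_sd), H, W)
  }
  f
}
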