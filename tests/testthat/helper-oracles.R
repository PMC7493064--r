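# Independent reference implementations used as oracles. Deliberately naive
# (mean-based formula, explicit loops) so they share no code with the package
# internals they check.

oracle_cusum <- function(x, s, e, b) {
  n <- e - s + 1
  n_l <- b - s + 1
  n_r <- e - b
  sqrt(n_l * n_r / n) * (mean(x[s:b]) - mean(x[(b + 1):e]))
}

oracle_max_cusum <- function(x, s, e, robust = FALSE) {
  if (robust) {
    seg <- x[s:e]
    x <- replace(x, s:e, sign(seg - median(seg)))
  }
  best <- list(b = s, contrast = oracle_cusum(x, s, e, s))
  for (b in s:(e - 1)) {
    ct <- oracle_cusum(x, s, e, b)
    if (abs(ct) > abs(best$contrast)) best <- list(b = b, contrast = ct)
  }
  best$magnitude <- abs(best$contrast)
  best
}

# best (magnitude, split) over every sub-interval; ties: smallest b, shortest
# interval — mirrors the recursion's selection rule
oracle_best_everywhere <- function(x, s, e) {
  best <- NULL
  for (a in s:(e - 1)) for (z in (a + 1):e) {
    m <- oracle_max_cusum(x, a, z)
    cand <- c(mag = m$magnitude, b = m$b, len = z - a)
    if (is.null(best) ||
        cand["mag"] > best["mag"] + 1e-12 ||
        (abs(cand["mag"] - best["mag"]) <= 1e-12 &&
         (cand["b"] < best["b"] ||
          (cand["b"] == best["b"] && cand["len"] < best["len"])))) {
      best <- cand
    }
  }
  best
}

# literal transcription of the selection rule, evaluated by exhaustive search
# over candidate sizes rather than vectorised index arithmetic
oracle_sdll <- function(mags, zeta, beta) {
  if (mags[1] < zeta) return(0L)
  s <- c(mags, 0)
  best_j <- NA_integer_
  best_drop <- -Inf
  for (j in seq_along(mags)) {
    if (s[j] >= beta * zeta && s[j + 1] < zeta) {
      drop <- if (s[j + 1] == 0) Inf else log(s[j]) - log(s[j + 1])
      if (drop > best_drop) {
        best_drop <- drop
        best_j <- j
      }
    }
  }
  if (!is.na(best_j)) return(best_j)
  max(which(mags >= zeta))
}

# replay the depth-first recursion from the recorded split locations to
# recover each path entry's current segment and its parent entry
replay_segments <- function(path) {
  n_obs <- attr(path, "n_obs")
  seg_s <- integer(nrow(path)); seg_e <- integer(nrow(path))
  parent <- integer(nrow(path))
  stack <- list(c(1L, n_obs, 0L))  # s, e, parent order (0 = root)
  for (k in seq_len(nrow(path))) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    seg_s[k] <- seg[1]; seg_e[k] <- seg[2]; parent[k] <- seg[3]
    b <- path$location[k]
    stopifnot(b >= seg[1], b <= seg[2] - 1L)
    if (seg[2] - (b + 1L) >= 1L) stack[[length(stack) + 1L]] <- c(b + 1L, seg[2], k)
    if (b - seg[1] >= 1L) stack[[length(stack) + 1L]] <- c(seg[1], b, k)
  }
  data.frame(order = path$order, seg_start = seg_s, seg_end = seg_e,
             parent = parent)
}

# sample a single element from a vector (sample() treats a length-1 numeric
# vector as 1:n, which is never what these tests mean)
sample1 <- function(v) v[sample.int(length(v), 1L)]
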