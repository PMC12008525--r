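# Independent oracles and random-structure generators used across the suite.
# These deliberately use explicit scalar loops / recursion so they share no
# code path with the vectorized implementations they check.

# random valid pair map, frequently pseudoknotted: greedily pick disjoint
# index pairs with separation >= 4
random_pair_map <- function(L, max_pairs = floor(L / 3)) {
  avail <- seq_len(L)
  pairs <- NULL
  for (k in seq_len(max_pairs)) {
    if (length(avail) < 2L) break
    i <- if (length(avail) == 1L) avail else sample(avail, 1L)
    js <- avail[abs(avail - i) >= 4L]
    if (length(js) == 0L) next
    j <- if (length(js) == 1L) js else sample(js, 1L)
    pairs <- rbind(pairs, c(min(i, j), max(i, j)))
    avail <- setdiff(avail, c(i, j))
  }
  pair_map(L, pairs)
}

random_structure <- function(L) pairs_to_matrix(random_pair_map(L))

random_rna <- function(L, id = "r") {
  rna_sequence(id, paste(sample(c("A", "U", "C", "G"), L, TRUE), collapse = ""))
}

# reference decoder: per-entry loops implementing argmax (lowest-index ties),
# mutual agreement, and the distance check
ref_decode <- function(M) {
  L <- nrow(M)
  Mh <- matrix(0, L, L)
  for (i in 1:L) for (j in 1:L) Mh[i, j] <- (M[i, j] + M[j, i]) / 2
  amax <- integer(L)
  for (i in 1:L) {
    best <- -Inf
    for (j in 1:L) if (Mh[i, j] > best) { best <- Mh[i, j]; amax[i] <- j }
  }
  P <- matrix(0, L, L)
  for (i in 1:L) for (j in 1:L) {
    if (amax[i] == j && amax[j] == i && abs(i - j) >= 4) P[i, j] <- 1
  }
  P
}

# scalar-loop weighted cross-entropy oracle over a batch of (Pr, label) pairs
ref_weighted_ce <- function(Pr_list, lab_list) {
  li <- c()
  inD <- c()
  for (k in seq_along(Pr_list)) {
    P <- Pr_list[[k]]
    S <- lab_list[[k]]
    for (i in seq_len(nrow(P))) {
      cls <- which(S[i, ] == 1)
      li <- c(li, -log(P[i, cls]))
      inD <- c(inD, cls == i)
    }
  }
  n <- length(li)
  nD <- sum(inD)
  if (nD == 0L || nD == n) return(mean(li))
  (sum(li[!inD]) + (n - nD) / nD * sum(li[inD])) / n
}

# exhaustive recursion (no memoisation) for the maximum number of
# non-crossing canonical/wobble pairs with separation >= 4
brute_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

brute_max_pairs <- function(ch, lo = 1L, hi = length(ch)) {
  if (hi - lo < 4L) return(0L)
  best <- brute_max_pairs(ch, lo + 1L, hi)
  for (k in (lo + 4L):hi) {
    if (brute_can_pair(ch[lo], ch[k])) {
      cand <- 1L + brute_max_pairs(ch, lo + 1L, k - 1L) +
        brute_max_pairs(ch, k + 1L, hi)
      if (cand > best) best <- cand
    }
  }
  best
}

# pair-set based P/R/F1, the independent route for the metric checks
ref_f1_from_pairs <- function(pred, ref) {
  pset <- function(S) {
    idx <- which(S == 1 & upper.tri(S), arr.ind = TRUE)
    if (nrow(idx) == 0L) return(character(0))
    paste(idx[, 1L], idx[, 2L])
  }
  a <- pset(pred)
  b <- pset(ref)
  if (length(a) == 0L && length(b) == 0L) return(1)
  tp <- length(intersect(a, b))
  if (tp == 0L) return(0)
  P <- tp / length(a)
  R <- tp / length(b)
  2 * P * R / (P + R)
}

tiny_config <- function(seed = 1L) {
  model_config(embed_dim = 8L, n_layers = 1L, n_heads = 2L, ff_dim = 16L,
               unet_depth = 1L, base_channels = 4L, max_len = 64L, seed = seed)
}
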