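# Independent brute-force oracles and shared fixture configs.

# Connected-component labeling by iterated minimum-label flooding: every
# foreground pixel starts with a unique label; repeatedly replace each pixel's
# label by the minimum over its neighborhood until a fixpoint. Structurally
# unlike the package's stack-based BFS labeling.
floodFillOracle <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  if (connectivity == 4) {
    nb <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    nb <- cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  repeat {
    cur <- lab
    for (k in seq_len(nrow(nb)))
      cur <- pmin(cur, shift(lab, nb[k, 1], nb[k, 2]))
    cur[!mask] <- Inf
    if (identical(cur, lab)) break
    lab <- cur
  }
  lab[!mask] <- 0
  matrix(as.integer(lab), nr, nc)
}

# canonical renumbering so two labelings can be compared as partitions
canonicalLabels <- function(lab) {
  ids <- unique(lab[lab > 0])
  out <- lab
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# U statistic by direct pair counting
bruteForceU <- function(case, control) {
  gt <- sum(outer(case, control, ">"))
  eq <- sum(outer(case, control, "=="))
  gt + eq / 2
}

# exact MWU p by enumerating every label split, U recomputed per split via
# pair counting (independent of the package's rank-based path)
bruteForceMWUp <- function(case, control,
                           sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  pooled <- c(case, control)
  n1 <- length(case)
  u <- bruteForceU(case, control)
  splits <- combn(length(pooled), n1)
  uNull <- apply(splits, 2, function(ii)
    bruteForceU(pooled[ii], pooled[-ii]))
  pGe <- mean(uNull >= u - 1e-9)
  pLe <- mean(uNull <= u + 1e-9)
  switch(sidedness, greater = pGe, less = pLe,
         two_sided = min(1, 2 * min(pGe, pLe)))
}

# minimum-cost assignment by exhaustive permutation search over the padded
# square problem (n, m small); forbidden pairs get a big-M so the search first
# maximizes the number of real matches, then minimizes total cost
bruteForceAssignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  s <- max(n, m)
  big <- sum(abs(cost[is.finite(cost)])) + 1
  M <- matrix(0, s, s)
  M[seq_len(n), seq_len(m)] <- ifelse(is.finite(cost), cost, big)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- Inf; bestPerm <- NULL
  for (p in perms(seq_len(s))) {
    tot <- sum(M[cbind(seq_len(s), p)])
    if (tot < best) { best <- tot; bestPerm <- p }
  }
  a <- rep(NA_integer_, n)
  for (i in seq_len(n))
    if (bestPerm[i] <= m && is.finite(cost[i, bestPerm[i]]))
      a[i] <- bestPerm[i]
  a
}

# a bright, noise-free, unbleached configuration in which every nascent
# transcript pushes the dot far above the detection threshold
cleanConfig <- function(nNucleiSide = 3L, nFrames = 50L, seed = 1L, ...) {
  args <- list(nNucleiSide = nNucleiSide, fieldSizePx = 32L * nNucleiSide,
               nFramesPerStage = as.integer(nFrames), noiseSd = 0,
               ampPerTranscript = 180, backgroundLevel = 20,
               bleachHalflifeS = Inf, dotDiffusionPx = 1, seed = seed)
  do.call(simConfig, utils::modifyList(args, list(...)))
}

# synthetic dots table builder for metric/tracking unit tests
dotRows <- function(frame, row, col, area = 5L, bright = 100,
                    stage = "nc14", norm = NA_real_, id = NA_integer_) {
  data.frame(stage = stage, frame = as.integer(frame), row = row, col = col,
             area_px = as.integer(area), mean_brightness = bright,
             norm_brightness = norm, track_id = id, stringsAsFactors = FALSE)
}
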