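# Shared fixtures and small oracles used across test files.

aaAlphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

propertyGroupOf <- local({
  groups <- list(acidic = c("D", "E"),
                 basic = c("K", "R", "H"),
                 polar = c("S", "T", "N", "Q", "C", "G", "P", "Y"),
                 hydrophobic = c("A", "V", "L", "I", "M", "F", "W"))
  m <- rep(NA_character_, 26); names(m) <- LETTERS
  for (g in names(groups)) m[groups[[g]]] <- g
  m
})

# rank-based AUROC of scores for a logical truth vector
auroc <- function(scores, truth) {
  ok <- !is.na(scores)
  scores <- scores[ok]; truth <- truth[ok]
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0 || nNeg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# toy two-clade alignment with known composition
toyAlignment <- function(seqsA, seqsB, cladeA = "m", cladeB = "s") {
  seqs <- c(seqsA, seqsB)
  names(seqs) <- c(paste0(cladeA, seq_along(seqsA)),
                   paste0(cladeB, seq_along(seqsB)))
  CladeAlignment(seqs, setNames(rep(c(cladeA, cladeB),
                                    c(length(seqsA), length(seqsB))),
                                names(seqs)))
}

# brute-force marginal root/internal posteriors and site likelihood by
# enumerating all internal-node state assignments (independent oracle for
# the pruning algorithm; <= 4 tips)
bruteForceAncestral <- function(tipStates, tree, model = "poisson") {
  mod <- nachrevo:::.aaModel(model)
  nTip <- length(tree$tip.label)
  nInt <- tree$Nnode
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    nachrevo:::.transitionMatrix(tree$edge.length[e], mod))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  states <- seq_along(aaAlphabet)
  combos <- as.matrix(expand.grid(rep(list(states), nInt)))
  lik <- apply(combos, 1L, function(assign) {
    nodeState <- function(v) {
      if (v <= nTip) match(tipStates[tree$tip.label[v]], aaAlphabet)
      else assign[v - nTip]
    }
    pr <- mod$bf[assign[root - nTip]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- nodeState(tree$edge[e, 1]); b <- nodeState(tree$edge[e, 2])
      pr <- pr * P[[e]][a, b]
    }
    pr
  })
  post <- sapply(seq_len(nInt), function(j)
    vapply(states, function(s) sum(lik[combos[, j] == s]), numeric(1)))
  list(siteLik = sum(lik), posteriors = sweep(post, 2L, colSums(post), `/`))
}
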