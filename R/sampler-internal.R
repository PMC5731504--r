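# Internal mutable chain state -------------------------------------------
#
# The sampler maintains the cluster set and every score component
# incrementally in an environment keyed by integer node indices. Cluster
# "slots" are recycled through a freelist so slot ids stay small and
# per-iteration tallies stay O(|X|). The invariants maintained:
#   densSum  = sum of generalized densities of active clusters
#   disSum   = sum of pairwise overlap penalties (finite: the chain only
#              ever occupies feasible states)
#   sizeCounts[s] = number of active clusters of size s
#   memberCount[v] = number of active clusters containing node v
#   nUnion   = number of nodes with memberCount > 0
#   sumInvW2 = sum over size-2 clusters of 1/w(x)
#   n3       = number of clusters of size >= 3

newSamplerState <- function(idx, sp) {
  st <- new.env(parent = emptyenv())
  st$idx <- idx
  st$sMax <- sp@sMax
  st$beta <- sp@beta
  st$cdis <- sp@cCluDis
  st$csizeCoef <- sp@cCluSize
  st$chy <- sp@cHy
  st$cpro <- sp@cProNum
  st$g0 <- sp@gamma0
  st$clist <- list()
  st$active <- logical(0)
  st$csize <- integer(0)
  st$cw <- numeric(0)
  st$slotMax <- 0L
  st$freelist <- integer(0)
  st$activeIds <- integer(0)
  st$keys <- new.env(parent = emptyenv())
  st$nX <- 0L
  st$n3 <- 0L
  st$sumInvW2 <- 0
  st$memberCount <- integer(idx$n)
  st$nodeClusters <- rep(list(integer(0)), idx$n)
  st$nUnion <- 0L
  st$densSum <- 0
  st$disSum <- 0
  st$sizeCounts <- integer(sp@sMax)
  st$cumw <- cumsum(idx$ew)
  st$inx <- logical(idx$n)      # scratch membership marks
  st$accw <- numeric(idx$n)     # scratch weight accumulator
  st
}

memKey <- function(mem) paste(mem, collapse = "_")

# Overlap-penalty contribution of a (candidate) cluster with members
# `mem` (sorted integer vector, size sA) against all active clusters
# except slot `self`. Inf when a forbidden overlap occurs.
disContrib <- function(st, mem, sA, self = 0L) {
  ids <- unlist(st$nodeClusters[mem], use.names = FALSE)
  if (self > 0L) ids <- ids[ids != self]
  if (!length(ids)) return(0)
  tb <- tabulate(ids, nbins = st$slotMax)
  js <- which(tb > 0L)
  beta <- st$beta
  tot <- 0
  for (j in js) {
    cc <- tb[j]
    sB <- st$csize[j]
    m <- min(sA, sB)
    ok <- if (m <= 3L) cc <= 1L else cc / m <= beta
    if (!ok) return(Inf)
    tot <- tot + cc / (sA + sB - cc)
  }
  tot
}

# Candidate total score from component values.
stateScore <- function(st, densSum, disSum, sizeCounts, nX, nUnion,
                       gamma, psi) {
  psiX <- if (nX > 0L) sizeCounts[-1L] / nX else numeric(st$sMax - 1L)
  -densSum + st$cdis * disSum +
    st$csizeCoef * sum((psiX - psi)^2) +
    st$chy * (gamma - st$g0)^2 +
    st$cpro * as.numeric(nUnion)^2
}

currentScore <- function(st, gamma, psi) {
  stateScore(st, st$densSum, st$disSum, st$sizeCounts, st$nX, st$nUnion,
             gamma, psi)
}

takeSlot <- function(st) {
  if (length(st$freelist)) {
    id <- st$freelist[[1L]]
    st$freelist <- st$freelist[-1L]
  } else {
    id <- st$slotMax + 1L
    st$slotMax <- id
    st$active[id] <- FALSE
    st$csize[id] <- 0L
    st$cw[id] <- 0
  }
  id
}

# w(v, set) for one node against the scratch marks currently set in st$inx.
wIntoMarks <- function(st, v) {
  nb <- st$idx$adj[[v]]
  if (!length(nb)) return(0)
  sum(st$idx$adjw[[v]][st$inx[nb]])
}

markMembers <- function(st, mem, value = TRUE) st$inx[mem] <- value

# Attachment weights w(v, x) for every member v of mem.
memberAttachment <- function(st, mem) {
  markMembers(st, mem, TRUE)
  res <- vapply(mem, function(v) wIntoMarks(st, v), 0)
  markMembers(st, mem, FALSE)
  res
}

# Neighbors of mem with their extension weights w(u, mem), u outside mem.
neighborWeights <- function(st, mem) {
  idx <- st$idx
  markMembers(st, mem, TRUE)
  cand <- integer(0)
  for (v in mem) {
    nb <- idx$adj[[v]]
    if (!length(nb)) next
    out <- !st$inx[nb]
    if (any(out)) {
      nbo <- nb[out]
      st$accw[nbo] <- st$accw[nbo] + idx$adjw[[v]][out]
      cand <- c(cand, nbo)
    }
  }
  markMembers(st, mem, FALSE)
  cand <- unique(cand)
  w <- st$accw[cand]
  st$accw[cand] <- 0
  list(cand = cand, w = w)
}

# ---- proposals -----------------------------------------------------------
# Each proposal returns a list with:
#   kind        "add-cluster" | "add-protein" | "remove-cluster" |
#               "remove-protein"
#   noop        candidate equals current state (X side)
#   infeasible  candidate has infinite score (surely rejected)
#   dDens, dDis, dU, sizeFrom, sizeTo   score-component deltas
#   qf, qr      forward/reverse proposal probabilities (move weight incl.)
#   payload for commitProposal()

proposeAddClusterInternal <- function(st, alpha) {
  idx <- st$idx
  m <- length(idx$ew)
  if (m == 0L) {
    return(list(kind = "add-cluster", noop = TRUE))
  }
  r <- stats::runif(1) * idx$totw
  k <- findInterval(r, st$cumw) + 1L
  if (k > m) k <- m
  a <- idx$edges[k, 1L]
  b <- idx$edges[k, 2L]
  wE <- idx$ew[k]
  key <- memKey(c(a, b))
  if (!is.null(st$keys[[key]])) {
    return(list(kind = "add-cluster", noop = TRUE, pick = c(a, b)))
  }
  dDis <- disContrib(st, c(a, b), 2L)
  if (is.infinite(dDis)) {
    return(list(kind = "add-cluster", infeasible = TRUE, pick = c(a, b)))
  }
  list(
    kind = "add-cluster", noop = FALSE, infeasible = FALSE,
    dDens = wE / sqrt(2), dDis = dDis,
    dU = (st$memberCount[a] == 0L) + (st$memberCount[b] == 0L),
    sizeFrom = NA_integer_, sizeTo = 2L,
    qf = alpha[1L] * wE / idx$totw,
    qr = alpha[3L] * (1 / wE) / (st$sumInvW2 + 1 / wE),
    mem = c(a, b), cwNew = wE, key = key, pick = c(a, b)
  )
}

proposeAddProteinInternal <- function(st, alpha) {
  if (st$nX == 0L) {
    return(list(kind = "add-protein", noop = TRUE))
  }
  i <- st$activeIds[[sample.int(st$nX, 1L)]]
  x <- st$clist[[i]]
  s <- st$csize[i]
  nw <- neighborWeights(st, x)
  if (!length(nw$cand)) {
    return(list(kind = "add-protein", noop = TRUE, cluster = i))
  }
  pickIdx <- sample.int(length(nw$cand), 1L, prob = nw$w)
  u <- nw$cand[[pickIdx]]
  wux <- nw$w[[pickIdx]]
  if (s + 1L > st$sMax) {
    return(list(kind = "add-protein", infeasible = TRUE,
                cluster = i, pick = u))
  }
  newMem <- sort.int(c(x, u))
  key <- memKey(newMem)
  if (!is.null(st$keys[[key]])) {
    return(list(kind = "add-protein", noop = TRUE, cluster = i, pick = u))
  }
  dNew <- disContrib(st, newMem, s + 1L, self = i)
  if (is.infinite(dNew)) {
    return(list(kind = "add-protein", infeasible = TRUE,
                cluster = i, pick = u))
  }
  dOld <- disContrib(st, x, s, self = i)
  cwNew <- st$cw[i] + wux
  # reverse: remove u from the enlarged cluster
  att <- memberAttachment(st, newMem)
  n3p <- st$n3 + (s == 2L)
  qr <- alpha[4L] * (1 / n3p) * (1 / wux) / sum(1 / att)
  list(
    kind = "add-protein", noop = FALSE, infeasible = FALSE,
    dDens = cwNew / sqrt(s + 1) - st$cw[i] / sqrt(s),
    dDis = dNew - dOld,
    dU = (st$memberCount[u] == 0L),
    sizeFrom = s, sizeTo = s + 1L,
    qf = alpha[2L] * (1 / st$nX) * wux / sum(nw$w),
    qr = qr,
    cluster = i, u = u, mem = newMem, cwNew = cwNew,
    key = key, oldKey = memKey(x), pick = u
  )
}

proposeRemoveClusterInternal <- function(st, alpha) {
  ids2 <- st$activeIds[st$csize[st$activeIds] == 2L]
  if (!length(ids2)) {
    return(list(kind = "remove-cluster", noop = TRUE))
  }
  w2 <- st$cw[ids2]
  if (any(w2 <= 0)) {
    stop("internal inconsistency: size-2 cluster with nonpositive weight")
  }
  inv <- 1 / w2
  i <- ids2[[sample.int(length(ids2), 1L, prob = inv)]]
  x <- st$clist[[i]]
  wE <- st$cw[i]
  dOld <- disContrib(st, x, 2L, self = i)
  list(
    kind = "remove-cluster", noop = FALSE, infeasible = FALSE,
    dDens = -wE / sqrt(2), dDis = -dOld,
    dU = -((st$memberCount[x[1L]] == 1L) + (st$memberCount[x[2L]] == 1L)),
    sizeFrom = 2L, sizeTo = NA_integer_,
    qf = alpha[3L] * (1 / wE) / st$sumInvW2,
    qr = alpha[1L] * wE / st$idx$totw,
    cluster = i, key = memKey(x), pick = x
  )
}

proposeRemoveProteinInternal <- function(st, alpha) {
  ids3 <- st$activeIds[st$csize[st$activeIds] >= 3L]
  if (!length(ids3)) {
    return(list(kind = "remove-protein", noop = TRUE))
  }
  i <- ids3[[sample.int(length(ids3), 1L)]]
  x <- st$clist[[i]]
  s <- st$csize[i]
  att <- memberAttachment(st, x)
  if (any(att <= 0)) {
    stop("internal inconsistency: member with zero attachment in a ",
         "feasible cluster")
  }
  invAtt <- 1 / att
  k <- sample.int(s, 1L, prob = invAtt)
  u <- x[[k]]
  newMem <- x[-k]
  if (!inducedConnected(st$idx, newMem)) {
    return(list(kind = "remove-protein", infeasible = TRUE,
                cluster = i, pick = u))
  }
  key <- memKey(newMem)
  if (!is.null(st$keys[[key]])) {
    return(list(kind = "remove-protein", noop = TRUE,
                cluster = i, pick = u))
  }
  dNew <- disContrib(st, newMem, s - 1L, self = i)
  if (is.infinite(dNew)) {
    return(list(kind = "remove-protein", infeasible = TRUE,
                cluster = i, pick = u))
  }
  dOld <- disContrib(st, x, s, self = i)
  cwNew <- st$cw[i] - att[[k]]
  # reverse: add u back to the shrunken cluster
  nw <- neighborWeights(st, newMem)
  qr <- alpha[2L] * (1 / st$nX) * att[[k]] / sum(nw$w)
  list(
    kind = "remove-protein", noop = FALSE, infeasible = FALSE,
    dDens = cwNew / sqrt(s - 1) - st$cw[i] / sqrt(s),
    dDis = dNew - dOld,
    dU = -(st$memberCount[u] == 1L),
    sizeFrom = s, sizeTo = s - 1L,
    qf = alpha[4L] * (1 / st$n3) * invAtt[[k]] / sum(invAtt),
    qr = qr,
    cluster = i, u = u, mem = newMem, cwNew = cwNew,
    key = key, oldKey = memKey(x), pick = u
  )
}

# ---- committing an accepted proposal ------------------------------------

addMembership <- function(st, v, slot) {
  if (st$memberCount[v] == 0L) st$nUnion <- st$nUnion + 1L
  st$memberCount[v] <- st$memberCount[v] + 1L
  st$nodeClusters[[v]] <- c(st$nodeClusters[[v]], slot)
}

dropMembership <- function(st, v, slot) {
  st$memberCount[v] <- st$memberCount[v] - 1L
  if (st$memberCount[v] == 0L) st$nUnion <- st$nUnion - 1L
  nc <- st$nodeClusters[[v]]
  st$nodeClusters[[v]] <- nc[nc != slot]
}

commitProposal <- function(st, p) {
  st$densSum <- st$densSum + p$dDens
  st$disSum <- st$disSum + p$dDis
  switch(p$kind,
    "add-cluster" = {
      id <- takeSlot(st)
      st$clist[[id]] <- p$mem
      st$active[id] <- TRUE
      st$csize[id] <- 2L
      st$cw[id] <- p$cwNew
      st$keys[[p$key]] <- id
      st$activeIds <- c(st$activeIds, id)
      st$nX <- st$nX + 1L
      st$sumInvW2 <- st$sumInvW2 + 1 / p$cwNew
      st$sizeCounts[2L] <- st$sizeCounts[2L] + 1L
      addMembership(st, p$mem[1L], id)
      addMembership(st, p$mem[2L], id)
    },
    "remove-cluster" = {
      i <- p$cluster
      mem <- st$clist[[i]]
      st$sumInvW2 <- st$sumInvW2 - 1 / st$cw[i]
      st$sizeCounts[2L] <- st$sizeCounts[2L] - 1L
      dropMembership(st, mem[1L], i)
      dropMembership(st, mem[2L], i)
      rm(list = p$key, envir = st$keys)
      st$active[i] <- FALSE
      st$csize[i] <- 0L
      st$cw[i] <- 0
      st$clist[[i]] <- integer(0)
      st$activeIds <- st$activeIds[st$activeIds != i]
      st$nX <- st$nX - 1L
      st$freelist <- c(st$freelist, i)
    },
    "add-protein" = {
      i <- p$cluster
      s <- st$csize[i]
      if (s == 2L) {
        st$sumInvW2 <- st$sumInvW2 - 1 / st$cw[i]
        st$n3 <- st$n3 + 1L
      }
      rm(list = p$oldKey, envir = st$keys)
      st$keys[[p$key]] <- i
      st$clist[[i]] <- p$mem
      st$csize[i] <- s + 1L
      st$cw[i] <- p$cwNew
      st$sizeCounts[s] <- st$sizeCounts[s] - 1L
      st$sizeCounts[s + 1L] <- st$sizeCounts[s + 1L] + 1L
      addMembership(st, p$u, i)
    },
    "remove-protein" = {
      i <- p$cluster
      s <- st$csize[i]
      rm(list = p$oldKey, envir = st$keys)
      st$keys[[p$key]] <- i
      st$clist[[i]] <- p$mem
      st$csize[i] <- s - 1L
      st$cw[i] <- p$cwNew
      st$sizeCounts[s] <- st$sizeCounts[s] - 1L
      st$sizeCounts[s - 1L] <- st$sizeCounts[s - 1L] + 1L
      if (s - 1L == 2L) {
        st$sumInvW2 <- st$sumInvW2 + 1 / p$cwNew
        st$n3 <- st$n3 - 1L
      }
      dropMembership(st, p$u, i)
    },
    stop("unknown proposal kind")
  )
  invisible(st)
}

# Insert an existing (validated) cluster into a fresh state; used when a
# chain state is reconstructed from a ClusterSet.
insertCluster <- function(st, mem) {
  s <- length(mem)
  if (s > st$sMax) stop("cluster exceeds the size cap sMax")
  if (!inducedConnected(st$idx, mem)) {
    stop("cluster is not connected in its induced subgraph")
  }
  key <- memKey(mem)
  if (!is.null(st$keys[[key]])) stop("duplicate cluster")
  d <- disContrib(st, mem, s)
  if (is.infinite(d)) stop("cluster set has a forbidden overlap")
  att <- memberAttachment(st, mem)
  cw <- sum(att) / 2
  id <- takeSlot(st)
  st$clist[[id]] <- mem
  st$active[id] <- TRUE
  st$csize[id] <- s
  st$cw[id] <- cw
  st$keys[[key]] <- id
  st$activeIds <- c(st$activeIds, id)
  st$nX <- st$nX + 1L
  if (s == 2L) st$sumInvW2 <- st$sumInvW2 + 1 / cw else st$n3 <- st$n3 + 1L
  st$sizeCounts[s] <- st$sizeCounts[s] + 1L
  for (v in mem) addMembership(st, v, id)
  st$densSum <- st$densSum + cw / sqrt(s)
  st$disSum <- st$disSum + d
  invisible(id)
}

stateFromClusterSet <- function(net, X, sp) {
  idx <- netIndex(net)
  st <- newSamplerState(idx, sp)
  for (x in clusters(X)) {
    insertCluster(st, sort.int(memberIdx(idx, x)))
  }
  st
}

stateClusterSet <- function(st) {
  nm <- st$idx$names
  clusterSet(lapply(st$clist[st$activeIds], function(m) nm[m]))
}
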