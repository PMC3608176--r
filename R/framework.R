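#' Multi-template framework configuration
#'
#' @param nTemplates number of templates F (1 = single-template mode, in
#'   which helix crossing is disabled by the protocol definition; 2--4 =
#'   multi-template mode).
#' @param iterations framework iterations T.
#' @param nPipelines number of region-assigned pipelines (default 8).
#' @param eliteCapacity elite-pool capacity (default \code{4 * nTemplates}).
#' @param crossingEnabled whether the helix-crossing step runs (default
#'   \code{TRUE} for multi-template mode).
#' @param masterSeed master seed from which all per-(iteration, pipeline)
#'   streams derive.
#' @return a \linkS4class{FrameworkConfig}.
#' @export
FrameworkConfig <- function(nTemplates, iterations, nPipelines = 8,
                            eliteCapacity = 4L * nTemplates,
                            crossingEnabled = nTemplates > 1L,
                            masterSeed = 1) {
  new("FrameworkConfig", nPipelines = as.integer(nPipelines),
      nTemplates = as.integer(nTemplates),
      iterations = as.integer(iterations),
      eliteCapacity = as.integer(eliteCapacity),
      crossingEnabled = as.logical(crossingEnabled),
      masterSeed = as.integer(masterSeed))
}

#' Assign helix/loop regions to pipelines
#'
#' With the standard eight pipelines: pipeline 1 refines TM1 plus the
#' N-terminal tail, pipeline 8 refines TM7 plus the C-terminal tail, and
#' pipelines 2..7 refine the adjacent pairs (TM1,TM2) .. (TM6,TM7) plus the
#' loop between them.  Other pipeline counts use the same scheme with the
#' middle pairs spread proportionally; every loop region is always covered.
#'
#' @param topology a \linkS4class{Topology} (must have 7 TM ranges).
#' @param nPipelines number of pipelines (default 8, minimum 2).
#' @return list of per-pipeline assignments, each a list with integer
#'   elements \code{helices} and \code{loops} (rows of
#'   \code{loopRanges(topology)}).
#' @export
assignPipelines <- function(topology, nPipelines = 8) {
  if (nrow(topology@tmRanges) != 7L) stop("topology must have 7 helices")
  np <- as.integer(nPipelines)
  if (np < 2L) stop("need at least 2 pipelines")
  lp <- topology@loopRanges
  n <- topology@n
  ntermRow <- which(lp[, 1] == 1L & lp[, 2] < topology@tmRanges[1, 1])
  ctermRow <- which(lp[, 2] == n & lp[, 1] > topology@tmRanges[7, 2])
  # interhelix loop i sits between TM i and TM i+1
  interRow <- vapply(seq_len(6L), function(i) {
    w <- which(lp[, 1] > topology@tmRanges[i, 2] &
                 lp[, 2] < topology@tmRanges[i + 1L, 1])
    if (length(w)) w[1] else NA_integer_
  }, integer(1))

  out <- vector("list", np)
  out[[1]] <- list(helices = 1L, loops = as.integer(ntermRow))
  out[[np]] <- list(helices = 7L, loops = as.integer(ctermRow))
  if (np > 2L) {
    mids <- 2:(np - 1L)
    # pair (k-1, k); spread k over 2..7 proportionally
    ks <- as.integer(round(seq(2, 7, length.out = length(mids))))
    for (j in seq_along(mids)) {
      out[[mids[j]]] <- list(helices = c(ks[j] - 1L, ks[j]),
                             loops = integer(0))
    }
    # each interhelix loop goes to the nearest middle pipeline
    for (i in seq_len(6L)) {
      if (is.na(interRow[i])) next
      j <- which.min(abs(ks - (i + 1L)))
      out[[mids[j]]]$loops <- c(out[[mids[j]]]$loops, interRow[i])
    }
  } else {
    # two pipelines: split the interhelix loops between them
    for (i in seq_len(6L)) {
      if (is.na(interRow[i])) next
      tgt <- if (i <= 3L) 1L else np
      out[[tgt]]$loops <- c(out[[tgt]]$loops, interRow[i])
    }
  }
  out
}

#' Create an empty elite pool
#'
#' @param capacity maximum number of stored conformations.
#' @return an \linkS4class{ElitePool}.
#' @export
ElitePool <- function(capacity) {
  new("ElitePool", entries = list(), capacity = as.integer(capacity),
      serial = 0L)
}

#' Update the elite pool with scored candidates
#'
#' Keeps the lowest-energy \code{capacity} entries of the union of the pool
#' and the candidates, with a stable tie-break on (energy, insertion
#' order).  Candidates with non-finite energy are never admitted.
#'
#' @param pool an \linkS4class{ElitePool}.
#' @param candidates list of candidates, each a list with elements
#'   \code{structure}, \code{energy} (numeric total), and optionally
#'   \code{provenance}.
#' @return the updated pool.
#' @export
updateElitePool <- function(pool, candidates) {
  serial <- pool@serial
  entries <- pool@entries
  for (cand in candidates) {
    if (!is.finite(cand$energy)) next
    serial <- serial + 1L
    entries[[length(entries) + 1L]] <-
      list(structure = cand$structure, energy = cand$energy,
           provenance = if (is.null(cand$provenance)) "" else cand$provenance,
           serial = serial)
  }
  if (length(entries)) {
    e <- vapply(entries, function(x) x$energy, numeric(1))
    srl <- vapply(entries, function(x) x$serial, integer(1))
    entries <- entries[order(e, srl)]
    if (length(entries) > pool@capacity)
      entries <- entries[seq_len(pool@capacity)]
  }
  new("ElitePool", entries = entries, capacity = pool@capacity,
      serial = serial)
}

#' @describeIn updateElitePool lowest stored energy (\code{Inf} when empty)
#' @export
poolBestEnergy <- function(pool) {
  if (length(pool@entries) == 0L) return(Inf)
  pool@entries[[1]]$energy
}

setMethod("show", "ElitePool", function(object) {
  cat(sprintf("ElitePool: %d/%d entries", length(object@entries),
              object@capacity))
  if (length(object@entries))
    cat(sprintf(", best energy %.4f", object@entries[[1]]$energy))
  cat("\n")
})

#' Select a starting conformation
#'
#' Iteration 1 draws uniformly from the templates; later iterations draw
#' uniformly from the elite pool, falling back to the templates while the
#' pool is empty.
#'
#' @param pool an \linkS4class{ElitePool}.
#' @param templates list of template \linkS4class{BackboneStructure}s.
#' @param rng a \code{\link{randomStream}}.
#' @param iteration current framework iteration (1-based).
#' @return a \linkS4class{BackboneStructure}.
#' @export
selectStart <- function(pool, templates, rng, iteration = 1) {
  fromPool <- iteration > 1 && length(pool@entries) > 0L
  if (!fromPool && length(templates) == 0L)
    stop("both the elite pool and the template set are empty")
  if (fromPool) {
    k <- streamEval(rng, sample.int(length(pool@entries), 1L))
    pool@entries[[k]]$structure
  } else {
    k <- streamEval(rng, sample.int(length(templates), 1L))
    templates[[k]]
  }
}

# Loop rows adjacent to helix h (junction loops re-closed after a graft).
adjacentLoopRows <- function(topology, h) {
  lp <- topology@loopRanges
  tm <- topology@tmRanges[h, ]
  which((lp[, 2] == tm[1] - 1L) | (lp[, 1] == tm[2] + 1L))
}

#' Cross best-so-far helices between pipelines
#'
#' For each recipient pipeline and each helix it owns, the other pipelines'
#' best poses donate their version of that helix in pipeline order; the
#' helix coordinates are grafted rigidly, the junction loops re-closed, and
#' the graft is kept only if the total energy strictly decreases (first
#' improving donor wins).  Loop regions are never grafted.  All donors are
#' read from an immutable snapshot of the states taken on entry.
#'
#' @param states list of \linkS4class{PipelineState}s, one per pipeline.
#' @param assignments region assignments from \code{\link{assignPipelines}}.
#' @param ctx an \code{\link{energyContext}}.
#' @param loopConfig closure configuration for junction re-closure.
#' @return the list of updated states.
#' @export
crossHelices <- function(states, assignments, ctx,
                         loopConfig = LoopRefineConfig()) {
  if (length(states) < 2L) stop("crossing needs at least 2 pipelines")
  topology <- ctx$topology
  snapshot <- lapply(states, function(st) st@best)
  ns <- vapply(snapshot, nResidues, integer(1))
  if (length(unique(ns)) != 1L)
    stop("pipelines hold structures of different lengths; topologies must match")
  for (p in seq_along(states)) {
    for (h in assignments[[p]]$helices) {
      rg <- topology@tmRanges[h, ]
      own <- atomCoords(states[[p]]@best, rg[1]:rg[2])
      tried <- list()
      for (q in seq_along(states)) {
        if (q == p) next
        donated <- atomCoords(snapshot[[q]], rg[1]:rg[2])
        # skip donors offering a helix we already hold or already tried
        if (isTRUE(all.equal(donated, own, tolerance = 1e-12))) next
        dup <- any(vapply(tried, function(m)
          isTRUE(all.equal(m, donated, tolerance = 1e-12)), logical(1)))
        if (dup) next
        tried[[length(tried) + 1L]] <- donated
        cand <- states[[p]]@best
        cand <- `residueCoords<-`(cand, rg[1]:rg[2], donated)
        for (lr in adjacentLoopRows(topology, h)) {
          lp <- topology@loopRanges[lr, ]
          n <- nResidues(cand)
          cand <- if (lp[1] == 1L || lp[2] == n) {
            snapTerminalLoop(cand, lp)
          } else {
            ccdClose(cand, lp, loopConfig)$structure
          }
        }
        e <- evalEnergy(cand, ctx)
        if (e@total < states[[p]]@bestEnergy@total) {
          st <- states[[p]]
          st@best <- cand; st@bestEnergy <- e
          st@current <- cand; st@currentEnergy <- e
          st@trajectory <- c(st@trajectory, e@total)
          states[[p]] <- st
          break
        }
      }
    }
  }
  states
}

#' Run the full multi-template refinement framework
#'
#' For T iterations, each pipeline selects a starting conformation
#' (templates first, the elite pool afterwards), refines its assigned
#' region with the single-pipeline protocol, then best-so-far helices are
#' exchanged across pipelines (if crossing is enabled) and improved results
#' are admitted to the elite pool.  Pipelines execute under deterministic
#' barrier semantics: crossing and pool updates happen at iteration
#' boundaries on consistent snapshots, and the whole run is reproducible
#' from the master seed.
#'
#' @param templates list of template \linkS4class{BackboneStructure}s, all
#'   of the same length as the topology.
#' @param topology the shared \linkS4class{Topology}.
#' @param frame a \linkS4class{MembraneFrame} (derived from the first
#'   template when \code{NULL}).
#' @param framework a \linkS4class{FrameworkConfig}.
#' @param params packing parameters.
#' @param moveRanges a \linkS4class{MoveRanges}.
#' @param loopConfig a \linkS4class{LoopRefineConfig}.
#' @param cyclesPerStage stage cycle count for every pipeline (default:
#'   one tenth of n, keeping a framework run linear in n per pipeline).
#' @param pipelineIterations stage-sequence repetitions within each
#'   pipeline run (default 2, so tilt-stage changes get follow-up
#'   translation cycles).
#' @param accumulateDecoys when \code{TRUE}, every pool-admitted candidate
#'   is kept in the decoy set; otherwise the decoys are the final pool
#'   snapshot.
#' @param ... further energy settings passed to \code{\link{energyContext}}.
#' @return a \linkS4class{RefinementRun}.
#' @export
runBundleRefinement <- function(templates, topology, frame = NULL,
                                framework, params = defaultPackingParams(),
                                moveRanges = MoveRanges(),
                                loopConfig = LoopRefineConfig(),
                                cyclesPerStage = max(1L, topology@n %/% 10L),
                                pipelineIterations = 2,
                                accumulateDecoys = FALSE, ...) {
  if (length(templates) < 1L) stop("need at least one template")
  if (length(templates) != framework@nTemplates)
    stop("framework@nTemplates must match the number of templates supplied")
  ns <- vapply(templates, nResidues, integer(1))
  if (any(ns != topology@n))
    stop("all templates must match the topology length before any work starts")
  if (is.null(frame))
    frame <- membraneFrameFromStructure(templates[[1]], topology)
  ctx <- energyContext(topology, frame, params, ...)
  assignments <- assignPipelines(topology, framework@nPipelines)
  master <- randomStream(framework@masterSeed)
  pool <- ElitePool(framework@eliteCapacity)

  templateEnergies <- vapply(templates, function(tp) evalEnergy(tp, ctx)@total,
                             numeric(1))
  decoys <- list()
  logRows <- list()

  if (framework@iterations == 0L) {
    cands <- lapply(seq_along(templates), function(k)
      list(structure = templates[[k]], energy = templateEnergies[k],
           provenance = sprintf("template %d", k)))
    pool <- updateElitePool(pool, cands)
    best <- which.min(templateEnergies)
    return(new("RefinementRun", best = templates[[best]],
               bestEnergy = evalEnergy(templates[[best]], ctx),
               pool = pool, decoys = pool@entries,
               log = data.frame(iteration = integer(0), pipeline = integer(0),
                                startEnergy = numeric(0),
                                finalEnergy = numeric(0),
                                improved = logical(0))))
  }

  for (t in seq_len(framework@iterations)) {
    poolSnapshot <- pool
    states <- vector("list", framework@nPipelines)
    startEnergies <- numeric(framework@nPipelines)
    for (p in seq_len(framework@nPipelines)) {
      rng <- randomStream(streamChildSeed(master))
      start <- selectStart(poolSnapshot, templates, rng, iteration = t)
      config <- PipelineConfig(cyclesPerStage,
                               iterationsT = pipelineIterations,
                               assignedHelices = assignments[[p]]$helices,
                               assignedLoops = assignments[[p]]$loops)
      startEnergies[p] <- evalEnergy(start, ctx)@total
      states[[p]] <- runPipeline(start, topology, frame, config, ctx = ctx,
                                 moveRanges = moveRanges,
                                 loopConfig = loopConfig, rng = rng)
    }
    if (framework@crossingEnabled && framework@nPipelines >= 2L) {
      states <- crossHelices(states, assignments, ctx, loopConfig)
    }
    improved <- vapply(seq_along(states), function(p)
      states[[p]]@bestEnergy@total < startEnergies[p], logical(1))
    cands <- lapply(which(improved), function(p)
      list(structure = states[[p]]@best,
           energy = states[[p]]@bestEnergy@total,
           provenance = sprintf("iteration %d pipeline %d", t, p)))
    pool <- updateElitePool(pool, cands)
    if (accumulateDecoys) decoys <- c(decoys, cands)
    logRows[[t]] <- data.frame(
      iteration = t, pipeline = seq_len(framework@nPipelines),
      startEnergy = startEnergies,
      finalEnergy = vapply(states, function(st) st@bestEnergy@total,
                           numeric(1)),
      improved = improved)
  }

  if (length(pool@entries)) {
    bestEntry <- pool@entries[[1]]
    best <- bestEntry$structure
    bestEnergy <- evalEnergy(best, ctx)
  } else {
    k <- which.min(templateEnergies)
    best <- templates[[k]]
    bestEnergy <- evalEnergy(best, ctx)
  }
  new("RefinementRun", best = best, bestEnergy = bestEnergy, pool = pool,
      decoys = if (accumulateDecoys) decoys else pool@entries,
      log = do.call(rbind, logRows))
}

#' Write a run's decoys as PDB files
#'
#' @param run a \linkS4class{RefinementRun}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeDecoys <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (i in seq_along(run@decoys)) {
    path <- file.path(dir, sprintf("decoy_%03d.pdb", i))
    writePDBBackbone(run@decoys[[i]]$structure, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

setMethod("show", "RefinementRun", function(object) {
  cat(sprintf("RefinementRun: best energy %.4f, %d decoys\n",
              object@bestEnergy@total, length(object@decoys)))
})
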