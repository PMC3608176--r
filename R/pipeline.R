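#' Single-pipeline refinement configuration
#'
#' @param stage2Cycles,stage3Cycles,stage4Cycles cycles of the translation,
#'   spin and tilt stages.
#' @param iterationsT repetitions of the whole stage sequence (plus the
#'   loop-refinement step) within one pipeline run (default 1).
#' @param assignedHelices contiguous non-empty subset of 1..7 the pipeline
#'   may move; the framework assigns at most an adjacent pair, a standalone
#'   run of the full protocol may take all seven.
#' @param assignedLoops loop indices (rows of the topology's loop ranges)
#'   the pipeline may refine.
#' @param seed pipeline seed (used when no stream is supplied).
#' @return a \linkS4class{PipelineConfig}.
#' @export
PipelineConfig <- function(stage2Cycles, stage3Cycles = stage2Cycles,
                           stage4Cycles = stage2Cycles, iterationsT = 1,
                           assignedHelices = 1:7,
                           assignedLoops = integer(0), seed = 1) {
  new("PipelineConfig", stage2Cycles = as.integer(stage2Cycles),
      stage3Cycles = as.integer(stage3Cycles),
      stage4Cycles = as.integer(stage4Cycles),
      iterationsT = as.integer(iterationsT),
      assignedHelices = as.integer(assignedHelices),
      assignedLoops = as.integer(assignedLoops), seed = as.integer(seed))
}

#' Default pipeline configuration for a chain
#'
#' Stage cycle counts scale linearly with the chain length n (the
#' complexity model of the protocol); \code{cyclesScale} rescales them for
#' smaller runs.
#'
#' @param topology a \linkS4class{Topology}.
#' @param assignedHelices,assignedLoops region assignment (defaults: all).
#' @param cyclesScale multiplier on n (default 1).
#' @param seed pipeline seed.
#' @return a \linkS4class{PipelineConfig}.
#' @export
defaultPipelineConfig <- function(topology, assignedHelices = 1:7,
                                  assignedLoops = seq_len(nrow(loopRanges(topology))),
                                  cyclesScale = 1, seed = 1) {
  cyc <- max(1L, as.integer(round(cyclesScale * topology@n)))
  PipelineConfig(cyc, cyc, cyc, assignedHelices = assignedHelices,
                 assignedLoops = assignedLoops, seed = seed)
}

#' Energy context
#'
#' Bundles everything the whole-pose energy needs so the refinement stages
#' can score proposals with one call.
#'
#' @param topology a \linkS4class{Topology}.
#' @param frame a \linkS4class{MembraneFrame}.
#' @param params a \linkS4class{PackingParams}.
#' @param dClash,dHelix,dLoopAxis,halfThickness,clashWeight,depthWeight,shapeWeight,contactMax
#'   surrogate membrane score settings (see
#'   \code{\link{surrogateMembraneScore}}).
#' @return an energy-context list.
#' @export
energyContext <- function(topology, frame, params = defaultPackingParams(),
                          dClash = 4, dHelix = 9, dLoopAxis = 7,
                          halfThickness = 16.5,
                          clashWeight = 1,
                          depthWeight = 1, shapeWeight = 1, contactMax = 11) {
  structure(list(topology = topology, frame = frame, params = params,
                 dClash = dClash, dHelix = dHelix, dLoopAxis = dLoopAxis,
                 halfThickness = halfThickness,
                 clashWeight = clashWeight, depthWeight = depthWeight,
                 shapeWeight = shapeWeight, contactMax = contactMax),
            class = "EnergyContext")
}

#' Evaluate the total energy under a context
#'
#' @param s a \linkS4class{BackboneStructure}.
#' @param ctx an \code{\link{energyContext}}.
#' @return an \linkS4class{EnergyReport}.
#' @export
evalEnergy <- function(s, ctx) {
  .asEnergyReport(.energyRaw(s, ctx))
}

newPipelineState <- function(s, e) {
  new("PipelineState", current = s, currentEnergy = e, best = s,
      bestEnergy = e,
      acceptCounts = c(translate = 0L, spin = 0L, tilt = 0L, loop = 0L),
      trajectory = e@total)
}

# Shared stage driver: propose / score / greedy-accept, reverting rejected
# proposals by construction (the current pose is only replaced on accept).
runStage <- function(state, cycles, helices, ctx, propose, stageName) {
  topology <- ctx$topology
  for (cycle in seq_len(cycles)) {
    for (h in helices) {
      prop <- propose(state@current, topology@tmRanges[h, ], h)
      e <- .energyRaw(prop, ctx)
      if (isTRUE(as.logical(greedyAccept(state@currentEnergy@total, e$total)))) {
        state@current <- prop
        state@currentEnergy <- .asEnergyReport(e)
        state@acceptCounts[stageName] <- state@acceptCounts[stageName] + 1L
        state@trajectory <- c(state@trajectory, e$total)
        if (e$total < state@bestEnergy@total) {
          state@best <- prop; state@bestEnergy <- state@currentEnergy
        }
      }
    }
  }
  state
}

#' Translation refinement stage
#'
#' For each cycle and each assigned helix, proposes a uniform rigid
#' translation, scores the whole pose, and keeps the move only on a strict
#' energy decrease.  Components are sampled per laboratory axis by
#' default; in \code{frameMode = "helix"} the same components are applied
#' in a frame aligned with the helix axis, so one component runs along
#' the helix and two perpendicular to it.
#'
#' @param state a \linkS4class{PipelineState}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param ctx an \code{\link{energyContext}}.
#' @param rng a \code{\link{randomStream}}.
#' @param ranges a \linkS4class{MoveRanges}.
#' @param frameMode \code{"lab"} (default) or \code{"helix"}.
#' @return the updated state.
#' @export
runStageTranslation <- function(state, config, ctx, rng,
                                ranges = MoveRanges(),
                                frameMode = c("lab", "helix")) {
  frameMode <- match.arg(frameMode)
  runStage(state, config@stage2Cycles, config@assignedHelices, ctx,
           function(s, rg, h) {
             delta <- sampleTranslation(ranges, rng)
             if (frameMode == "helix") {
               a <- .fitAxisRaw(s, rg)$axis
               p <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
               e1 <- unitv(cross3(a, p)); e2 <- cross3(a, e1)
               delta <- delta[1] * a + delta[2] * e1 + delta[3] * e2
             }
             translateHelix(s, rg, delta)
           },
           "translate")
}

#' Spin refinement stage
#'
#' As the translation stage, with uniform spins about each helix's own
#' (re-fitted) axis; axis positions are unchanged by the move, so the
#' packing term is constant across this stage.
#'
#' @inheritParams runStageTranslation
#' @return the updated state.
#' @export
runStageSpin <- function(state, config, ctx, rng, ranges = MoveRanges()) {
  runStage(state, config@stage3Cycles, config@assignedHelices, ctx,
           function(s, rg, h) spinHelix(s, rg, sampleSpin(ranges, rng),
                                        maxAngle = ranges@spinMax),
           "spin")
}

#' Tilt refinement stage
#'
#' As the translation stage, with Gaussian-sampled absolute tilt targets
#' against the membrane normal.
#'
#' @inheritParams runStageTranslation
#' @return the updated state.
#' @export
runStageTilt <- function(state, config, ctx, rng, ranges = MoveRanges()) {
  runStage(state, config@stage4Cycles, config@assignedHelices, ctx,
           function(s, rg, h) tiltHelix(s, rg, ctx$frame, rng, ranges)$structure,
           "tilt")
}

#' Run the single-pipeline refinement protocol
#'
#' The four-part protocol on the assigned region: translation stage, spin
#' stage, tilt stage (greedy acceptance against the whole-pose energy
#' throughout), then one random loop refinement over the assigned loops,
#' also greedily accepted.  Helix axes are re-fitted on the fly as helices
#' move; the membrane frame stays fixed for the run.
#'
#' @param start starting \linkS4class{BackboneStructure}.
#' @param topology its \linkS4class{Topology}.
#' @param frame a \linkS4class{MembraneFrame} (derived from \code{start}
#'   when \code{NULL}).
#' @param config a \linkS4class{PipelineConfig}.
#' @param ctx optional \code{\link{energyContext}} (built from the other
#'   arguments when \code{NULL}).
#' @param params packing parameters used when \code{ctx} is \code{NULL}.
#' @param moveRanges a \linkS4class{MoveRanges}.
#' @param loopConfig a \linkS4class{LoopRefineConfig}.
#' @param rng a \code{\link{randomStream}} (created from \code{config@seed}
#'   when missing).
#' @return the final \linkS4class{PipelineState}.
#' @export
runPipeline <- function(start, topology, frame = NULL, config,
                        ctx = NULL, params = defaultPackingParams(),
                        moveRanges = MoveRanges(),
                        loopConfig = LoopRefineConfig(), rng = NULL) {
  if (is.null(frame)) frame <- membraneFrameFromStructure(start, topology)
  if (is.null(ctx)) ctx <- energyContext(topology, frame, params)
  if (is.null(rng)) rng <- randomStream(config@seed)
  state <- newPipelineState(start, evalEnergy(start, ctx))
  for (rep in seq_len(config@iterationsT)) {
    state <- runStageTranslation(state, config, ctx, rng, moveRanges)
    state <- runStageSpin(state, config, ctx, rng, moveRanges)
    state <- runStageTilt(state, config, ctx, rng, moveRanges)
    if (length(config@assignedLoops) > 0L &&
        nrow(topology@loopRanges) > 0L) {
      prop <- refineLoopsRandomly(state@current, topology, loopConfig, rng,
                                  loops = config@assignedLoops)
      e <- evalEnergy(prop, ctx)
      if (isTRUE(as.logical(greedyAccept(state@currentEnergy@total, e@total)))) {
        state@current <- prop; state@currentEnergy <- e
        state@acceptCounts["loop"] <- state@acceptCounts["loop"] + 1L
        state@trajectory <- c(state@trajectory, e@total)
        if (e@total < state@bestEnergy@total) {
          state@best <- prop; state@bestEnergy <- e
        }
      }
    }
  }
  state
}

setMethod("show", "PipelineState", function(object) {
  cat(sprintf("PipelineState: energy %.4f (best %.4f), accepts %s\n",
              object@currentEnergy@total, object@bestEnergy@total,
              paste(names(object@acceptCounts), object@acceptCounts,
                    sep = "=", collapse = " ")))
})
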