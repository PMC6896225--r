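#' Integrate one restraint stage
#'
#' Runs Brownian dynamics for `duration` ps under a fixed bias spring
#' constant, sampling the lab-frame protomer RMSD to the reference every
#' `checkInterval` ps and saving trajectory frames every `saveEvery` ps.
#' If `threshold` is given, the stage stops at the first sampled RMSD
#' strictly below it.
#'
#' @param system starting [BeadSystem-class].
#' @param reference reference [BeadSystem-class] sharing protomer bead
#'   ids.
#' @param kBias bias spring constant, kJ/(mol nm^2) per bead.
#' @param duration stage duration, ps.
#' @param params a [SimParams-class].
#' @param saveEvery frame saving interval, ps.
#' @param checkInterval RMSD sampling interval, ps.
#' @param threshold optional early-stop RMSD threshold, Angstrom.
#' @param tStart time origin of the stage, ps.
#' @param seed optional RNG seed (set once; omit to continue the current
#'   RNG stream).
#' @return list with `trajectory` ([BeadTrajectory-class]), `rmsdTrace`
#'   (data.frame time/rmsd), `finalSystem`, `converged`, `stepsDone`.
#' @export
runStage <- function(system, reference, kBias, duration,
                     params = simParams(), saveEvery = 20,
                     checkInterval = 1, threshold = NULL, tStart = 0,
                     seed = NULL) {
  if (duration <= 0) rwStop("rw_spec_error", "duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  a <- simArgs(system, params, reference)
  dt <- params@dt
  nSteps <- max(1L, as.integer(round(duration / dt)))
  saveSteps <- max(1L, as.integer(round(saveEvery / dt)))
  checkSteps <- max(1L, as.integer(round(checkInterval / dt)))
  kBT <- kBOLTZ * params@temperature
  res <- tryCatch(
    .cppRunStage(system@coords, a$radii, params@epsilon, system@box,
                 a$bodyId, a$bodyAllowZ, a$isStatic, a$leafletTarget,
                 params@leafletK, a$refCoords, a$biasRows, kBias,
                 params@gamma, kBT, dt, nSteps, saveSteps, checkSteps,
                 if (is.null(threshold)) -1 else threshold,
                 params@cutoff, tStart),
    error = function(e) {
      if (grepl("divergence", conditionMessage(e)))
        rwStop("rw_divergence_error", conditionMessage(e))
      stop(e)
    })
  nf <- res$nFrames
  arr <- aperm(array(res$frames, dim = c(3, nrow(system@coords), nf)),
               c(2, 1, 3))
  finalSystem <- system
  finalSystem@coords <- res$finalCoords
  list(
    trajectory = BeadTrajectory(system, res$frameTimes, arr),
    rmsdTrace = data.frame(time = res$rmsdTimes, rmsd = res$rmsdVals),
    finalSystem = finalSystem,
    converged = res$converged,
    stepsDone = res$stepsDone
  )
}

#' Run the full staged assembly protocol
#'
#' Weak pulling stage until the lab-frame protomer RMSD drops below the
#' convergence threshold (or the stage budget expires, classifying the
#' run as not assembled); converged runs are then refined by the ordered
#' strong restraint stages. The final frame is analysed for encapsulated
#' lipids per leaflet.
#'
#' @param system starting [BeadSystem-class] (typically from
#'   [makeAssemblySystem()]).
#' @param reference reference ring sharing protomer bead ids.
#' @param protocol a [BiasProtocol-class].
#' @param params a [SimParams-class].
#' @param seed RNG seed for the run.
#' @param saveEvery frame saving interval, ps.
#' @return an [AssemblyResult-class].
#' @export
runAssemblyProtocol <- function(system, reference,
                                protocol = biasProtocol(),
                                params = simParams(), seed = 1,
                                saveEvery = 20) {
  if (!is(protocol, "BiasProtocol"))
    rwStop("rw_spec_error", "protocol must be a BiasProtocol")
  set.seed(seed)
  stages <- list()
  weak <- runStage(system, reference, protocol@weakK,
                   protocol@weakMaxDuration, params,
                   saveEvery = saveEvery,
                   checkInterval = protocol@checkInterval,
                   threshold = protocol@convergenceThreshold, tStart = 0)
  weak$rmsdTrace$stage <- "weak"
  stages[[1]] <- weak
  convergenceTime <- if (weak$converged) {
    idx <- which(weak$rmsdTrace$rmsd < protocol@convergenceThreshold)[1]
    weak$rmsdTrace$time[idx]
  } else NA_real_
  cur <- weak$finalSystem
  tCur <- utils::tail(weak$rmsdTrace$time, 1)
  if (weak$converged && nrow(protocol@strongStages) > 0) {
    for (si in seq_len(nrow(protocol@strongStages))) {
      st <- runStage(cur, reference, protocol@strongStages[si, "k"],
                     protocol@strongStages[si, "duration"], params,
                     saveEvery = saveEvery,
                     checkInterval = protocol@checkInterval,
                     threshold = NULL, tStart = tCur)
      st$rmsdTrace$stage <- sprintf("strong%d", si)
      stages[[length(stages) + 1L]] <- st
      cur <- st$finalSystem
      tCur <- utils::tail(st$rmsdTrace$time, 1)
    }
  }
  # final lab-frame protomer RMSD
  isProt <- cur@kind == "protomer_bead"
  hit <- match(cur@beadId[isProt], reference@beadId)
  finalRmsd <- rmsd(cur@coords[isProt, , drop = FALSE],
                    reference@coords[hit, , drop = FALSE])
  # concatenate stage trajectories and traces
  times <- unlist(lapply(stages, function(s) s$trajectory@times))
  arrs <- lapply(stages, function(s) s$trajectory@coords)
  allArr <- array(unlist(arrs), dim = c(dim(arrs[[1]])[1], 3,
                                        length(times)))
  traces <- lapply(seq_along(stages), function(i) {
    tr <- stages[[i]]$rmsdTrace
    if (i > 1) tr <- tr[-1, , drop = FALSE]  # drop duplicated boundary
    tr
  })
  trace <- do.call(rbind, traces)
  traj <- BeadTrajectory(system, times, allArr)
  counts <- tryCatch({
    cls <- classifyLipids(cur, ringRegion(cur))
    c(loop = sum(cls$inside & cls$leaflet == "loop_side"),
      nc = sum(cls$inside & cls$leaflet == "nc_side"))
  }, error = function(e) c(loop = 0L, nc = 0L))
  outcome <- if (finalRmsd < protocol@assembledThreshold) "assembled"
             else "not_assembled"
  new("AssemblyResult", outcome = outcome,
      convergenceTime = convergenceTime, finalRmsd = finalRmsd,
      rmsdTrace = trace, nLoop = as.integer(counts["loop"]),
      nNC = as.integer(counts["nc"]),
      nTotal = as.integer(sum(counts)), trajectory = traj)
}
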