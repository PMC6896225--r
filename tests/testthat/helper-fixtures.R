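# Shared small fixtures, built in code at test time.

# A mixed 20-bead system with 5 single-bead protomers, 5 two-bead lipids
# and 5 waters in a small periodic box; used for force/gradient checks.
mixedTestSystem <- function(seed = 1) {
  set.seed(seed)
  n <- 20
  kind <- rep(c("protomer_bead", "lipid_head", "lipid_tail", "water"),
              each = 5)
  prot <- ifelse(kind == "protomer_bead", 0:4, NA)[1:20]
  molecule <- c(0:4, 5:9, 5:9, 10:14)
  leaf <- ifelse(kind %in% c("lipid_head", "lipid_tail"), "loop_side",
                 "none")
  sys <- BeadSystem(coords = cbind(runif(n, 0, 6), runif(n, 0, 6),
                                   runif(n, 2, 4)),
                    kind = kind, box = c(6, 6, 8), protomer = prot,
                    molecule = molecule, leaflet = leaf)
  ref <- BeadSystem(coords = coords(sys)[1:5, ] + 0.3, kind = kind[1:5],
                    box = c(6, 6, 8), beadId = beadIds(sys)[1:5],
                    protomer = prot[1:5], molecule = 0:4)
  list(system = sys, reference = ref)
}

# One protomer bead in a box, with itself as reference (harmonic well).
singleBeadWell <- function(at = c(3, 3, 3), box = c(6, 6, 6)) {
  BeadSystem(coords = matrix(at, 1, 3), kind = "protomer_bead", box = box,
             protomer = 0L, molecule = 0L)
}

# Static single-frame trajectory of a system.
staticTrajectory <- function(system, times = 0) {
  BeadTrajectory(system, times,
                 array(rep(coords(system), length(times)),
                       dim = c(nBeads(system), 3, length(times))))
}
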