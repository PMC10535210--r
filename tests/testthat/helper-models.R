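# shared fixtures: built once per test run, reused across files
adult_params <- function() slip_params(mass = 68, stature = 1.74)

cached <- local({
  env <- new.env()
  function(name, build) {
    if (is.null(env[[name]])) env[[name]] <- build()
    env[[name]]
  }
})

adult_gait <- function(speed = 4.5) {
  cached(paste0("gait", speed), function() slip_gait(adult_params(), speed))
}

adult_topology <- function() cached("topo", function() skeleton_topology(1.74))

adult_model <- function() cached("model", function() pedestrian_model(1.74, 68))

adult_trajectory <- function() {
  cached("traj", function()
    build_joint_trajectory(adult_gait(), adult_topology(), adult_model()))
}

adult_mb <- function() cached("mb", function() mb_model(adult_model()))

## a free-floating two-link chain for conservation oracles
two_link_chain <- function(k = 5, gravity = 0) {
  pedrecon:::mb_custom(list(
    list(type = "r", axis = c(0, 1, 0), origin = c(0, 0, 0), mass = 1.5,
         com = c(0, 0, -0.3), inertia = diag(0.02, 3), name = "A", k = k),
    list(type = "r", axis = c(0, 1, 0), origin = c(0, 0, -0.6), mass = 1.0,
         com = c(0, 0, -0.25), inertia = diag(0.01, 3), name = "B",
         k = k)),
    floating = TRUE, gravity = gravity)
}

mb_state0 <- function(model, q = NULL, qd = NULL) {
  structure(list(q = q %||% numeric(model$nb),
                 qd = qd %||% numeric(model$nb),
                 a = rep(0, nrow(model$modes)),
                 ad = rep(0, nrow(model$modes)), t = 0),
            class = "mb_state")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## scaled-down case scenario for simulation tests (coarser horizon; the
## impact phase and event ordering are unaffected)
case1_scenario <- function(max_time = NULL) {
  scn <- load_scenario(pedrecon_fixture("case1.yaml"))
  if (!is.null(max_time)) scn$max_time <- max_time
  scn
}

case1_result <- function() {
  cached("case1", function() {
    suppressWarnings(reconstruct(case1_scenario()))
  })
}
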