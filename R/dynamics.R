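## Articulated rigid-flexible multibody dynamics of the pedestrian.
##
## Reduced (joint-space) coordinates on a kinematic tree: every joint is a
## chain of one-degree-of-freedom revolute or prismatic sub-joints
## (multi-DOF joints are realised through massless intermediate bodies),
## and the floating base is three prismatic plus three revolute DOFs in
## x, z, y order so that the gimbal-singular middle axis is the vertical
## yaw, which stays small in mostly-sagittal impacts.  Accelerations come
## from the articulated-body algorithm (spatial 6-D algebra); joint
## spring-dampers, range-limit stops, gravity and externally supplied
## contact wrenches enter as generalized active forces, and lumped modal
## coordinates on the tibiae carry the flexible-body elastic force
## -K a - C a'.

skew <- function(v) {
  matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
}

## point-rotation matrix (Rodrigues)
rot_axis <- function(a, q) {
  c1 <- cos(q); s1 <- sin(q)
  aa <- a %o% a
  c1 * diag(3L) + s1 * skew(a) + (1 - c1) * aa
}

## spatial cross-product matrices (motion / force)
crm <- function(v) {
  w <- skew(v[1:3]); u <- skew(v[4:6])
  rbind(cbind(w, matrix(0, 3L, 3L)), cbind(u, w))
}
crf <- function(v) -t(crm(v))

## spatial inertia from mass, COM offset c and rotational inertia about COM
spatial_inertia <- function(m, cvec, Ic) {
  C <- skew(cvec)
  rbind(cbind(Ic + m * C %*% t(C), m * C), cbind(m * t(C), m * diag(3L)))
}

## Plucker transform for translation r then coordinate rotation E
xform <- function(E, r) {
  rbind(cbind(E, matrix(0, 3L, 3L)), cbind(-E %*% skew(r), E))
}

#' Build the reduced-coordinate multibody model of a pedestrian
#'
#' @param pedestrian a [pedestrian_model()].
#' @return object of class `"mb_model"`: flattened tree of 1-DOF
#'   sub-joints, per-DOF stiffness/damping/limit presets, channel name to
#'   DOF index map, spatial inertias, capsule geometry references, and two
#'   lumped flexible modes hosted on the tibiae.
#' @export
mb_model <- function(pedestrian) {
  stopifnot(inherits(pedestrian, "pedestrian_model"))
  topo <- pedestrian$topology
  seg <- pedestrian$segments
  nb_max <- 6L + sum(vapply(topo$joints, function(j) length(j$dofs), 0L))
  parent <- integer(0); jtype <- character(0)
  axis <- list(); tr <- list(); Ib <- list()
  body_seg <- character(0)        # "" for virtual bodies
  dof_channel <- character(0)
  dof_k <- numeric(0); dof_c <- numeric(0)
  dof_lo <- numeric(0); dof_hi <- numeric(0); dof_kstop <- numeric(0)
  seg_body <- integer(0)          # body index per real segment
  names(seg_body) <- character(0)

  zeroI <- matrix(0, 6L, 6L)
  add_body <- function(par, type, ax, r, segname, channel,
                       k = 0, cc = 0, lo = -Inf, hi = Inf, kstop = 0) {
    parent[[length(parent) + 1L]] <<- par
    jtype[[length(jtype) + 1L]] <<- type
    axis[[length(axis) + 1L]] <<- ax
    tr[[length(tr) + 1L]] <<- r
    body_seg[[length(body_seg) + 1L]] <<- segname
    dof_channel[[length(dof_channel) + 1L]] <<- channel
    dof_k[[length(dof_k) + 1L]] <<- k
    dof_c[[length(dof_c) + 1L]] <<- cc
    dof_lo[[length(dof_lo) + 1L]] <<- lo
    dof_hi[[length(dof_hi) + 1L]] <<- hi
    dof_kstop[[length(dof_kstop) + 1L]] <<- kstop
    if (segname != "") {
      i <- pedestrian$segments$name == segname
      Ib[[length(Ib) + 1L]] <<- spatial_inertia(
        seg$mass[i], pedestrian$com_offset[which(i), ],
        pedestrian$inertia[[which(i)]])
      seg_body[[segname]] <<- length(parent)
    } else {
      Ib[[length(Ib) + 1L]] <<- zeroI
    }
    length(parent)
  }
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  z3 <- c(0, 0, 0)
  ## floating base -> pelvis (translations x,y,z then rotations x,z,y)
  b <- add_body(0L, "p", ex, z3, "", "base.x")
  b <- add_body(b, "p", ey, z3, "", "base.y")
  b <- add_body(b, "p", ez, z3, "", "base.z")
  b <- add_body(b, "r", ex, z3, "", "base.rx")
  b <- add_body(b, "r", ez, z3, "", "base.rz")
  b <- add_body(b, "r", ey, z3, "pelvis", "base.ry")
  ## joint chains in topological order (parents before children)
  done <- c("pelvis")
  pending <- topo$joints
  while (length(pending)) {
    again <- list()
    for (j in pending) {
      if (!(j$parent %in% done)) { again[[length(again) + 1L]] <- j; next }
      par_body <- seg_body[[j$parent]]
      ndof <- length(j$dofs)
      for (k in seq_len(ndof)) {
        ch <- names(j$dofs)[k]
        segname <- if (k == ndof) j$child else ""
        par_body <- add_body(
          par_body, "r", j$dofs[[k]],
          if (k == 1L) j$origin else z3, segname,
          paste0(j$name, ".", ch),
          k = j$stiffness, cc = j$damping,
          lo = j$limits[1L], hi = j$limits[2L], kstop = j$stop_stiffness)
      }
      done <- c(done, j$child)
    }
    if (length(again) == length(pending))
      stopf("joint tree is not topologically ordered")
    pending <- again
  }
  nb <- length(parent)
  chan_idx <- stats::setNames(seq_len(nb), dof_channel)
  ## lumped flexible modes on the tibiae (bending compliance feeding the
  ## long-bone injury proxy): modal mass 1, K in N/m-equivalent modal units
  modes <- data.frame(host = c("calf_l", "calf_r"),
                      K = c(4e4, 4e4), C = c(40, 40), mass = c(1, 1),
                      stringsAsFactors = FALSE)
  structure(list(
    pedestrian = pedestrian, nb = nb, parent = unlist(parent),
    jtype = unlist(jtype), axis = axis, tr = tr, Ibody = Ib,
    body_seg = unlist(body_seg), seg_body = seg_body,
    dof_channel = unlist(dof_channel), chan_idx = chan_idx,
    dof_k = unlist(dof_k), dof_c = unlist(dof_c),
    dof_lo = unlist(dof_lo), dof_hi = unlist(dof_hi),
    dof_kstop = unlist(dof_kstop),
    ## armature: small reflected inertia per joint DOF (none on the free
    ## base), regularizing the near-singular gimbal modes of chained
    ## three-axis joints
    dof_armature = c(rep(0, 6L), rep(0.01, nb - 6L)),
    base_idx = 1:6, modes = modes, gravity = GRAV),
    class = "mb_model")
}

#' @export
print.mb_model <- function(x, ...) {
  cat(sprintf(
    "Multibody pedestrian model: %d DOF (%d segments + 6-DOF base), %d flexible modes\n",
    x$nb, length(x$seg_body), nrow(x$modes)))
  invisible(x)
}

## motion subspace and joint transform for one sub-joint
sub_jcalc <- function(type, a, q) {
  if (type == "r") {
    list(XJ = xform(t(rot_axis(a, q)), c(0, 0, 0)), S = c(a, 0, 0, 0))
  } else {
    list(XJ = xform(diag(3L), a * q), S = c(0, 0, 0, a))
  }
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

## parent->child coordinate rotation E, joint translation r (parent frame)
## and motion subspace for sub-joint i at coordinate q_i; Xup = xform(E, r)
joint_ErS <- function(model, i, qi) {
  a <- model$axis[[i]]
  if (model$jtype[i] == "r")
    list(E = t(rot_axis(a, qi)), r = model$tr[[i]], S = c(a, 0, 0, 0))
  else
    list(E = diag(3L), r = model$tr[[i]] + a * qi, S = c(0, 0, 0, a))
}

## forward kinematics: world orientation (coordinate transform E: world ->
## body) and world origin position r for every body
mb_fk <- function(model, q) {
  nb <- model$nb
  E <- vector("list", nb); r <- vector("list", nb)
  for (i in seq_len(nb)) {
    a <- model$axis[[i]]
    if (model$jtype[i] == "r") {
      Ej <- t(rot_axis(a, q[i])); rj <- model$tr[[i]]
    } else {
      Ej <- diag(3L); rj <- model$tr[[i]] + a * q[i]
    }
    p <- model$parent[i]
    if (p == 0L) {
      E[[i]] <- Ej; r[[i]] <- rj
    } else {
      ## body frame: translate rj in parent frame then rotate Ej
      E[[i]] <- Ej %*% E[[p]]
      r[[i]] <- r[[p]] + t(E[[p]]) %*% rj
    }
  }
  list(E = E, r = r)
}

## joint spring torque (neutral springs + range-limit stop springs) and
## total viscous damping coefficient per DOF; stops add extra damping
## (5 % of the stop stiffness) so limit impacts do not wind up
dof_spring_damp <- function(model, q) {
  tau <- -model$dof_k * q
  cc <- model$dof_c
  below <- q < model$dof_lo
  above <- q > model$dof_hi
  tau[below] <- tau[below] +
    model$dof_kstop[below] * (model$dof_lo[below] - q[below])
  tau[above] <- tau[above] +
    model$dof_kstop[above] * (model$dof_hi[above] - q[above])
  cc[below | above] <- cc[below | above] +
    0.05 * model$dof_kstop[below | above]
  tau[model$base_idx] <- 0
  cc[model$base_idx] <- 0
  list(tau = tau, c = cc)
}

## full generalized joint force at given rates (diagnostic / force-array
## reporting path)
dof_tau <- function(model, q, qd) {
  sd <- dof_spring_damp(model, q)
  sd$tau - sd$c * qd
}

#' Articulated-body forward dynamics
#'
#' Computes generalized accelerations for the pedestrian tree under
#' gravity, joint spring-damper/stop torques and externally supplied
#' world-frame contact wrenches.
#'
#' @param model an [mb_model()].
#' @param q,qd generalized coordinates and rates (length `model$nb`).
#' @param f_ext named list of world-frame spatial forces `c(n_O, f)`
#'   (moment about the world origin, force) per segment name.
#' @param gravity gravitational acceleration (m/s^2), 0 to disable.
#' @param tau_extra optional additional generalized forces.
#' @return list with `qdd`, the per-body world kinematics (`fk`), and the
#'   per-body spatial velocities.
#' @export
mb_aba <- function(model, q, qd, f_ext = list(), gravity = model$gravity,
                   tau_extra = NULL, dt = Inf) {
  nb <- model$nb
  Xup <- vector("list", nb); S <- vector("list", nb)
  v <- vector("list", nb); cvec <- vector("list", nb)
  IA <- vector("list", nb); pA <- vector("list", nb)
  X0 <- vector("list", nb)
  sd <- dof_spring_damp(model, q)
  tau <- sd$tau
  if (!is.null(tau_extra)) tau <- tau + tau_extra
  has_ext <- length(f_ext) > 0L
  for (i in seq_len(nb)) {
    je <- joint_ErS(model, i, q[i])
    Xup[[i]] <- xform(je$E, je$r)
    S[[i]] <- je$S
    vJ <- je$S * qd[i]
    p <- model$parent[i]
    if (p == 0L) {
      v[[i]] <- vJ
      if (has_ext) X0[[i]] <- Xup[[i]]
    } else {
      v[[i]] <- as.numeric(Xup[[i]] %*% v[[p]]) + vJ
      if (has_ext) X0[[i]] <- Xup[[i]] %*% X0[[p]]
    }
    vi <- v[[i]]
    w <- vi[1:3]; u <- vi[4:6]
    ## c = v x vJ (motion cross), pA = v x* (I v) (force cross)
    cvec[[i]] <- c(cross3(w, vJ[1:3]),
                   cross3(u, vJ[1:3]) + cross3(w, vJ[4:6]))
    IA[[i]] <- model$Ibody[[i]]
    h <- as.numeric(model$Ibody[[i]] %*% vi)
    pA[[i]] <- c(cross3(w, h[1:3]) + cross3(u, h[4:6]), cross3(w, h[4:6]))
    segname <- model$body_seg[i]
    if (has_ext && segname != "" && !is.null(f_ext[[segname]])) {
      Ei <- X0[[i]][1:3, 1:3]
      Xstar <- rbind(cbind(Ei, X0[[i]][4:6, 1:3]),
                     cbind(matrix(0, 3L, 3L), Ei))
      pA[[i]] <- pA[[i]] - as.numeric(Xstar %*% f_ext[[segname]])
    }
  }
  arm <- model$dof_armature %||% numeric(nb)
  U <- vector("list", nb); d <- numeric(nb); u <- numeric(nb)
  for (i in rev(seq_len(nb))) {
    U[[i]] <- IA[[i]] %*% S[[i]]
    d[i] <- sum(S[[i]] * U[[i]]) + arm[i]
    if (d[i] <= 0)
      stopf("mass-matrix conditioning failure at DOF %s (d = %.3e)",
            model$dof_channel[i], d[i])
    ## viscous joint damping, coefficient capped at the explicit-stepping
    ## stability limit of this DOF's articulated inertia
    c_eff <- min(sd$c[i], 0.25 * d[i] / dt)
    u[i] <- tau[i] - c_eff * qd[i] - sum(S[[i]] * pA[[i]])
    p <- model$parent[i]
    if (p != 0L) {
      Ia <- IA[[i]] - (U[[i]] %*% t(U[[i]])) / d[i]
      pa <- pA[[i]] + Ia %*% cvec[[i]] + U[[i]] * (u[i] / d[i])
      IA[[p]] <- IA[[p]] + t(Xup[[i]]) %*% Ia %*% Xup[[i]]
      pA[[p]] <- pA[[p]] + t(Xup[[i]]) %*% pa
    }
  }
  a <- vector("list", nb)
  qdd <- numeric(nb)
  a_grav <- c(0, 0, 0, 0, 0, -gravity)
  for (i in seq_len(nb)) {
    p <- model$parent[i]
    ap <- if (p == 0L) Xup[[i]] %*% (-a_grav) else Xup[[i]] %*% a[[p]]
    ap <- ap + cvec[[i]]
    qdd[i] <- (u[i] - sum(U[[i]] * ap)) / d[i]
    a[[i]] <- ap + S[[i]] * qdd[i]
  }
  list(qdd = qdd, v = v, X0 = X0)
}

## world kinematics of the real segments: origin position/orientation,
## COM position/velocity, angular velocity (world frame)
mb_seg_kin <- function(model, q, qd) {
  nb <- model$nb
  E <- vector("list", nb); r <- vector("list", nb)
  v <- vector("list", nb)
  for (i in seq_len(nb)) {
    je <- joint_ErS(model, i, q[i])
    p <- model$parent[i]
    if (p == 0L) {
      E[[i]] <- je$E; r[[i]] <- je$r
      v[[i]] <- je$S * qd[i]
    } else {
      E[[i]] <- je$E %*% E[[p]]
      r[[i]] <- r[[p]] + as.numeric(t(E[[p]]) %*% je$r)
      v[[i]] <- as.numeric(xform(je$E, je$r) %*% v[[p]]) + je$S * qd[i]
    }
  }
  fk <- list(E = E, r = r)
  segs <- names(model$seg_body)
  out <- list()
  for (s in segs) {
    i <- model$seg_body[[s]]
    E <- fk$E[[i]]; r <- fk$r[[i]]
    w_b <- v[[i]][1:3]; v_b <- v[[i]][4:6]
    ped <- model$pedestrian
    k <- which(ped$segments$name == s)
    cb <- ped$com_offset[k, ]
    out[[s]] <- list(
      E = E, r = as.numeric(r),
      w = as.numeric(t(E) %*% w_b),
      v_origin = as.numeric(t(E) %*% v_b),
      com = as.numeric(r + t(E) %*% cb),
      v_com = as.numeric(t(E) %*% (v_b + skew(w_b) %*% cb)),
      mass = ped$segments$mass[k])
  }
  out
}

## whole-body COM and COM velocity
mb_com <- function(model, q, qd = NULL) {
  kin <- mb_seg_kin(model, q, qd %||% numeric(model$nb))
  M <- sum(vapply(kin, `[[`, 0, "mass"))
  com <- Reduce(`+`, lapply(kin, function(k) k$mass * k$com)) / M
  vcom <- Reduce(`+`, lapply(kin, function(k) k$mass * k$v_com)) / M
  list(com = com, vel = vcom, mass = M)
}

## total linear and angular momentum (about the world origin)
mb_momentum <- function(model, q, qd) {
  kin <- mb_seg_kin(model, q, qd)
  ped <- model$pedestrian
  lin <- c(0, 0, 0); ang <- c(0, 0, 0)
  for (s in names(kin)) {
    k <- kin[[s]]
    ks <- which(ped$segments$name == s)
    R <- t(k$E)                      # body -> world
    Iw <- R %*% ped$inertia[[ks]] %*% t(R)
    lin <- lin + k$mass * k$v_com
    ang <- ang + k$mass * as.numeric(skew(k$com) %*% k$v_com) +
      as.numeric(Iw %*% k$w)
  }
  list(linear = lin, angular = ang)
}

#' Generalized force arrays of the coupled system
#'
#' Splits the right-hand side of the variational equations into the
#' per-body generalized inertial (gyroscopic/centrifugal) forces, the
#' generalized active forces (gravity, joint spring-damper torques,
#' supplied contact loads) and the flexible-body elastic forces
#' `-K a - C a'`.
#'
#' @param model an [mb_model()].
#' @param q,qd generalized coordinates and rates.
#' @param a,ad modal coordinates and rates (one per flexible mode).
#' @param f_ext world-frame contact wrenches per segment (see [mb_aba()]).
#' @param gravity gravitational acceleration; 0 disables gravity.
#' @return list with `inertial` (per real segment, spatial bias force in
#'   body coordinates), `active` (per-DOF generalized force), `elastic`
#'   (per-mode).
#' @export
generalized_forces <- function(model, q, qd, a = NULL, ad = NULL,
                               f_ext = list(), gravity = model$gravity) {
  nb <- model$nb
  v <- vector("list", nb)
  X0 <- vector("list", nb)
  inertial <- list()
  for (i in seq_len(nb)) {
    jc <- sub_jcalc(model$jtype[i], model$axis[[i]], q[i])
    XT <- xform(diag(3L), model$tr[[i]])
    Xup <- jc$XJ %*% XT
    p <- model$parent[i]
    v[[i]] <- if (p == 0L) jc$S * qd[i] else Xup %*% v[[p]] + jc$S * qd[i]
    X0[[i]] <- if (p == 0L) Xup else Xup %*% X0[[p]]
    segname <- model$body_seg[i]
    if (segname != "")
      inertial[[segname]] <-
        as.numeric(-crf(v[[i]]) %*% (model$Ibody[[i]] %*% v[[i]]))
  }
  ## active: joint torques + gravity + external loads projected on DOFs
  tau <- dof_tau(model, q, qd)
  kin <- mb_seg_kin(model, q, qd)
  fg <- list()
  for (s in names(kin)) {
    fz <- c(0, 0, -kin[[s]]$mass * gravity)
    nO <- skew(kin[[s]]$com) %*% fz
    fg[[s]] <- c(as.numeric(nO), fz)
    if (!is.null(f_ext[[s]])) fg[[s]] <- fg[[s]] + f_ext[[s]]
  }
  ## project world wrenches onto DOFs: tau_ext = sum_i S_i' X0*_i f_i over
  ## bodies in the subtree; equivalently accumulate up the tree
  pext <- vector("list", nb)
  for (i in seq_len(nb)) pext[[i]] <- numeric(6L)
  for (i in seq_len(nb)) {
    segname <- model$body_seg[i]
    if (segname != "" && !is.null(fg[[segname]])) {
      Ei <- X0[[i]][1:3, 1:3]
      Xstar <- rbind(cbind(Ei, X0[[i]][4:6, 1:3]),
                     cbind(matrix(0, 3L, 3L), Ei))
      pext[[i]] <- pext[[i]] + as.numeric(Xstar %*% fg[[segname]])
    }
  }
  active <- tau
  for (i in rev(seq_len(nb))) {
    jc <- sub_jcalc(model$jtype[i], model$axis[[i]], q[i])
    active[i] <- active[i] + sum(jc$S * pext[[i]])
    p <- model$parent[i]
    if (p != 0L) {
      XT <- xform(diag(3L), model$tr[[i]])
      Xup <- jc$XJ %*% XT
      pext[[p]] <- pext[[p]] + as.numeric(t(Xup) %*% pext[[i]])
    }
  }
  elastic <- if (is.null(a)) numeric(0) else
    -model$modes$K * a - model$modes$C * (ad %||% numeric(length(a)))
  list(inertial = inertial, active = active, elastic = elastic)
}

#' Initial system state from a collision-moment pose
#'
#' Sets the joint angles and angular velocities from the pose, orients the
#' root with the stored trunk pitch and a heading, drops the root so the
#' lowest collision capsule touches the ground, and offsets the base
#' linear rate so the whole-body (mass-weighted) centre-of-mass velocity
#' equals `com_velocity` exactly.
#'
#' @param model an [mb_model()].
#' @param pose a `"pose"` object ([sample_pose()] or [read_pose()]).
#' @param com_velocity world COM velocity `c(vx, vy, vz)`, m/s.
#' @param heading yaw of the pedestrian (rad about +z; 0 = running along
#'   +x).
#' @param ground_z ground height, m.
#' @return list of class `"mb_state"` with `q`, `qd`, modal `a`, `ad`,
#'   `t = 0`. Pose values outside the joint limits are clamped with a
#'   warning.
#' @export
apply_pose <- function(model, pose, com_velocity = c(0, 0, 0),
                       heading = 0, ground_z = 0) {
  stopifnot(inherits(model, "mb_model"))
  nb <- model$nb
  q <- numeric(nb); qd <- numeric(nb)
  pitch <- attr(pose, "trunk_pitch") %||% 0
  q[model$chan_idx[["base.ry"]]] <- pitch
  q[model$chan_idx[["base.rz"]]] <- heading
  sig <- attr(pose, "signed_rates")
  if (!is.null(pose$joints)) {
    for (i in seq_len(nrow(pose$joints))) {
      jn <- pose$joints$joint[i]
      for (ch in c("R1", "R2", "R3")) {
        val <- pose$joints[[paste0(ch, "_rad")]][i]
        key <- paste0(jn, ".", ch)
        if (!is.na(val) && key %in% names(model$chan_idx)) {
          k <- model$chan_idx[[key]]
          if (val < model$dof_lo[k] || val > model$dof_hi[k]) {
            warnf("pose value %s = %.3f outside limits [%.2f, %.2f]; clamped",
                  key, val, model$dof_lo[k], model$dof_hi[k])
            val <- min(max(val, model$dof_lo[k]), model$dof_hi[k])
          }
          q[k] <- val
        }
      }
    }
  }
  ## angular velocities: exact signed channel rates when the pose was
  ## sampled from a planned trajectory; otherwise map body-part angular
  ## speeds onto the sagittal channels with a toward-neutral sign heuristic
  if (!is.null(sig)) {
    for (key in names(sig)) {
      if (key %in% names(model$chan_idx)) qd[model$chan_idx[[key]]] <- sig[[key]]
    }
  } else if (!is.null(pose$body_parts) && nrow(pose$body_parts)) {
    bp <- pose$body_parts
    wof <- function(part) {
      i <- match(part, bp$body_part)
      if (is.na(i)) 0 else bp$angular_velocity_rad_per_s[i]
    }
    set_rate <- function(key, val) {
      if (key %in% names(model$chan_idx)) {
        k <- model$chan_idx[[key]]
        qd[k] <<- if (q[k] != 0) -sign(q[k]) * abs(val) else abs(val)
      }
    }
    set_rate("HipL.R2", wof("Left thigh"))
    set_rate("HipR.R2", wof("Right thigh"))
    set_rate("KneeL.R1", wof("Left calf") - wof("Left thigh"))
    set_rate("KneeR.R1", wof("Right calf") - wof("Right thigh"))
    set_rate("ShoulderL.R1", wof("Upper left arm"))
    set_rate("ShoulderR.R1", wof("Upper right arm"))
  }
  ## drop the root so the lowest capsule surface rests on the ground
  cp <- capsule_points(model, q)
  low <- min(cp[, 3L] - attr(cp, "radius"))
  q[model$chan_idx[["base.z"]]] <- q[model$chan_idx[["base.z"]]] +
    (ground_z - low)
  ## base rate so the mass-weighted COM velocity matches exactly
  v0 <- mb_com(model, q, qd)$vel
  qd[model$chan_idx[["base.x"]]] <- com_velocity[1L] - v0[1L]
  qd[model$chan_idx[["base.y"]]] <- com_velocity[2L] - v0[2L]
  qd[model$chan_idx[["base.z"]]] <- com_velocity[3L] - v0[3L]
  structure(list(q = q, qd = qd,
                 a = rep(0, nrow(model$modes)),
                 ad = rep(0, nrow(model$modes)), t = 0),
            class = "mb_state")
}

## world positions of the capsule sample points of every segment
## (endpoints + midpoint); returns matrix with columns x,y,z and
## attributes seg (segment name per row)
capsule_points <- function(model, q, qd = NULL, kin = NULL) {
  if (is.null(kin)) kin <- mb_seg_kin(model, q, qd %||% numeric(model$nb))
  ped <- model$pedestrian
  segs <- names(model$seg_body)
  np <- 3L * length(segs)
  pts <- matrix(0, np, 3L)
  vels <- if (!is.null(qd)) matrix(0, np, 3L) else NULL
  labs <- character(np); radii <- numeric(np)
  row <- 0L
  for (s in segs) {
    k <- which(ped$segments$name == s)
    p0 <- ped$capsule_p0[k, ]; p1 <- ped$capsule_p1[k, ]
    K <- kin[[s]]
    R <- t(K$E)
    for (j in 1:3) {
      loc <- switch(j, p0, (p0 + p1) / 2, p1)
      row <- row + 1L
      off <- as.numeric(R %*% loc)
      pts[row, ] <- K$r + off
      if (!is.null(vels)) vels[row, ] <- K$v_origin + cross3(K$w, off)
      labs[row] <- s
      radii[row] <- ped$capsule_r[k]
    }
  }
  attr(pts, "seg") <- labs
  attr(pts, "radius") <- radii
  if (!is.null(vels)) attr(pts, "vel") <- vels
  pts
}

#' Advance the coupled rigid-flexible system one step
#'
#' Semi-implicit Euler (rate update from the articulated-body
#' accelerations, then position update with the new rates) or classical
#' RK4. Flexible modal coordinates advance alongside with the elastic
#' force `-K a - C a'` plus the supplied modal excitation.
#'
#' @param state an `"mb_state"`.
#' @param model an [mb_model()].
#' @param loads optional function `(t, q, qd)` returning a list with
#'   `f_ext` (world wrenches per segment) and `modal` (excitation per
#'   flexible mode); `NULL` for free motion.
#' @param dt time step, s.
#' @param method `"semi_implicit"` (contact-robust default) or `"rk4"`
#'   (high-accuracy, smooth-force oracle runs).
#' @param gravity gravitational acceleration.
#' @return updated `"mb_state"`.
#' @export
mb_step <- function(state, model, loads = NULL, dt = 1e-4,
                    method = c("semi_implicit", "rk4"),
                    gravity = model$gravity) {
  method <- match.arg(method)
  deriv <- function(t, q, qd, a, ad) {
    ld <- if (is.null(loads)) NULL else loads(t, q, qd)
    f_ext <- ld$f_ext %||% list()
    res <- mb_aba(model, q, qd, f_ext = f_ext, gravity = gravity,
                  dt = if (method == "semi_implicit") dt else Inf)
    add <- (-model$modes$K * a - model$modes$C * ad +
              (ld$modal %||% rep(0, nrow(model$modes)))) / model$modes$mass
    list(qdd = res$qdd, add = add)
  }
  if (method == "semi_implicit") {
    d1 <- deriv(state$t, state$q, state$qd, state$a, state$ad)
    qd2 <- state$qd + dt * d1$qdd
    ad2 <- state$ad + dt * d1$add
    q2 <- state$q + dt * qd2
    ## revolute coordinates live on the circle: wrap to (-pi, pi] so
    ## chained-rotation joints cannot wind up through aligned-axis
    ## configurations (all joint limits lie inside +/- pi)
    rot <- model$jtype == "r"
    q2[rot] <- ((q2[rot] + pi) %% (2 * pi)) - pi
    structure(list(q = q2, qd = qd2,
                   a = state$a + dt * ad2, ad = ad2, t = state$t + dt),
              class = "mb_state")
  } else {
    y <- list(q = state$q, qd = state$qd, a = state$a, ad = state$ad)
    f <- function(t, y) {
      d <- deriv(t, y$q, y$qd, y$a, y$ad)
      list(q = y$qd, qd = d$qdd, a = y$ad, ad = d$add)
    }
    axpy <- function(y, k, h) Map(function(u, v) u + h * v, y, k)
    k1 <- f(state$t, y)
    k2 <- f(state$t + dt / 2, axpy(y, k1, dt / 2))
    k3 <- f(state$t + dt / 2, axpy(y, k2, dt / 2))
    k4 <- f(state$t + dt, axpy(y, k3, dt))
    yn <- Map(function(u, a1, a2, a3, a4) u + dt / 6 * (a1 + 2 * a2 + 2 * a3 + a4),
              y, k1, k2, k3, k4)
    structure(list(q = yn$q, qd = yn$qd, a = yn$a, ad = yn$ad,
                   t = state$t + dt), class = "mb_state")
  }
}

## minimal hand-built chain model (oracle tests): `links` is a list of
## lists with fields type ("r"/"p"), axis, origin (in parent frame), mass,
## com, inertia (3x3 about COM), k, c; a free base is prepended when
## floating = TRUE.  Capsule geometry: point at the COM.
mb_custom <- function(links, floating = FALSE, gravity = GRAV) {
  parent <- integer(0); jtype <- character(0)
  axis <- list(); tr <- list(); Ib <- list()
  body_seg <- character(0); dof_channel <- character(0)
  dof_k <- numeric(0); dof_c <- numeric(0)
  seg_names <- character(0)
  segments <- data.frame(name = character(0), mass = numeric(0),
                         stringsAsFactors = FALSE)
  com_offset <- NULL; inertia <- list()
  cap0 <- NULL; cap1 <- NULL; capr <- numeric(0)
  b <- 0L
  add <- function(par, type, ax, r, seg, k, cc) {
    parent <<- c(parent, par); jtype <<- c(jtype, type)
    axis[[length(axis) + 1L]] <<- ax; tr[[length(tr) + 1L]] <<- r
    body_seg <<- c(body_seg, seg)
    dof_channel <<- c(dof_channel, paste0("dof", length(parent)))
    dof_k <<- c(dof_k, k); dof_c <<- c(dof_c, cc)
    length(parent)
  }
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1); z3 <- c(0, 0, 0)
  base_idx <- integer(0)
  if (floating) {
    b <- add(0L, "p", ex, z3, "", 0, 0)
    b <- add(b, "p", ey, z3, "", 0, 0)
    b <- add(b, "p", ez, z3, "", 0, 0)
    b <- add(b, "r", ex, z3, "", 0, 0)
    b <- add(b, "r", ez, z3, "", 0, 0)
    base_idx <- 1:5
  }
  for (i in seq_along(links)) {
    L <- links[[i]]
    nm <- L$name %||% paste0("link", i)
    b <- add(if (i == 1L) b else b, L$type %||% "r", L$axis %||% ey,
             L$origin %||% z3, nm, L$k %||% 0, L$c %||% 0)
    if (floating && i == 1L) base_idx <- c(base_idx, b)
    seg_names <- c(seg_names, nm)
    segments <- rbind(segments,
                      data.frame(name = nm, mass = L$mass,
                                 stringsAsFactors = FALSE))
    com_offset <- rbind(com_offset, L$com)
    inertia[[nm]] <- L$inertia
    cap0 <- rbind(cap0, L$com); cap1 <- rbind(cap1, L$com)
    capr <- c(capr, L$radius %||% 0.05)
  }
  rownames(com_offset) <- seg_names
  nb <- length(parent)
  Ib <- vector("list", nb)
  seg_body <- integer(0)
  for (i in seq_len(nb)) {
    s <- body_seg[i]
    if (s == "") Ib[[i]] <- matrix(0, 6L, 6L) else {
      k <- which(segments$name == s)
      Ib[[i]] <- spatial_inertia(segments$mass[k], com_offset[k, ],
                                 inertia[[s]])
      seg_body[[s]] <- i
    }
  }
  ped <- structure(list(stature = NA, mass = sum(segments$mass),
                        segments = segments, com_offset = com_offset,
                        inertia = inertia, capsule_p0 = cap0,
                        capsule_p1 = cap1, capsule_r = capr),
                   class = "pedestrian_model")
  structure(list(pedestrian = ped, nb = nb, parent = parent,
                 jtype = jtype, axis = axis, tr = tr, Ibody = Ib,
                 body_seg = body_seg, seg_body = seg_body,
                 dof_channel = dof_channel,
                 chan_idx = stats::setNames(seq_len(nb), dof_channel),
                 dof_k = dof_k, dof_c = dof_c,
                 dof_lo = rep(-Inf, nb), dof_hi = rep(Inf, nb),
                 dof_kstop = rep(0, nb),
                 base_idx = if (length(base_idx)) base_idx else integer(0),
                 modes = data.frame(host = character(0), K = numeric(0),
                                    C = numeric(0), mass = numeric(0)),
                 gravity = gravity),
            class = "mb_model")
}

## total mechanical energy (kinetic + gravitational + joint springs +
## modal) -- diagnostic
mb_energy <- function(model, state, gravity = model$gravity) {
  kin <- mb_seg_kin(model, state$q, state$qd)
  ke <- 0; pe <- 0
  for (s in names(kin)) {
    k <- kin[[s]]
    i <- model$seg_body[[s]]
    ped <- model$pedestrian
    ks <- which(ped$segments$name == s)
    w_b <- as.numeric(k$E %*% k$w)
    ke <- ke + 0.5 * k$mass * sum(k$v_com^2) +
      0.5 * sum(w_b * (ped$inertia[[ks]] %*% w_b))
    pe <- pe + k$mass * gravity * k$com[3L]
  }
  qj <- state$q; qj[model$base_idx] <- 0
  pe_j <- 0.5 * sum(model$dof_k * qj^2)
  pe_m <- 0.5 * sum(model$modes$K * state$a^2)
  ke_m <- 0.5 * sum(model$modes$mass * state$ad^2)
  ke + pe + pe_j + pe_m + ke_m
}
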