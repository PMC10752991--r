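# Internal vectorized "scene" machinery: one flat description of every via
# point and contact node of the hand model, evaluated for all digits at once.
# The simulator leans on this for path lengths, exact path-length gradients
# (moment arms via the tendon-excursion relation) and contact-node
# positions/velocities/Jacobians without per-point R-level loops.

build_scene <- function(model) {
  nd <- length(model$digits)
  Lseg <- t(vapply(model$digits, `[[`, numeric(3), "segment_lengths"))
  anchors <- t(vapply(model$digits, `[[`, numeric(2), "metacarpal_anchor"))
  digit_ids <- vapply(model$digits, `[[`, 1L, "digit_id")

  pd <- integer(0); ps <- integer(0); plx <- numeric(0); ply <- numeric(0)
  ppath <- integer(0)
  e1 <- integer(0); e2 <- integer(0); epath <- integer(0)
  path_digit <- integer(0); path_names <- character(0)
  for (k in seq_along(model$paths)) {
    p <- model$paths[[k]]
    di <- match(paste0("d", p$digit_id), names(model$digits))
    vp <- p$via_points
    n0 <- length(pd)
    pd <- c(pd, rep(di, nrow(vp)))
    ps <- c(ps, vp$segment)
    plx <- c(plx, vp$x); ply <- c(ply, vp$y)
    ppath <- c(ppath, rep(k, nrow(vp)))
    idx <- n0 + seq_len(nrow(vp))
    e1 <- c(e1, idx[-length(idx)]); e2 <- c(e2, idx[-1])
    epath <- c(epath, rep(k, nrow(vp) - 1))
    path_digit <- c(path_digit, di)
    path_names <- c(path_names, p$mtu_name)
  }

  # contact nodes: mid and distal end of each phalanx, on the centerline
  nd_seg <- 3L
  node_d <- rep(seq_len(nd), each = nd_seg * 2)
  node_s <- rep(rep(1:3, each = 2), nd)
  node_f <- rep(c(0.5, 1.0), nd_seg * nd)
  node_lx <- Lseg[cbind(node_d, node_s)] * node_f
  node_ly <- numeric(length(node_lx))

  list(nd = nd, Lseg = Lseg, anchors = anchors, digit_ids = digit_ids,
       pd = pd, ps = ps, plx = plx, ply = ply, ppath = ppath,
       e1 = e1, e2 = e2, epath = epath,
       n_path = length(model$paths), path_digit = path_digit,
       path_names = path_names,
       node_d = node_d, node_s = node_s, node_lx = node_lx,
       node_ly = node_ly)
}

# Evaluate the scene at joint angles q ([nd, 3], flexion positive).
# Returns path lengths, per-path length gradients wrt the owning digit's
# three joint angles (dL[path, j] = dL/dq_j), and contact node positions,
# velocities and Jacobian components.
scene_eval <- function(sc, q, qdot = NULL, need_nodes = FALSE) {
  nd <- sc$nd
  TH <- cbind(0, -q[, 1], -(q[, 1] + q[, 2]),
              -(q[, 1] + q[, 2] + q[, 3]))          # [nd, 4]
  cTH <- cos(TH); sTH <- sin(TH)
  Ox <- matrix(0, nd, 4); Oy <- matrix(0, nd, 4)
  Ox[, 1] <- sc$anchors[, 1]; Oy[, 1] <- sc$anchors[, 2]
  Ox[, 2] <- Ox[, 1];         Oy[, 2] <- Oy[, 1]
  Ox[, 3] <- Ox[, 2] + sc$Lseg[, 1] * cTH[, 2]
  Oy[, 3] <- Oy[, 2] + sc$Lseg[, 1] * sTH[, 2]
  Ox[, 4] <- Ox[, 3] + sc$Lseg[, 2] * cTH[, 3]
  Oy[, 4] <- Oy[, 3] + sc$Lseg[, 2] * sTH[, 3]

  ii <- cbind(sc$pd, sc$ps + 1L)
  cc <- cTH[ii]; ss <- sTH[ii]
  Px <- Ox[ii] + sc$plx * cc - sc$ply * ss
  Py <- Oy[ii] + sc$plx * ss + sc$ply * cc

  dx <- Px[sc$e2] - Px[sc$e1]; dy <- Py[sc$e2] - Py[sc$e1]
  elen <- sqrt(dx * dx + dy * dy)
  L <- as.numeric(rowsum(elen, sc$epath, reorder = TRUE))
  ux <- dx / elen; uy <- dy / elen

  dL <- matrix(0, sc$n_path, 3)
  for (j in 1:3) {
    act <- sc$ps >= j
    cj <- cbind(sc$pd, j + 1L)
    gx <- (Py - Oy[cj]) * act
    gy <- -(Px - Ox[cj]) * act
    dL[, j] <- as.numeric(rowsum(ux * (gx[sc$e2] - gx[sc$e1]) +
                                 uy * (gy[sc$e2] - gy[sc$e1]),
                                 sc$epath, reorder = TRUE))
  }

  out <- list(L = L, dL = dL, Ox = Ox, Oy = Oy, cTH = cTH, sTH = sTH)
  if (need_nodes) {
    ni <- cbind(sc$node_d, sc$node_s + 1L)
    ncc <- cTH[ni]; nss <- sTH[ni]
    Nx <- Ox[ni] + sc$node_lx * ncc - sc$node_ly * nss
    Ny <- Oy[ni] + sc$node_lx * nss + sc$node_ly * ncc
    # node Jacobians wrt the owning digit's joint angles
    NJx <- matrix(0, length(Nx), 3); NJy <- matrix(0, length(Nx), 3)
    for (j in 1:3) {
      act <- sc$node_s >= j
      cj <- cbind(sc$node_d, j + 1L)
      NJx[, j] <- (Ny - Oy[cj]) * act
      NJy[, j] <- -(Nx - Ox[cj]) * act
    }
    out$Nx <- Nx; out$Ny <- Ny; out$NJx <- NJx; out$NJy <- NJy
    if (!is.null(qdot)) {
      out$Nvx <- rowSums(NJx * qdot[sc$node_d, , drop = FALSE])
      out$Nvy <- rowSums(NJy * qdot[sc$node_d, , drop = FALSE])
    }
  }
  if (!is.null(qdot)) {
    out$v_path <- rowSums(dL * qdot[sc$path_digit, , drop = FALSE])
  }
  out
}
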