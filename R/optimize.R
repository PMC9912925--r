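# Geometry optimization backends. The built-in backend is NOT a quantum
# method: it minimizes a deterministic objective assembled from the base
# restraint dictionary (harmonic bonds and angles, periodic cosine
# torsions) plus a soft repulsion between nonbonded pairs, so the whole
# pipeline is testable at desk scale. External semi-empirical engines are
# reached through a file-level adapter (MOPAC-style Cartesian deck writer
# and output parser).

#' Default mobile selection of a cluster
#'
#' Ligand atoms, cap atoms and added water hydrogens move; environment
#' heavy atoms are fixed. With `side_chains = TRUE` the side-chain atoms
#' (everything beyond N, CA, C, O) of model-native amino-acid residues are
#' mobile too. Symmetry-image atoms are always immobile, since moving them
#' would desynchronize them from their source atoms.
#'
#' @param cluster A capped, protonated [ligand_cluster()].
#' @param side_chains Let environment side chains co-optimize.
#' @return Integer vector of cluster atom serials.
#' @export
default_mobile_selection <- function(cluster, side_chains = FALSE) {
  a <- cluster$atoms
  mob <- a$role %in% c("ligand", "cap", "proton")
  if (side_chains) {
    native <- a$operator == 1L & a$shift_a == 0L & a$shift_b == 0L & a$shift_c == 0L
    side <- a$role == "environment" & a$kind == "amino_acid" & native &
      !a$name %in% c("N", "CA", "C", "O", "OXT")
    mob <- mob | side
  }
  img <- a$operator != 1L | a$shift_a != 0L | a$shift_b != 0L | a$shift_c != 0L
  a$serial[mob & !img]
}

#' Define a geometry-optimization job
#'
#' @param cluster A capped, protonated [ligand_cluster()].
#' @param base The base [restraint_dictionary()] of the ligand.
#' @param mobile Atom serials free to move; defaults to
#'   [default_mobile_selection()].
#' @param method `"builtin"`, `"external:PM7"`, `"external:PM6-D3H4"` or
#'   `"external:<name>"`.
#' @param max_steps Maximum minimizer steps (> 0).
#' @param convergence_grad Convergence threshold on the largest gradient
#'   component (objective units per Angstrom).
#' @param total_charge Total charge passed to external engines; defaults
#'   to the dictionary's formal charge.
#' @param side_chains Used when `mobile` is NULL.
#' @return Object of class `optimization_job`.
#' @export
optimization_job <- function(cluster, base, mobile = NULL, method = "builtin",
                             max_steps = 10000L, convergence_grad = 1e-2,
                             total_charge = NULL, side_chains = FALSE) {
  stopifnot(inherits(cluster, "ligand_cluster"))
  stopifnot(inherits(base, "restraint_dictionary"))
  if (max_steps <= 0) abort("max_steps must be positive")
  if (is.null(mobile)) mobile <- default_mobile_selection(cluster, side_chains)
  if (!all(mobile %in% cluster$atoms$serial)) {
    abort("mobile selection references serials outside the cluster")
  }
  structure(
    list(
      cluster = cluster, base = base, mobile = as.integer(mobile),
      method = method, max_steps = as.integer(max_steps),
      convergence_grad = convergence_grad,
      total_charge = if (is.null(total_charge)) base$formal_charge else as.integer(total_charge)
    ),
    class = "optimization_job"
  )
}

# --- objective assembly ----------------------------------------------------

.row_cross <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

.row_norm <- function(m) sqrt(rowSums(m * m))

# Covalent bond list of a cluster, as index pairs into the atom table.
.cluster_bond_pairs <- function(cluster, base) {
  a <- cluster$atoms
  idx_of_serial <- setNames(seq_len(nrow(a)), a$serial)
  pairs <- list()
  lig <- which(a$role == "ligand")
  lig_idx <- setNames(lig, a$name[lig])
  b <- base$bonds
  for (i in seq_len(nrow(b))) {
    ii <- lig_idx[b$atom1[i]]
    jj <- lig_idx[b$atom2[i]]
    if (!is.na(ii) && !is.na(jj)) pairs[[length(pairs) + 1L]] <- c(ii, jj)
  }
  # environment residues: distance rule within each residue copy
  env <- a$role == "environment"
  tag <- paste(.res_key(a), a$operator, a$shift_a, a$shift_b, a$shift_c)
  for (tg in unique(tag[env])) {
    rows <- which(tag == tg & a$role %in% c("environment", "proton"))
    db <- .distance_bonds(a[rows, , drop = FALSE])
    if (!is.null(db)) {
      for (r in seq_len(nrow(db))) {
        pairs[[length(pairs) + 1L]] <- c(rows[db$i[r]], rows[db$j[r]])
      }
    }
  }
  # peptide links between environment residues
  cn <- which(env & a$name == "C")
  nn <- which(env & a$name == "N")
  for (ci in cn) for (ni in nn) {
    if (tag[ci] == tag[ni]) next
    d <- sqrt(sum((as.numeric(a[ci, c("x", "y", "z")]) -
      as.numeric(a[ni, c("x", "y", "z")]))^2))
    if (d < 1.7) pairs[[length(pairs) + 1L]] <- c(ci, ni)
  }
  # caps and protons bind their link atom
  for (r in which(a$role %in% c("cap", "proton"))) {
    ln <- idx_of_serial[as.character(a$link_serial[r])]
    if (!is.na(ln)) pairs[[length(pairs) + 1L]] <- c(r, ln)
  }
  if (!length(pairs)) return(matrix(integer(), 0, 2))
  m <- do.call(rbind, pairs)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  unique(m)
}

# Pairs within `nbonds` bonds of each other (exclusion set for repulsion).
.bonded_within <- function(bond_pairs, n_atoms, nbonds = 3L) {
  adj <- vector("list", n_atoms)
  for (r in seq_len(nrow(bond_pairs))) {
    i <- bond_pairs[r, 1]
    j <- bond_pairs[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  excl <- new.env(parent = emptyenv())
  mark <- function(i, j) {
    if (i != j) assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  }
  for (i in seq_len(n_atoms)) {
    frontier <- i
    seen <- i
    for (depth in seq_len(nbonds)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- setdiff(nxt, seen)
      for (j in nxt) mark(i, j)
      seen <- c(seen, nxt)
      frontier <- nxt
      if (!length(frontier)) break
    }
  }
  excl
}

# Assemble the builtin objective terms for a job. Weights: 1/esd^2 for
# bonds (Angstrom) and angles (radians); torsions use
# k = 2/(esd_rad^2 p^2) with energy k*(1-cos(p*dphi)) so the small-angle
# curvature matches the harmonic e.s.d. weight. Nonbonded soft repulsion
# w*(r0-r)^2 below r0 = 0.75*(vdw_i+vdw_j), skipping 1-2/1-3/1-4 pairs
# and polar-hydrogen/acceptor pairs (hydrogen bonds are wanted contacts).
.build_objective <- function(job) {
  cluster <- job$cluster
  base <- job$base
  a <- cluster$atoms
  n <- nrow(a)
  lig <- which(a$role == "ligand")
  lig_idx <- setNames(lig, a$name[lig])
  deg <- pi / 180

  bonds_i <- integer(); bonds_j <- integer(); bonds_t <- numeric(); bonds_w <- numeric()
  add_bond <- function(i, j, target, esd) {
    bonds_i <<- c(bonds_i, i); bonds_j <<- c(bonds_j, j)
    bonds_t <<- c(bonds_t, target); bonds_w <<- c(bonds_w, 1 / esd^2)
  }
  for (r in seq_len(nrow(base$bonds))) {
    ii <- lig_idx[base$bonds$atom1[r]]
    jj <- lig_idx[base$bonds$atom2[r]]
    if (!is.na(ii) && !is.na(jj)) add_bond(ii, jj, base$bonds$target[r], base$bonds$esd[r])
  }
  ang_i <- integer(); ang_j <- integer(); ang_k <- integer()
  ang_t <- numeric(); ang_w <- numeric()
  add_angle <- function(i, j, k, target_deg, esd_deg) {
    ang_i <<- c(ang_i, i); ang_j <<- c(ang_j, j); ang_k <<- c(ang_k, k)
    ang_t <<- c(ang_t, target_deg * deg); ang_w <<- c(ang_w, 1 / (esd_deg * deg)^2)
  }
  for (r in seq_len(nrow(base$angles))) {
    ii <- lig_idx[base$angles$atom1[r]]
    jj <- lig_idx[base$angles$atom2[r]]
    kk <- lig_idx[base$angles$atom3[r]]
    if (!anyNA(c(ii, jj, kk))) add_angle(ii, jj, kk, base$angles$target[r], base$angles$esd[r])
  }
  tor_i <- integer(); tor_j <- integer(); tor_k <- integer(); tor_l <- integer()
  tor_t <- numeric(); tor_k2 <- numeric(); tor_p <- integer()
  for (r in seq_len(nrow(base$torsions))) {
    ii <- lig_idx[base$torsions$atom1[r]]
    jj <- lig_idx[base$torsions$atom2[r]]
    kk <- lig_idx[base$torsions$atom3[r]]
    ll <- lig_idx[base$torsions$atom4[r]]
    if (anyNA(c(ii, jj, kk, ll))) next
    p <- base$torsions$period[r]
    esd_rad <- base$torsions$esd[r] * deg
    tor_i <- c(tor_i, ii); tor_j <- c(tor_j, jj)
    tor_k <- c(tor_k, kk); tor_l <- c(tor_l, ll)
    tor_t <- c(tor_t, base$torsions$target[r] * deg)
    tor_k2 <- c(tor_k2, 2 / (esd_rad^2 * p^2))
    tor_p <- c(tor_p, p)
  }
  # caps and water protons: restrain to ideal attachment geometry
  for (r in which(a$role == "cap")) {
    ln <- match(a$link_serial[r], a$serial)
    el <- a$element[ln]
    ideal <- if (a$element[r] == "H") {
      dd <- unname(.hx_distance[el]); if (is.na(dd)) 1.0 else dd
    } else {
      1.25 # carboxylate OXT
    }
    add_bond(r, ln, ideal, 0.02)
  }
  water_tag <- paste(.res_key(a), a$operator, a$shift_a, a$shift_b, a$shift_c)
  for (tg in unique(water_tag[a$kind == "water"])) {
    rows <- which(water_tag == tg)
    o <- rows[!a$is_hydrogen[rows]][1]
    hs <- rows[a$is_hydrogen[rows]]
    for (h in hs) add_bond(h, o, .water_h_geometry$oh, 0.02)
    if (length(hs) == 2) add_angle(hs[1], o, hs[2], .water_h_geometry$hoh, 2)
  }
  # mobile environment side chains: restrain bonds to their input lengths
  mobile_rows <- match(job$mobile, a$serial)
  bond_pairs <- .cluster_bond_pairs(cluster, base)
  xyz0 <- as.matrix(a[, c("x", "y", "z")])
  side_rows <- setdiff(mobile_rows, c(lig, which(a$role %in% c("cap", "proton"))))
  if (length(side_rows)) {
    for (r in seq_len(nrow(bond_pairs))) {
      i <- bond_pairs[r, 1]; j <- bond_pairs[r, 2]
      if ((i %in% side_rows || j %in% side_rows) &&
        !(i %in% lig) && !(j %in% lig) &&
        !a$role[i] %in% c("cap", "proton") && !a$role[j] %in% c("cap", "proton")) {
        add_bond(i, j, sqrt(sum((xyz0[i, ] - xyz0[j, ])^2)), 0.02)
      }
    }
  }
  # nonbonded soft repulsion
  excl <- .bonded_within(bond_pairs, n, 3L)
  is_mob <- seq_len(n) %in% mobile_rows
  polar_h <- a$is_hydrogen & vapply(seq_len(n), function(r) {
    ln <- match(a$link_serial[r], a$serial)
    if (!is.na(ln)) return(a$element[ln] %in% c("O", "N"))
    FALSE
  }, logical(1))
  acceptor <- a$element %in% c("O", "N")
  nb_i <- integer(); nb_j <- integer(); nb_r0 <- numeric()
  vdw <- vdw_radius(a$element)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!is_mob[i] && !is_mob[j]) next
      if (exists(paste(i, j), envir = excl, inherits = FALSE)) next
      if ((polar_h[i] && acceptor[j]) || (polar_h[j] && acceptor[i])) next
      nb_i <- c(nb_i, i); nb_j <- c(nb_j, j)
      nb_r0 <- c(nb_r0, 0.75 * (vdw[i] + vdw[j]))
    }
  }
  list(
    bonds = list(i = bonds_i, j = bonds_j, t = bonds_t, w = bonds_w),
    angles = list(i = ang_i, j = ang_j, k = ang_k, t = ang_t, w = ang_w),
    torsions = list(
      i = tor_i, j = tor_j, k = tor_k, l = tor_l, t = tor_t,
      kf = tor_k2, p = tor_p
    ),
    nb = list(i = nb_i, j = nb_j, r0 = nb_r0, w = 100),
    n_atoms = n
  )
}

.acc_grad <- function(grad, idx, contrib) {
  if (!length(idx)) return(grad)
  s <- rowsum(contrib, group = idx)
  gi <- as.integer(rownames(s))
  grad[gi, ] <- grad[gi, ] + s
  grad
}

# Objective value and gradient at positions P (n x 3 matrix).
.objective_eval <- function(terms, P, want_grad = TRUE) {
  E <- 0
  grad <- if (want_grad) matrix(0, terms$n_atoms, 3) else NULL
  b <- terms$bonds
  if (length(b$i)) {
    dv <- P[b$i, , drop = FALSE] - P[b$j, , drop = FALSE]
    d <- .row_norm(dv)
    E <- E + sum(b$w * (d - b$t)^2)
    if (want_grad) {
      f <- 2 * b$w * (d - b$t) / pmax(d, 1e-12)
      g1 <- dv * f
      grad <- .acc_grad(grad, b$i, g1)
      grad <- .acc_grad(grad, b$j, -g1)
    }
  }
  an <- terms$angles
  if (length(an$i)) {
    u <- P[an$i, , drop = FALSE] - P[an$j, , drop = FALSE]
    v <- P[an$k, , drop = FALSE] - P[an$j, , drop = FALSE]
    nu <- .row_norm(u)
    nv <- .row_norm(v)
    cosv <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    th <- acos(cosv)
    E <- E + sum(an$w * (th - an$t)^2)
    if (want_grad) {
      sinv <- pmax(sqrt(1 - cosv^2), 1e-8)
      uh <- u / nu
      vh <- v / nv
      dEdth <- 2 * an$w * (th - an$t)
      gi <- (uh * cosv - vh) / (nu * sinv) * dEdth
      gk <- (vh * cosv - uh) / (nv * sinv) * dEdth
      grad <- .acc_grad(grad, an$i, gi)
      grad <- .acc_grad(grad, an$k, gk)
      grad <- .acc_grad(grad, an$j, -(gi + gk))
    }
  }
  to <- terms$torsions
  if (length(to$i)) {
    b1 <- P[to$j, , drop = FALSE] - P[to$i, , drop = FALSE]
    b2 <- P[to$k, , drop = FALSE] - P[to$j, , drop = FALSE]
    b3 <- P[to$l, , drop = FALSE] - P[to$k, , drop = FALSE]
    n1 <- .row_cross(b1, b2)
    n2 <- .row_cross(b2, b3)
    nb2 <- .row_norm(b2)
    b2h <- b2 / nb2
    phi <- atan2(rowSums(.row_cross(n1, n2) * b2h), rowSums(n1 * n2))
    dphi <- phi - to$t
    E <- E + sum(to$kf * (1 - cos(to$p * dphi)))
    if (want_grad) {
      dEdphi <- to$kf * to$p * sin(to$p * dphi)
      n1sq <- pmax(rowSums(n1 * n1), 1e-12)
      n2sq <- pmax(rowSums(n2 * n2), 1e-12)
      Fv <- -n1 * (nb2 / n1sq)
      Gv <- n2 * (nb2 / n2sq)
      c12 <- rowSums(b1 * b2) / nb2^2
      c32 <- rowSums(b3 * b2) / nb2^2
      d2 <- -Fv * (1 + c12) + Gv * c32
      d3 <- Fv * c12 - Gv * (1 + c32)
      grad <- .acc_grad(grad, to$i, Fv * dEdphi)
      grad <- .acc_grad(grad, to$j, d2 * dEdphi)
      grad <- .acc_grad(grad, to$k, d3 * dEdphi)
      grad <- .acc_grad(grad, to$l, Gv * dEdphi)
    }
  }
  nb <- terms$nb
  if (length(nb$i)) {
    dv <- P[nb$i, , drop = FALSE] - P[nb$j, , drop = FALSE]
    d <- .row_norm(dv)
    pen <- pmax(nb$r0 - d, 0)
    E <- E + nb$w * sum(pen^2)
    if (want_grad) {
      f <- -2 * nb$w * pen / pmax(d, 1e-12)
      g1 <- dv * f
      grad <- .acc_grad(grad, nb$i, g1)
      grad <- .acc_grad(grad, nb$j, -g1)
    }
  }
  list(E = E, grad = grad)
}

# Rough per-atom curvature estimate used as a diagonal preconditioner.
.precondition <- function(terms) {
  c_at <- rep(1, terms$n_atoms)
  add <- function(idx, val) {
    for (r in seq_along(idx)) c_at[idx[r]] <<- c_at[idx[r]] + val[r]
  }
  b <- terms$bonds
  add(b$i, 2 * b$w); add(b$j, 2 * b$w)
  an <- terms$angles
  add(an$i, 2 * an$w); add(an$j, 4 * an$w); add(an$k, 2 * an$w)
  to <- terms$torsions
  kp2 <- 2 * to$kf * to$p^2
  add(to$i, kp2); add(to$j, kp2); add(to$k, kp2); add(to$l, kp2)
  nb <- terms$nb
  add(nb$i, rep(2 * nb$w, length(nb$i)))
  add(nb$j, rep(2 * nb$w, length(nb$j)))
  c_at
}

#' Built-in deterministic restrained minimizer
#'
#' Minimizes the dictionary-restraint objective (harmonic bonds/angles,
#' periodic cosine torsions, soft nonbonded repulsion) over the mobile
#' atoms by diagonally preconditioned gradient descent with backtracking
#' (Armijo) line search. Deterministic: no randomness anywhere, so the
#' same input yields the same trajectory.
#'
#' @param job An [optimization_job()].
#' @return Object of class `optimization_result` with `positions` (full
#'   n x 3 matrix in cluster serial order), `final_objective`, `n_steps`,
#'   `converged`, `trace` (non-increasing objective values) and the
#'   updated `cluster`.
#' @export
builtin_minimize <- function(job) {
  stopifnot(inherits(job, "optimization_job"))
  cluster <- job$cluster
  a <- cluster$atoms
  terms <- .build_objective(job)
  mobile_rows <- match(job$mobile, a$serial)
  covered <- unique(c(
    terms$bonds$i, terms$bonds$j, terms$angles$i, terms$angles$j,
    terms$angles$k, terms$torsions$i, terms$torsions$j, terms$torsions$k,
    terms$torsions$l, terms$nb$i, terms$nb$j
  ))
  uncovered <- setdiff(mobile_rows, covered)
  if (length(uncovered)) {
    abort(sprintf(
      "mobile atom(s) %s have no restraint or nonbonded term",
      paste(a$name[uncovered], collapse = ", ")
    ))
  }
  P <- unname(as.matrix(a[, c("x", "y", "z")]))
  cond <- .precondition(terms)
  ev <- .objective_eval(terms, P)
  trace <- ev$E
  n_steps <- 0L
  converged <- FALSE
  dir <- NULL
  g_prev <- NULL
  pg_prev <- NULL
  alpha0 <- 1
  criterion <- NA_character_
  n_stalled <- 0L
  for (step in seq_len(job$max_steps)) {
    g <- ev$grad
    g[-mobile_rows, ] <- 0
    gmax <- max(abs(g))
    if (!is.finite(gmax) || gmax > 1e6) {
      abort(sprintf(
        "exploding gradient (%.3g) at step %d: objective %.3g",
        gmax, step, ev$E
      ))
    }
    if (gmax < job$convergence_grad) {
      converged <- TRUE
      criterion <- "gradient"
      break
    }
    # preconditioned conjugate-gradient direction (Polak-Ribiere+, with
    # automatic reset to plain preconditioned descent when not downhill)
    pg <- g / cond
    if (is.null(dir)) {
      dir <- -pg
    } else {
      beta <- sum(g * (pg - pg_prev)) / max(sum(g_prev * pg_prev), 1e-300)
      beta <- max(0, beta)
      dir <- -pg + beta * dir
    }
    slope <- sum(g * dir)
    if (slope >= 0) {
      dir <- -pg
      slope <- sum(g * dir)
    }
    g_prev <- g
    pg_prev <- pg
    alpha <- alpha0
    accepted <- FALSE
    try_at <- function(al) {
      P_try <- P
      P_try[mobile_rows, ] <- P[mobile_rows, ] + al * dir[mobile_rows, ]
      list(P = P_try, ev = .objective_eval(terms, P_try))
    }
    while (alpha > 1e-12) {
      cand <- try_at(alpha)
      if (is.finite(cand$ev$E) && cand$ev$E <= ev$E + 1e-4 * alpha * slope) {
        # guard against barely-decreasing overshoots: shrink while that
        # strictly improves the objective
        while (alpha > 1e-12) {
          probe <- try_at(alpha / 2)
          if (is.finite(probe$ev$E) && probe$ev$E < cand$ev$E) {
            alpha <- alpha / 2
            cand <- probe
          } else {
            break
          }
        }
        P <- cand$P
        ev <- cand$ev
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break # no descent possible at machine step size
    alpha0 <- min(64, alpha * 2)
    n_steps <- n_steps + 1L
    E_prev <- trace[length(trace)]
    trace <- c(trace, ev$E)
    # objective-stationarity stop: the line search only finds decreases
    # below machine-relevant size for many consecutive steps
    if (E_prev - ev$E <= 1e-12 + 1e-9 * abs(E_prev)) {
      n_stalled <- n_stalled + 1L
      if (n_stalled >= 25L) {
        converged <- TRUE
        criterion <- "objective"
        break
      }
    } else {
      n_stalled <- 0L
    }
  }
  if (!converged) {
    g <- ev$grad
    g[-mobile_rows, ] <- 0
    converged <- max(abs(g)) < job$convergence_grad
    if (converged) criterion <- "gradient"
  }
  out_cluster <- cluster
  out_cluster$atoms$x <- P[, 1]
  out_cluster$atoms$y <- P[, 2]
  out_cluster$atoms$z <- P[, 3]
  structure(
    list(
      positions = P, final_objective = ev$E, n_steps = n_steps,
      converged = converged, criterion = criterion, trace = trace,
      method = "builtin", cluster = out_cluster
    ),
    class = "optimization_result"
  )
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf(
    "<optimization_result [%s]: %d steps, objective %.6g, %s>\n",
    x$method, x$n_steps, x$final_objective,
    if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.optimization_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_steps = x$n_steps,
    final_objective = x$final_objective, converged = x$converged
  )
}

# --- cache -----------------------------------------------------------------

.job_hash <- function(job) {
  a <- job$cluster$atoms
  canon <- c(
    job$method, job$total_charge, job$max_steps,
    sprintf("%g", job$convergence_grad),
    paste(sort(job$mobile), collapse = ","),
    paste(a$name, a$element, sprintf("%.7f", a$x), sprintf("%.7f", a$y),
      sprintf("%.7f", a$z),
      collapse = ";"
    ),
    paste(sprintf("%.6f", job$base$bonds$target), collapse = ","),
    paste(sprintf("%.6f", job$base$angles$target), collapse = ","),
    paste(sprintf("%.6f", job$base$torsions$target), collapse = ",")
  )
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}

.cache_path <- function(cache_dir, hash) {
  file.path(cache_dir, sprintf("qmr-opt-%s.json", hash))
}

.cache_write <- function(path, result, hash) {
  obj <- list(
    hash = hash, method = result$method, n_steps = result$n_steps,
    converged = result$converged, final_objective = result$final_objective,
    trace = result$trace,
    positions = unname(as.matrix(result$positions))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

.cache_read <- function(path, job, hash) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$hash, unname(hash))) return(NULL)
  P <- matrix(as.numeric(obj$positions), ncol = 3)
  out_cluster <- job$cluster
  out_cluster$atoms$x <- P[, 1]
  out_cluster$atoms$y <- P[, 2]
  out_cluster$atoms$z <- P[, 3]
  structure(
    list(
      positions = P, final_objective = obj$final_objective,
      n_steps = obj$n_steps, converged = obj$converged,
      trace = obj$trace, method = obj$method, cluster = out_cluster,
      from_cache = TRUE
    ),
    class = "optimization_result"
  )
}

#' Run a geometry-optimization job
#'
#' Dispatches to the requested backend. Results are cached to a sidecar
#' JSON file keyed by a content hash of the job (method, charge, mobile
#' set, all coordinates to 1e-7 Angstrom, dictionary targets), so repeated
#' runs of an identical job read the file instead of re-optimizing.
#'
#' @param job An [optimization_job()].
#' @param cache_dir Optional directory for sidecar cache files.
#' @param runner For external methods: a function taking the input deck
#'   (character vector) and returning the engine output text. Without it,
#'   external methods raise an actionable error naming the adapter.
#' @return An `optimization_result` (with `from_cache = TRUE` on a hit).
#' @export
optimize_cluster <- function(job, cache_dir = NULL, runner = NULL) {
  stopifnot(inherits(job, "optimization_job"))
  hash <- .job_hash(job)
  if (!is.null(cache_dir)) {
    path <- .cache_path(cache_dir, hash)
    if (file.exists(path)) {
      hit <- .cache_read(path, job, hash)
      if (!is.null(hit)) return(hit)
    }
  }
  result <- if (identical(job$method, "builtin")) {
    builtin_minimize(job)
  } else if (startsWith(job$method, "external:")) {
    engine <- sub("^external:", "", job$method)
    if (is.null(runner)) {
      abort(sprintf(
        paste0(
          "external engine adapter '%s' is not configured: supply a ",
          "`runner` function that executes the deck written by ",
          "write_external_input()"
        ),
        engine
      ))
    }
    deck <- write_external_input(job)
    out <- runner(deck)
    res <- parse_external_output(out, n_atoms = nrow(job$cluster$atoms))
    out_cluster <- job$cluster
    out_cluster$atoms$x <- res$positions[, 1]
    out_cluster$atoms$y <- res$positions[, 2]
    out_cluster$atoms$z <- res$positions[, 3]
    res$cluster <- out_cluster
    res$method <- job$method
    res
  } else {
    abort(sprintf("unknown optimization method '%s'", job$method))
  }
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    .cache_write(.cache_path(cache_dir, hash), result, hash)
  }
  result
}

# --- external-engine adapter -----------------------------------------------

#' Write a MOPAC-style Cartesian input deck for an external engine
#'
#' First line: method keyword and charge directive; then a title line and
#' a blank line; then one row per atom, `element x flag y flag z flag`,
#' flag 1 for optimized (mobile) coordinates and 0 for fixed ones, in
#' cluster serial order.
#'
#' @param job An [optimization_job()] with an `external:` method.
#' @return Character vector: the deck lines.
#' @export
write_external_input <- function(job) {
  stopifnot(inherits(job, "optimization_job"))
  if (!startsWith(job$method, "external:")) {
    abort("write_external_input needs an external method")
  }
  engine <- sub("^external:", "", job$method)
  a <- job$cluster$atoms
  mob <- a$serial %in% job$mobile
  flag <- ifelse(mob, 1L, 0L)
  c(
    sprintf("%s CHARGE=%d XYZ PRECISE", engine, job$total_charge),
    sprintf(
      "qmrestraints cluster %s %s/%s/%d",
      job$cluster$model_id, job$cluster$ligand$chain_id,
      job$cluster$ligand$comp_id, job$cluster$ligand$seq_id
    ),
    "",
    sprintf(
      " %-2s %14.8f %d %14.8f %d %14.8f %d",
      a$element, a$x, flag, a$y, flag, a$z, flag
    )
  )
}

#' Parse the output of an external engine run
#'
#' Extracts the final Cartesian coordinate block (the last block following
#' a `CARTESIAN COORDINATES` header) and the final heat-of-formation-like
#' scalar. Coordinate order must match the deck (cluster serial order).
#'
#' @param text Engine output (character scalar or lines).
#' @param n_atoms Expected number of atoms.
#' @return An `optimization_result` without a cluster (the caller rebuilds
#'   it); `converged` is TRUE unless the output flags otherwise.
#' @export
parse_external_output <- function(text, n_atoms) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  hof <- NA_real_
  hof_lines <- grep("FINAL HEAT OF FORMATION", lines, value = TRUE)
  if (length(hof_lines)) {
    m <- regmatches(
      hof_lines[length(hof_lines)],
      regexpr("-?[0-9]+\\.?[0-9]*", hof_lines[length(hof_lines)])
    )
    if (length(m)) hof <- as.numeric(m)
  }
  hdr <- grep("CARTESIAN COORDINATES", lines)
  if (!length(hdr)) {
    excerpt <- paste(utils::tail(lines, 5), collapse = " | ")
    abort(sprintf(
      "engine output lacks a final geometry block (tail: %s)", excerpt
    ))
  }
  start <- hdr[length(hdr)] + 1L
  pat <- "^\\s*\\d+\\s+[A-Za-z]{1,2}\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)\\s+(-?[0-9.]+)\\s*$"
  rows <- list()
  i <- start
  while (i <= length(lines)) {
    if (grepl(pat, lines[i])) {
      nums <- as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]][3:5])
      rows[[length(rows) + 1L]] <- nums
    } else if (length(rows)) {
      break
    }
    i <- i + 1L
  }
  if (length(rows) != n_atoms) {
    abort(sprintf(
      "engine output geometry has %d atoms, expected %d",
      length(rows), n_atoms
    ))
  }
  structure(
    list(
      positions = do.call(rbind, rows), final_objective = hof,
      n_steps = NA_integer_, converged = TRUE, trace = numeric(),
      method = "external"
    ),
    class = "optimization_result"
  )
}
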