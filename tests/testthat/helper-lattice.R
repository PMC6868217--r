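# Shared fixtures and independent oracles, all built in code.

# Apply an arbitrary rigid motion to a lattice (for invariance tests).
rigid_move <- function(lat, axis = c(1, 2, 3), angle = 33,
                       shift = c(100, -50, 20)) {
  R <- mtlattice:::rotation_about_axis(axis, angle)
  transform_lattice(lat, R, shift)
}

# Brute-force superposition oracle for the known-axis family: target is a
# z-rotation (+ translation) of source; exhaustive 1D grid search over the
# rotation angle after centroid alignment.
grid_superpose_z <- function(source, target, step = 0.1) {
  A <- sweep(source, 2, colMeans(source))
  B <- sweep(target, 2, colMeans(target))
  angles <- seq(0, 360 - step, by = step)
  best <- Inf
  for (ang in angles) {
    R <- mtlattice:::rotation_z(ang)
    r <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
    if (r < best) best <- r
  }
  best
}

# Exhaustive optimal assignment oracle for transfer_assignments:
# maximize number of matches, then minimize total scaled distance, over
# all tolerance-admissible one-to-one pairings (DFS).
optimal_transfer <- function(solution, observed,
                             tol = c(HN = 0.1, N = 0.6, CA = 0.5)) {
  dims <- intersect(c("HN", "N", "CA"),
                    intersect(names(solution), names(observed)))
  n_s <- nrow(solution); n_o <- nrow(observed)
  adm <- vector("list", n_s)
  dmat <- matrix(Inf, n_s, n_o)
  for (i in seq_len(n_s)) {
    ok <- rep(TRUE, n_o); d2 <- rep(0, n_o)
    for (d in dims) {
      dev <- observed[[d]] - solution[[d]][i]
      ok <- ok & abs(dev) <= tol[[d]]
      d2 <- d2 + (dev / tol[[d]])^2
    }
    adm[[i]] <- which(ok)
    dmat[i, ok] <- sqrt(d2[ok])
  }
  best <- list(n = -1L, dist = Inf, pairs = NULL)
  dfs <- function(i, used, pairs, dist) {
    if (i > n_s) {
      n <- nrow(pairs) %||% 0L
      if (n > best$n || (n == best$n && dist < best$dist))
        best <<- list(n = n, dist = dist, pairs = pairs)
      return(invisible())
    }
    for (j in adm[[i]]) {
      if (!used[j]) {
        used[j] <- TRUE
        dfs(i + 1L, used, rbind(pairs, c(i, j)), dist + dmat[i, j])
        used[j] <- FALSE
      }
    }
    dfs(i + 1L, used, pairs, dist)  # leave solution i unmatched
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  dfs(1L, logical(n_o), NULL, 0)
  best
}

# Synthetic four-subunit binding-site model with a CKK body reaching into
# the interprotofilament wedge: one chain per tubulin monomer around a
# chosen junction, CKK pseudo-atoms placed a controlled distance from the
# nearest atom of each monomer.
synthetic_site_model <- function(lat, junction = 3, reach = 4.9) {
  stopifnot(inherits(lat, "mt_lattice"))
  bs <- enumerate_binding_sites(lat)
  site <- bs[bs$junction == junction & bs$dimer == 0, ]
  near <- lat$monomers[lat$monomers$pf %in% c(junction, junction + 1) &
                         lat$monomers$dimer == 0, ]
  atoms <- NULL; roles <- character(0); ckk <- NULL
  for (i in seq_len(nrow(near))) {
    ch <- LETTERS[i]
    roles[ch] <- paste0(ifelse(near$kind[i] == "alpha", "alpha", "beta"),
                        ifelse(near$pf[i] == junction, 1, 2))
    aa <- lat$atoms[lat$atoms$pf == near$pf[i] &
                      lat$atoms$j == near$j[i], ]
    atoms <- rbind(atoms, data.frame(
      chain = ch, resno = aa$j + 1, insert = "", resid = "TUB",
      elety = paste0("A", aa$atom), x = aa$x, y = aa$y, z = aa$z))
    # one CKK atom `reach` Angstrom from this monomer's nearest atom,
    # on the segment toward the site centre
    d <- sqrt((aa$x - site$x)^2 + (aa$y - site$y)^2 + (aa$z - site$z)^2)
    k <- which.min(d)
    v <- c(site$x - aa$x[k], site$y - aa$y[k], site$z - aa$z[k])
    v <- v / sqrt(sum(v^2))
    ckk <- rbind(ckk, data.frame(
      chain = "K", resno = i, insert = "", resid = "CKK", elety = "CA",
      x = aa$x[k] + reach * v[1], y = aa$y[k] + reach * v[2],
      z = aa$z[k] + reach * v[3]))
  }
  roles["K"] <- "CKK"
  structure(list(atoms = rbind(atoms, ckk), chain_roles = roles,
                 source = "synthetic"),
            class = "structure_model")
}

# Small synthetic protein-like model for region_rmsd tests: one chain,
# backbone N/CA/C/O atoms on a jittered path.
synthetic_protein_model <- function(n_res = 30, chain = "A", seed = 1) {
  set.seed(seed)
  bb <- c("N", "CA", "C", "O")
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    base <- c(3.8 * r, 2 * sin(r / 3), 2 * cos(r / 3))
    off <- matrix(c(0, 0, 0, 1.5, 0.4, 0, 2.4, 1.6, 0.3, 2.5, 2.8, 0.2),
                  ncol = 3, byrow = TRUE)
    data.frame(chain = chain, resno = r, insert = "", resid = "ALA",
               elety = bb, x = base[1] + off[, 1] + rnorm(4, 0, 0.05),
               y = base[2] + off[, 2] + rnorm(4, 0, 0.05),
               z = base[3] + off[, 3] + rnorm(4, 0, 0.05))
  }))
  structure(list(atoms = atoms,
                 chain_roles = stats::setNames("unknown", chain),
                 source = "synthetic"),
            class = "structure_model")
}
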