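## Coordinate-model I/O and model-space measurements: PDB/mmCIF parsing
## (via bio3d), synthetic-lattice export, the 5-Angstrom contact footprint
## of a bound CKK domain, and per-region backbone RMSD after core
## superposition.

#' Read a coordinate model (PDB or mmCIF)
#'
#' Parses a coordinate file into a flat atom table with chain-role
#' annotation. Roles identify which chains are the CKK domain and which
#' are tubulin subunits (alpha1/beta1/alpha2/beta2 in a dimer pair);
#' deposited chain identifiers are not standardized, so the mapping is
#' supplied by the caller (optionally from a JSON sidecar file).
#'
#' @param path PDB (`.pdb`) or mmCIF (`.cif`) file.
#' @param chain_roles Named character vector mapping chain IDs to roles
#'   (e.g. `c(K = "CKK", A = "alpha1", B = "beta1")`), a path to a JSON
#'   file with that mapping, or NULL (roles marked "unknown").
#' @return Object of class `structure_model`: list with `atoms` (chain,
#'   resno, insert, resid, elety, x, y, z), `chain_roles` and `source`.
#' @export
read_model <- function(path, chain_roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch(
    switch(ext,
           cif = bio3d::read.cif(path, verbose = FALSE),
           bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) stop("malformed coordinate file '", path,
                             "': ", conditionMessage(e)))
  at <- parsed$atom
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resid = at$resid, elety = at$elety,
                      x = at$x, y = at$y, z = at$z)
  if (is.character(chain_roles) && length(chain_roles) == 1 &&
      file.exists(chain_roles)) {
    chain_roles <- unlist(jsonlite::read_json(chain_roles))
  }
  roles <- stats::setNames(rep("unknown", length(unique(atoms$chain))),
                           unique(atoms$chain))
  if (!is.null(chain_roles)) {
    known <- intersect(names(chain_roles), names(roles))
    roles[known] <- chain_roles[known]
  }
  structure(list(atoms = atoms, chain_roles = roles, source = path),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure model: %d atoms, %d chains (%s)\n",
              nrow(x$atoms), length(x$chain_roles),
              paste(names(x$chain_roles), x$chain_roles, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' Write a synthetic lattice as a PDB file
#'
#' One chain per protofilament (A, B, C, ...), one residue per monomer
#' (residue names TBA for alpha- and TBB for beta-tubulin, residue number
#' = axial monomer index + 1), and the five body pseudo-atoms as carbon
#' records named A1..A5.
#'
#' @param lat An `mt_lattice`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_lattice_pdb <- function(lat, path) {
  stopifnot(inherits(lat, "mt_lattice"))
  a <- lat$atoms[order(lat$atoms$pf, lat$atoms$j, lat$atoms$atom), ]
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    chain = LETTERS[a$pf + 1L],
    resno = a$j + 1L,
    resid = ifelse(a$kind == "alpha", "TBA", "TBB"),
    eleno = seq_len(nrow(a)),
    elety = paste0("A", a$atom),
    elesy = rep("C", nrow(a)))
  invisible(path)
}

#' Reconstruct a lattice object from a written lattice model
#'
#' Inverse of [write_lattice_pdb()] for measurement on re-loaded files:
#' protofilament index from the chain letter, axial index from the residue
#' number, kind from the residue name. The truth record cannot be
#' recovered from coordinates; generator metadata (`n_dimers`, seam, ...)
#' is taken from `spec` when supplied, otherwise inferred minimally.
#'
#' @param model A `structure_model` written by [write_lattice_pdb()].
#' @param spec Optional original [lattice_spec()].
#' @return An `mt_lattice` with coordinates from the model.
#' @export
lattice_from_model <- function(model, spec = NULL) {
  at <- model$atoms
  pf <- match(at$chain, LETTERS) - 1L
  j <- at$resno - 1L
  n_pf <- length(unique(pf))
  n_dimers <- (max(j) + 1L) %/% 2L
  spec <- spec %||% lattice_spec(n_pf = n_pf, n_dimers = n_dimers)
  lat <- build_lattice(spec)
  ord <- order(pf, j, at$elety)
  at <- at[ord, ]
  key_new <- paste(pf[ord], j[ord], at$elety)
  key_lat <- paste(lat$atoms$pf, lat$atoms$j, paste0("A", lat$atoms$atom))
  idx <- match(key_lat, key_new)
  if (anyNA(idx)) stop("model does not look like a written lattice")
  lat$atoms[, c("x", "y", "z")] <- at[idx, c("x", "y", "z")]
  n_at <- 5L
  for (v in c("x", "y", "z")) {
    lat$monomers[[v]] <- colMeans(matrix(lat$atoms[[v]], nrow = n_at))
  }
  lat
}

#' Contact footprint of the bound CKK domain
#'
#' Residues of each tubulin subunit with any atom within the cutoff
#' distance (inclusive) of any CKK atom — the distance-cutoff analogue of
#' the footprint colouring at < 5 Angstrom. Counts per subunit support
#' the alpha- versus beta-tubulin contact comparison; they are contact
#' counts, not buried-surface areas.
#'
#' @param model A `structure_model` with chain roles annotated (one role
#'   must be `"CKK"`).
#' @param cutoff Contact distance in Angstrom (default 5).
#' @return List of class `footprint_result`: `residues` (per-subunit
#'   residue-number vectors), `counts` (per-subunit contact-residue
#'   counts) and `cutoff`.
#' @export
contact_footprint <- function(model, cutoff = 5) {
  stopifnot(inherits(model, "structure_model"))
  roles <- model$chain_roles
  if (all(roles == "unknown")) stop("chain roles not annotated")
  ckk_chains <- names(roles)[roles == "CKK"]
  if (!length(ckk_chains)) stop("no chain annotated as CKK")
  at <- model$atoms
  ckk <- as.matrix(at[at$chain %in% ckk_chains, c("x", "y", "z")])
  subunits <- setdiff(unique(roles), c("CKK", "unknown"))
  residues <- counts <- list()
  for (su in subunits) {
    chains <- names(roles)[roles == su]
    tu <- at[at$chain %in% chains, ]
    if (nrow(tu) == 0 || cutoff <= 0 || nrow(ckk) == 0) {
      residues[[su]] <- integer(0); counts[[su]] <- 0L; next
    }
    xyz <- as.matrix(tu[, c("x", "y", "z")])
    ## min distance of each tubulin atom to any CKK atom
    d2 <- outer(rowSums(xyz^2), rep(1, nrow(ckk))) +
      outer(rep(1, nrow(xyz)), rowSums(ckk^2)) - 2 * xyz %*% t(ckk)
    mind <- sqrt(pmax(apply(d2, 1, min), 0))
    hit <- sort(unique(tu$resno[mind <= cutoff]))
    residues[[su]] <- hit
    counts[[su]] <- length(hit)
  }
  structure(list(residues = residues, counts = unlist(counts),
                 cutoff = cutoff),
            class = "footprint_result")
}

#' @export
print.footprint_result <- function(x, ...) {
  cat(sprintf("Contact footprint at %.1f A cutoff:\n", x$cutoff))
  for (su in names(x$counts))
    cat(sprintf("  %-8s %d contact residues\n", su, x$counts[[su]]))
  invisible(x)
}

## Parse a "chain:first-last" selection string.
parse_selection <- function(sel) {
  m <- regmatches(sel, regexec("^([A-Za-z0-9]):(-?[0-9]+)-(-?[0-9]+)$",
                               sel))[[1]]
  if (length(m) != 4) stop("bad selection '", sel,
                           "': use \"chain:first-last\"")
  list(chain = m[2], first = as.integer(m[3]), last = as.integer(m[4]))
}

## Extract corresponded backbone coordinates for a selection from two
## models; correspondence is by chain + residue number + atom name.
matched_backbone <- function(modelA, modelB, sel,
                             backbone = c("N", "CA", "C", "O")) {
  s <- parse_selection(sel)
  pick <- function(m) {
    at <- m$atoms
    at[at$chain == s$chain & at$resno >= s$first & at$resno <= s$last &
         at$elety %in% backbone, ]
  }
  a <- pick(modelA); b <- pick(modelB)
  key <- function(d) paste(d$chain, d$resno, d$insert, d$elety)
  common <- intersect(key(a), key(b))
  if (!length(common)) stop("empty correspondence for selection ", sel)
  list(A = as.matrix(a[match(common, key(a)), c("x", "y", "z")]),
       B = as.matrix(b[match(common, key(b)), c("x", "y", "z")]))
}

#' Per-region backbone RMSD after core superposition
#'
#' Superposes `modelB` onto `modelA` using the backbone (N, CA, C, O)
#' atoms of the core selection, then reports the backbone RMSD of each
#' region selection under that single transform — the standard way to
#' quantify divergent loops (e.g. loop3, the C-terminal single-turn helix
#' and the beta-hairpin into loop7 of CKK orthologs) over a conserved
#' core.
#'
#' @param modelA,modelB `structure_model` objects.
#' @param core_selection Selection string `"chain:first-last"` defining
#'   the superposition core.
#' @param region_selections Named character vector of region selections.
#' @return Named numeric vector of per-region backbone RMSDs (Angstrom),
#'   with the core residual as attribute `core_rmsd`.
#' @export
region_rmsd <- function(modelA, modelB, core_selection,
                        region_selections) {
  core <- matched_backbone(modelA, modelB, core_selection)
  fit <- superpose_rigid(core$B, core$A)
  out <- vapply(region_selections, function(sel) {
    reg <- matched_backbone(modelA, modelB, sel)
    moved <- apply_rigid(reg$B, fit$rotation, fit$translation)
    sqrt(mean(rowSums((moved - reg$A)^2)))
  }, numeric(1))
  attr(out, "core_rmsd") <- fit$rmsd
  out
}
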