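# Geometric feature detectors for pZBD structural analysis: zinc
# coordination spheres, (long-range) side-chain hydrogen bonds, the
# Tyr-(i+4) backbone H-bond, Arg-aromatic cation-pi contacts, and
# least-squares rigid superposition.
#
# Thresholds follow standard structural-biology practice (they are not
# taken from any single structure): Zn-ligand 2.8 A, heavy-atom H-bond
# 3.5 A, cation-pi 6.0 A centroid distance with the centroid-cation vector
# within 45 degrees of the ring normal.  Hydrogens are ignored throughout;
# donor/acceptor chemistry is simplified to heavy N/O atoms.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

## aromatic six-membered ring atoms per residue type
RING_ATOMS <- list(
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

#' Read a protein structure from PDB text or file
#'
#' Parses ATOM/HETATM records (via the `bio3d` PDB reader) into a light
#' structure model. Only the first MODEL of a multi-model file is used.
#' Alternate locations are collapsed to a single coordinate set per atom:
#' highest occupancy wins, ties broken towards altloc `"A"`.
#'
#' @param pdb Path to a PDB file, or a character scalar containing raw PDB
#'   text (recognised by embedded newlines).
#' @param chain Optional chain identifier; when given, only that chain's
#'   ATOM records are retained (hetero atoms are kept regardless).
#' @return An object of class `structure_model`: a list with `atoms` (data
#'   frame: `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`, and `residx`,
#'   the ordinal residue index within each chain) and `hetero` (data frame
#'   of HETATM coordinates with `resid` and `elety`; zinc ions have
#'   `resid == "ZN"`).
#' @export
read_structure <- function(pdb, chain = NULL) {
  path <- pdb
  if (length(pdb) == 1L && grepl("\n", pdb)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(strsplit(pdb, "\n")[[1]], path)
    on.exit(unlink(path))
  }
  p <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                verbose = FALSE),
                error = function(e) stop("cannot parse PDB input: ",
                                         conditionMessage(e)))
  at <- p$atom
  if (!any(at$type == "ATOM")) stop("no ATOM records in PDB input")
  atoms <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) {
    atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
    if (!nrow(atoms)) stop("no ATOM records for chain ", chain)
  }
  ## collapse altlocs: highest occupancy, then altloc 'A' (then first seen)
  alt <- atoms$alt; alt[is.na(alt)] <- ""
  occ <- atoms$o; occ[is.na(occ)] <- 1
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "|")
  ord <- order(key, -occ, alt != "A", alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$elety, sep = "|")), , drop = FALSE]
  atoms <- atoms[order(match(atoms$chain, unique(at$chain)), atoms$resno), ,
                 drop = FALSE]
  res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
  residx <- stats::ave(seq_along(res_key), atoms$chain,
                       FUN = function(i) match(res_key[i], unique(res_key[i])))
  out_atoms <- data.frame(
    chain = atoms$chain, resno = atoms$resno, resid = atoms$resid,
    elety = atoms$elety, x = atoms$x, y = atoms$y, z = atoms$z,
    residx = as.integer(residx), stringsAsFactors = FALSE)
  if (any(!is.finite(c(out_atoms$x, out_atoms$y, out_atoms$z))))
    stop("non-finite coordinates in PDB input")
  het <- at[at$type == "HETATM", , drop = FALSE]
  hetero <- data.frame(resid = het$resid, elety = het$elety,
                       x = het$x, y = het$y, z = het$z,
                       stringsAsFactors = FALSE)
  structure(list(atoms = out_atoms, hetero = hetero), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  nres <- length(unique(paste(x$atoms$chain, x$atoms$residx)))
  cat("structure_model: ", nres, " residue(s), ", nrow(x$atoms),
      " atoms, ", sum(toupper(x$hetero$resid) == "ZN"), " Zn\n", sep = "")
  invisible(x)
}

## element of a heavy atom from its PDB atom name (first letter)
atom_element <- function(elety) substr(gsub("^[0-9]+", "", elety), 1L, 1L)

coords <- function(df) cbind(df$x, df$y, df$z)

empty_interactions <- function() {
  data.frame(kind = character(0), chain_i = character(0), resno_i = integer(0),
             resid_i = character(0), atom_i = character(0),
             chain_j = character(0), resno_j = integer(0),
             resid_j = character(0), atom_j = character(0),
             distance = numeric(0), angle = numeric(0),
             seq_separation = integer(0), long_range = logical(0),
             stringsAsFactors = FALSE)
}

interaction_row <- function(kind, ai, aj, distance, angle = NA_real_,
                            sep = NA_integer_, long_range = NA) {
  data.frame(kind = kind,
             chain_i = ai$chain, resno_i = ai$resno, resid_i = ai$resid,
             atom_i = ai$elety,
             chain_j = aj$chain, resno_j = aj$resno, resid_j = aj$resid,
             atom_j = aj$elety,
             distance = distance, angle = angle,
             seq_separation = sep, long_range = long_range,
             stringsAsFactors = FALSE)
}

#' Detect zinc coordination spheres
#'
#' For every zinc ion in the model, reports candidate coordinating atoms
#' within `cutoff`: cysteine SG, histidine ND1/NE2, tyrosine OH, and any
#' backbone or side-chain N/O atom. Returns the interaction records together
#' with a per-zinc coordination summary string counting ligands by element,
#' e.g. `"S3N1"` for the three-sulfur/one-nitrogen sphere.
#'
#' @param model A [structure_model][read_structure].
#' @param cutoff Zn-ligand distance cutoff in Angstrom (default 2.8).
#' @return A list with `records` (interaction data frame; `kind`
#'   `"zn_ligand"`, the `j` columns describing the zinc) and `summary`
#'   (character vector, one string per zinc; `""` for an unligated zinc).
#'   With no zinc in the model both are empty (not an error).
#' @export
detect_zn_site <- function(model, cutoff = 2.8) {
  zn <- model$hetero[toupper(model$hetero$resid) == "ZN", , drop = FALSE]
  if (!nrow(zn)) return(list(records = empty_interactions(), summary = character(0)))
  at <- model$atoms
  elem <- atom_element(at$elety)
  cand <- elem %in% c("N", "O") | (at$resid == "CYS" & at$elety == "SG")
  at <- at[cand, , drop = FALSE]
  elem <- elem[cand]
  rows <- list(); summaries <- character(nrow(zn))
  for (zi in seq_len(nrow(zn))) {
    zpos <- c(zn$x[zi], zn$y[zi], zn$z[zi])
    d <- sqrt(colSums((t(coords(at)) - zpos)^2))
    lig <- which(d <= cutoff)
    counts <- table(factor(elem[lig], levels = c("S", "N", "O")))
    summaries[zi] <- paste0(
      ifelse(counts > 0, paste0(names(counts), counts), ""), collapse = "")
    zatom <- list(chain = "-", resno = NA_integer_, resid = "ZN", elety = "ZN")
    for (k in lig)
      rows[[length(rows) + 1L]] <-
        interaction_row("zn_ligand", at[k, ], zatom, d[k])
  }
  records <- if (length(rows)) do.call(rbind, rows) else empty_interactions()
  rownames(records) <- NULL
  list(records = records, summary = summaries)
}

#' Detect heavy-atom hydrogen bonds involving side chains
#'
#' Reports all N/O-N/O heavy-atom pairs from different residues of the same
#' chain, at distance at most `dmax`, in which at least one partner is a
#' side-chain atom. A pair is flagged long-range when the ordinal residue
#' separation |i - j| is at least `long_range_min_sep` (more than four
#' residues apart by default); ordinal indices within the chain are used, so
#' author numbering gaps and insertion codes cannot corrupt the separation.
#'
#' @param model A [structure_model][read_structure].
#' @param dmax Donor-acceptor heavy-atom distance cutoff in Angstrom
#'   (default 3.5).
#' @param long_range_min_sep Minimum |i - j| for the long-range flag
#'   (default 5).
#' @return An interaction data frame (`kind` `"hbond"`), one row per pair.
#' @export
detect_hbonds <- function(model, dmax = 3.5, long_range_min_sep = 5L) {
  at <- model$atoms
  elem <- atom_element(at$elety)
  no <- which(elem %in% c("N", "O"))
  rows <- list()
  if (length(no) >= 2L) {
    xyz <- coords(at)
    for (a in seq_along(no)) {
      i <- no[a]
      for (b in seq_along(no)) {
        if (b <= a) next
        j <- no[b]
        if (at$chain[i] != at$chain[j]) next
        if (at$residx[i] == at$residx[j]) next
        if (at$elety[i] %in% BACKBONE_ATOMS && at$elety[j] %in% BACKBONE_ATOMS)
          next
        d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
        if (d > dmax) next
        sep <- abs(at$residx[i] - at$residx[j])
        rows[[length(rows) + 1L]] <- interaction_row(
          "hbond", at[i, ], at[j, ], d, sep = sep,
          long_range = sep >= long_range_min_sep)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_interactions()
  rownames(out) <- NULL
  out
}

#' Detect the conserved Tyr-(i+4) backbone hydrogen bond
#'
#' For every tyrosine at ordinal position i whose phenolic oxygen (OH) lies
#' within `dmax` of the backbone nitrogen of residue i+4 in the same chain,
#' emits a record. This contact immobilises the tyrosine side chain in
#' zinc-free pZBDs, standing in for zinc ligation of the same oxygen.
#'
#' @param model A [structure_model][read_structure].
#' @param dmax Distance cutoff in Angstrom (default 3.5).
#' @return An interaction data frame (`kind` `"tyr_i4_hbond"`).
#' @export
detect_tyr_i4_hbond <- function(model, dmax = 3.5) {
  at <- model$atoms
  tyr_oh <- which(at$resid == "TYR" & at$elety == "OH")
  rows <- list()
  for (i in tyr_oh) {
    j <- which(at$chain == at$chain[i] &
               at$residx == at$residx[i] + 4L & at$elety == "N")
    if (!length(j)) next
    j <- j[1]
    d <- sqrt(sum((c(at$x[i], at$y[i], at$z[i]) -
                   c(at$x[j], at$y[j], at$z[j]))^2))
    if (d <= dmax)
      rows[[length(rows) + 1L]] <-
        interaction_row("tyr_i4_hbond", at[i, ], at[j, ], d, sep = 4L)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_interactions()
  rownames(out) <- NULL
  out
}

## centroid + unit normal of a planar-ish atom set (normal via SVD)
ring_geometry <- function(xyz) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  list(centroid = ctr, normal = sv$v[, 3])
}

#' Detect arginine-aromatic cation-pi interactions
#'
#' An interaction is reported for every Arg-aromatic (Tyr/Phe/Trp six-ring)
#' pair whose guanidinium centroid (CZ, NH1, NH2) lies within `dmax` of the
#' ring centroid and whose centroid-to-cation vector makes an angle of at
#' most `max_angle` with the ring normal (face-on geometry; edge-on
#' arrangements are rejected).
#'
#' @param model A [structure_model][read_structure].
#' @param dmax Centroid-centroid distance cutoff in Angstrom (default 6.0).
#' @param max_angle Maximum angle between ring normal and centroid-cation
#'   vector, degrees (default 45).
#' @return An interaction data frame (`kind` `"cation_pi"`; `atom_i`/
#'   `atom_j` are `"GUA"`/`"RING"` centroid descriptors; `angle` in
#'   degrees). Aromatic residues with missing ring atoms are skipped with a
#'   warning.
#' @export
detect_cation_pi <- function(model, dmax = 6.0, max_angle = 45) {
  at <- model$atoms
  res_key <- paste(at$chain, at$residx)
  args <- unique(res_key[at$resid == "ARG"])
  aroms <- unique(res_key[at$resid %in% names(RING_ATOMS)])
  rows <- list()
  for (rk in args) {
    sel <- res_key == rk & at$elety %in% c("CZ", "NH1", "NH2")
    if (sum(sel) < 3L) next
    gua <- colMeans(coords(at[sel, , drop = FALSE]))
    arg_row <- at[which(res_key == rk)[1], ]
    for (ak in aroms) {
      aresid <- at$resid[which(res_key == ak)[1]]
      ring_names <- RING_ATOMS[[aresid]]
      sel2 <- res_key == ak & at$elety %in% ring_names
      if (sum(sel2) < 6L) {
        warning("aromatic residue ", ak, " (", aresid,
                ") missing ring atoms; pair skipped")
        next
      }
      rg <- ring_geometry(coords(at[sel2, , drop = FALSE]))
      v <- gua - rg$centroid
      d <- sqrt(sum(v^2))
      if (d > dmax || d == 0) next
      cosang <- abs(sum(v * rg$normal)) / d
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang > max_angle) next
      arom_row <- at[which(res_key == ak)[1], ]
      ai <- list(chain = arg_row$chain, resno = arg_row$resno,
                 resid = "ARG", elety = "GUA")
      aj <- list(chain = arom_row$chain, resno = arom_row$resno,
                 resid = aresid, elety = "RING")
      sep <- abs(arg_row$residx - arom_row$residx)
      rows[[length(rows) + 1L]] <-
        interaction_row("cation_pi", ai, aj, d, angle = ang, sep = sep)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_interactions()
  rownames(out) <- NULL
  out
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' two matched coordinate sets, by singular value decomposition of the
#' cross-covariance matrix.
#'
#' @param a,b Numeric n-by-3 matrices of matched coordinates (n >= 3,
#'   non-collinear). `b` is rotated onto `a`.
#' @return A list with `rotation` (3x3, determinant +1), `translation`
#'   (length 3; the fit is `b %*% rotation + translation`), and `rmsd`.
#' @examples
#' a <- matrix(rnorm(30), ncol = 3)
#' superpose(a, a)$rmsd
#' @export
superpose <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (ncol(a) != 3L || ncol(b) != 3L || nrow(a) != nrow(b))
    stop("'a' and 'b' must be matched n-by-3 coordinate matrices")
  n <- nrow(a)
  if (n < 3L) stop("need at least 3 matched points")
  ca <- colMeans(a); cb <- colMeans(b)
  A0 <- sweep(a, 2, ca); B0 <- sweep(b, 2, cb)
  if (min(svd(B0)$d) < 1e-9 * max(svd(B0)$d, 1))
    stop("collinear (rank-deficient) coordinates: superposition is degenerate")
  H <- t(B0) %*% A0
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fit <- B0 %*% R
  rmsd <- sqrt(mean(rowSums((fit - A0)^2)))
  list(rotation = R, translation = as.numeric(ca - cb %*% R), rmsd = rmsd)
}

#' Run all geometric feature detectors on a structure
#'
#' Convenience wrapper combining [detect_zn_site()], [detect_hbonds()],
#' [detect_tyr_i4_hbond()] and [detect_cation_pi()] into one interaction
#' table.
#'
#' @param model A [structure_model][read_structure].
#' @param features Character vector naming detectors to run; any of
#'   `"zn"`, `"hbond"`, `"tyr_i4"`, `"cation_pi"`.
#' @param ... Threshold arguments forwarded to the detectors.
#' @return An interaction data frame (rows from all requested detectors).
#' @export
detect_features <- function(model,
                            features = c("zn", "hbond", "tyr_i4", "cation_pi"),
                            ...) {
  dots <- list(...)
  pick <- function(f, args) {
    args <- dots[intersect(names(dots), args)]
    do.call(f, c(list(model), args))
  }
  out <- list()
  if ("zn" %in% features)
    out$zn <- pick(detect_zn_site, "cutoff")$records
  if ("hbond" %in% features)
    out$hb <- pick(detect_hbonds, c("dmax", "long_range_min_sep"))
  if ("tyr_i4" %in% features)
    out$ty <- pick(detect_tyr_i4_hbond, "dmax")
  if ("cation_pi" %in% features)
    out$cp <- pick(detect_cation_pi, c("dmax", "max_angle"))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
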