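# Independent oracles used by the test suite.  These deliberately share no
# code with the package: naive enumeration, all-pairs loops, and numeric
# minimisation, kept slow and obvious.

## ---- motif scanning: naive start x gap-combination enumeration ----------

oracle_scan_one <- function(seq, pattern) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  k <- length(pattern$residue_sets)
  gap_grid <- if (k > 1L)
    expand.grid(lapply(seq_len(k - 1L), function(j)
      pattern$gap_min[j]:pattern$gap_max[j]), KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)
  rows <- list()
  for (s0 in seq_len(n) - 1L) {          # 0-based start
    for (gi in seq_len(max(1L, nrow(gap_grid)))) {
      gaps <- if (k > 1L) as.integer(gap_grid[gi, ]) else integer(0)
      pos <- s0 + cumsum(c(0L, gaps + 1L))
      if (pos[k] >= n) next
      ok <- TRUE
      for (j in seq_len(k)) {
        if (!(chars[pos[j] + 1L] %in% pattern$residue_sets[[j]])) {
          ok <- FALSE; break
        }
      }
      if (ok)
        rows[[length(rows) + 1L]] <- data.frame(
          pattern = pattern$name, start = s0, end = pos[k] + 1L,
          anchored_positions = paste(pos, collapse = ","),
          gaps = paste(gaps, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

oracle_scan <- function(seq, patterns) {
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  out <- do.call(rbind, lapply(patterns, function(p) oracle_scan_one(seq, p)))
  if (is.null(out))
    return(data.frame(pattern = character(0), start = integer(0),
                      end = integer(0), anchored_positions = character(0),
                      gaps = character(0), stringsAsFactors = FALSE))
  out
}

## canonical key set for order-insensitive hit comparison
hit_keys <- function(hits)
  sort(paste(hits$pattern, hits$start, hits$end, hits$anchored_positions,
             hits$gaps, sep = "|"))

## ---- geometry: all-pairs loop detectors ---------------------------------

.backbone <- c("N", "CA", "C", "O", "OXT")
.elem <- function(name) substr(gsub("^[0-9]+", "", name), 1, 1)
.dist <- function(p, q) sqrt(sum((p - q)^2))
.xyz <- function(at, i) c(at$x[i], at$y[i], at$z[i])

oracle_hbonds <- function(model, dmax = 3.5, min_sep = 5L) {
  at <- model$atoms
  found <- list()
  for (i in seq_len(nrow(at))) {
    for (j in seq_len(nrow(at))) {
      if (j <= i) next
      if (!(.elem(at$elety[i]) %in% c("N", "O"))) next
      if (!(.elem(at$elety[j]) %in% c("N", "O"))) next
      if (at$chain[i] != at$chain[j]) next
      if (at$residx[i] == at$residx[j]) next
      if (at$elety[i] %in% .backbone && at$elety[j] %in% .backbone) next
      d <- .dist(.xyz(at, i), .xyz(at, j))
      if (d > dmax) next
      found[[length(found) + 1L]] <- c(
        i = at$residx[i], j = at$residx[j],
        d = d, lr = as.numeric(abs(at$residx[i] - at$residx[j]) >= min_sep))
    }
  }
  if (!length(found))
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("i", "j", "d", "lr"))))
  do.call(rbind, found)
}

oracle_tyr_i4 <- function(model, dmax = 3.5) {
  at <- model$atoms
  found <- list()
  for (i in seq_len(nrow(at))) {
    if (at$resid[i] != "TYR" || at$elety[i] != "OH") next
    for (j in seq_len(nrow(at))) {
      if (at$elety[j] != "N" || at$chain[j] != at$chain[i]) next
      if (at$residx[j] != at$residx[i] + 4L) next
      d <- .dist(.xyz(at, i), .xyz(at, j))
      if (d <= dmax) found[[length(found) + 1L]] <- c(at$residx[i], d)
    }
  }
  if (!length(found))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("i", "d"))))
  do.call(rbind, found)
}

oracle_zn <- function(model, cutoff = 2.8) {
  zn <- model$hetero[toupper(model$hetero$resid) == "ZN", , drop = FALSE]
  at <- model$atoms
  out <- list()
  for (zi in seq_len(nrow(zn))) {
    zpos <- c(zn$x[zi], zn$y[zi], zn$z[zi])
    ligs <- character(0)
    for (i in seq_len(nrow(at))) {
      el <- .elem(at$elety[i])
      cand <- el %in% c("N", "O") ||
        (at$resid[i] == "CYS" && at$elety[i] == "SG")
      if (!cand) next
      if (.dist(.xyz(at, i), zpos) <= cutoff) ligs <- c(ligs, el)
    }
    out[[zi]] <- ligs
  }
  out
}

oracle_cation_pi <- function(model, dmax = 6.0, max_angle = 45) {
  at <- model$atoms
  rings <- list(TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
  key <- paste(at$chain, at$residx)
  found <- list()
  for (rk in unique(key[at$resid == "ARG"])) {
    sel <- key == rk & at$elety %in% c("CZ", "NH1", "NH2")
    if (sum(sel) < 3) next
    gua <- colMeans(cbind(at$x[sel], at$y[sel], at$z[sel]))
    for (ak in unique(key[at$resid %in% names(rings)])) {
      rr <- at$resid[key == ak][1]
      sel2 <- key == ak & at$elety %in% rings[[rr]]
      if (sum(sel2) < 6) next
      xyz <- cbind(at$x[sel2], at$y[sel2], at$z[sel2])
      ctr <- colMeans(xyz)
      ## ring normal: cross product of two in-plane vectors
      v1 <- xyz[2, ] - xyz[1, ]; v2 <- xyz[4, ] - xyz[1, ]
      nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
               v1[3] * v2[1] - v1[1] * v2[3],
               v1[1] * v2[2] - v1[2] * v2[1])
      nrm <- nrm / sqrt(sum(nrm^2))
      v <- gua - ctr
      d <- sqrt(sum(v^2))
      if (d > dmax || d == 0) next
      ang <- acos(min(1, abs(sum(v * nrm)) / d)) * 180 / pi
      if (ang <= max_angle)
        found[[length(found) + 1L]] <- c(d = d, ang = ang)
    }
  }
  if (!length(found))
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("d", "ang"))))
  do.call(rbind, found)
}

## numeric-minimisation superposition oracle: optimise Euler angles +
## translation for minimum RMSD
oracle_superpose_rmsd <- function(a, b) {
  rotmat <- function(th) {
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0),
                c(sin(th[1]),  cos(th[1]), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
                c(-sin(th[2]), 0, cos(th[2])))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[3]), -sin(th[3])),
                c(0, sin(th[3]), cos(th[3])))
    Rz %*% Ry %*% Rx
  }
  obj <- function(par)
    sqrt(mean(rowSums((b %*% rotmat(par[1:3]) +
                       matrix(par[4:6], nrow(b), 3, byrow = TRUE) - a)^2)))
  best <- Inf
  for (st in list(rep(0, 6), c(0.5, -0.3, 0.8, 0, 0, 0),
                  c(2, 1, -1, 0, 0, 0), c(-1.5, 2.5, 0.4, 0, 0, 0))) {
    o <- stats::optim(st, obj, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

## exhaustive two-sided hypergeometric p for a 2x2 table
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## random proper rotation + translation
random_rigid <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = runif(3, -20, 20))
}

## apply a rigid transform to every coordinate of a structure model
transform_model <- function(model, rigid) {
  tr <- function(df) {
    if (!nrow(df)) return(df)
    xyz <- cbind(df$x, df$y, df$z) %*% rigid$R
    df$x <- xyz[, 1] + rigid$t[1]
    df$y <- xyz[, 2] + rigid$t[2]
    df$z <- xyz[, 3] + rigid$t[3]
    df
  }
  model$atoms <- tr(model$atoms)
  model$hetero <- tr(model$hetero)
  model
}

## all strings of a given length over an alphabet
all_strings <- function(len, alphabet) {
  if (len == 0L) return(character(0))
  g <- do.call(expand.grid, c(rep(list(alphabet), len),
                              stringsAsFactors = FALSE))
  do.call(paste0, g)
}

random_string <- function(len, alphabet)
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
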