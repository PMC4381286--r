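# Synthetic-data generators.  Every input class the pipeline consumes can
# be generated with known ground truth, so each stage has a round-trip test
# without any external download.  All generators are deterministic given
# their seed (a single RNG stream per call, restored on exit).

## sample a single element from a vector (safe for length-1 vectors)
sample_one <- function(v) v[sample.int(length(v), 1L)]

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(code)
}

## background alphabet that can neither create nor extend a ZB-motif
## (excludes the anchored letters C, H, Y of every shipped catalog)
SAFE_ALPHABET <- setdiff(AA_STANDARD, c("C", "H", "Y"))

rand_residues <- function(n, alphabet = SAFE_ALPHABET)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

## realize a pattern instance with uniformly sampled gap lengths
realize_motif <- function(pattern) {
  k <- length(pattern$residue_sets)
  gaps <- if (k > 1L)
    vapply(seq_len(k - 1L), function(j)
      sample_one(pattern$gap_min[j]:pattern$gap_max[j]), integer(1))
  else integer(0)
  anchors <- vapply(pattern$residue_sets, function(set)
    sample_one(set), character(1))
  pieces <- character(0)
  for (j in seq_len(k)) {
    pieces <- c(pieces, anchors[j])
    if (j < k) pieces <- c(pieces, rand_residues(gaps[j]))
  }
  list(seq = paste(pieces, collapse = ""), gaps = gaps)
}

## default per-group pZBD length ranges (residues)
DEFAULT_LENGTH_RANGES <- list(I = c(46L, 54L), II = c(46L, 54L),
                              III = c(46L, 54L), IV = c(31L, 36L),
                              V = c(10L, 17L))

## E3 / E4 anchor strand blocks (fixed; drawn from the safe alphabet)
E3_BLOCK <- "VEIKV"
E4_BLOCK <- "LTLEG"

#' Generate a synthetic GluRS cohort with planted pZBD composition
#'
#' Builds one sequence per cohort member: a random N-terminal flank, the E3
#' anchor strand, a pZBD of group-appropriate length, the E4 anchor strand
#' and a C-terminal flank. Groups I/II carry a planted instance of the
#' taxon's canonical/modified motif inside the pZBD; groups III/IV/V are
#' guaranteed motif-free by rejection sampling against the scanner. The
#' records are also returned as a gapped alignment (pZBDs right-padded to
#' the maximum length) with the matching [anchor_spec()], plus a truth
#' table.
#'
#' @param n_per_group Named integer vector, e.g. `c(I = 88, II = 5,
#'   III = 105, IV = 7, V = 7)`; groups with zero members may be omitted.
#' @param taxon Catalog selector for [zb_catalog()] (default bacterial
#'   GluRS).
#' @param length_ranges Named list of `c(min, max)` pZBD lengths per group;
#'   defaults to 46-54 for I/II/III, 31-36 for IV, 10-17 for V (the
#'   observed ranges).
#' @param flank Length of each terminal flank (default 20).
#' @param seed RNG seed (required; the generator is deterministic given it).
#' @return A list with `sequences` (named character vector, ungapped),
#'   `alignment` (named character vector, equal widths), `anchors`
#'   ([anchor_spec()]), and `truth` (data frame: `seq_id`, `group`,
#'   `length`, `motif_label`, `motif_start`, `motif_end` in ungapped
#'   0-based coordinates, `NA` for motif-free).
#' @examples
#' cohort <- gen_sequence_cohort(c(I = 3, V = 2), seed = 7)
#' cohort$truth
#' @export
gen_sequence_cohort <- function(n_per_group, taxon = "bacteria-GluRS",
                                length_ranges = DEFAULT_LENGTH_RANGES,
                                flank = 20L, seed) {
  catalog <- if (is.character(taxon)) zb_catalog(taxon) else taxon
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("'n_per_group' must be named by group (I, II, III, IV, V)")
  bad <- setdiff(names(n_per_group), c("I", "II", "III", "IV", "V"))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  if (any(n_per_group < 0)) stop("negative group counts")
  if (("II" %in% names(n_per_group)) && n_per_group[["II"]] > 0 &&
      length(catalog) < 2L)
    stop("taxon catalog has no group-II pattern")
  ranges <- utils::modifyList(DEFAULT_LENGTH_RANGES, as.list(length_ranges))

  with_seed(seed, {
    rows <- list(); seqs <- character(0); pzbds <- character(0)
    idx <- 0L
    for (grp in names(n_per_group)) {
      ng <- n_per_group[[grp]]
      if (ng == 0) next
      rng <- ranges[[grp]]
      pat <- switch(grp, I = catalog[[1]], II = catalog[[2]], NULL)
      if (!is.null(pat) && pattern_min_span(pat) > rng[2])
        stop("impossible spec: motif ", pat$name, " (minimum span ",
             pattern_min_span(pat), ") cannot fit group ", grp,
             " length range ", rng[1], "-", rng[2])
      for (m in seq_len(ng)) {
        idx <- idx + 1L
        id <- sprintf("%s_%s_%03d", gsub("[^A-Za-z0-9]", "", taxon_label(taxon)),
                      grp, idx)
        if (!is.null(pat)) {
          repeat {
            lo <- max(rng[1], pattern_min_span(pat))
            L <- sample_one(lo:rng[2])
            mot <- realize_motif(pat)
            pad <- L - nchar(mot$seq)
            left <- sample_one(0:pad)
            pz <- paste0(rand_residues(left), mot$seq, rand_residues(pad - left))
            ## the planted instance must be the classifying hit
            hits <- scan_sequence(pz, catalog)
            if (classify_motif(hits, catalog) == pat$name) break
          }
          mstart <- left
          mend <- left + nchar(mot$seq)
          label <- pat$name
        } else {
          rng_lo <- rng[1]
          repeat {
            L <- sample_one(rng_lo:rng[2])
            pz <- rand_residues(L, AA_STANDARD)
            if (!nrow(scan_sequence(pz, catalog))) break
          }
          mstart <- NA_integer_; mend <- NA_integer_; label <- "none"
        }
        pzbds <- c(pzbds, stats::setNames(pz, id))
        full <- paste0(rand_residues(flank), E3_BLOCK, pz, E4_BLOCK,
                       rand_residues(flank))
        seqs <- c(seqs, stats::setNames(full, id))
        off <- flank + nchar(E3_BLOCK)
        rows[[idx]] <- data.frame(
          seq_id = id, group = grp, length = nchar(pz), motif_label = label,
          motif_start = if (is.na(mstart)) NA_integer_ else off + mstart,
          motif_end = if (is.na(mend)) NA_integer_ else off + mend,
          stringsAsFactors = FALSE)
      }
    }
    if (!idx) stop("empty cohort specification")
    truth <- do.call(rbind, rows)
    lmax <- max(nchar(pzbds))
    aln <- vapply(seq_along(pzbds), function(i) {
      pz <- pzbds[[i]]
      paste0(substr(seqs[[i]], 1, flank), E3_BLOCK,
             pz, strrep("-", lmax - nchar(pz)), E4_BLOCK,
             substr(seqs[[i]], nchar(seqs[[i]]) - flank + 1L, nchar(seqs[[i]])))
    }, character(1))
    names(aln) <- names(seqs)
    anchors <- anchor_spec(e3_col = flank + nchar(E3_BLOCK) - 1L,
                           e4_col = flank + nchar(E3_BLOCK) + lmax)
    list(sequences = seqs, alignment = aln, anchors = anchors, truth = truth)
  })
}

taxon_label <- function(taxon)
  if (is.character(taxon)) taxon else "custom"

#' Plant non-overlapping motif instances in a clean background
#'
#' Embeds `k` instances of a pattern, separated and flanked by residues from
#' an alphabet that cannot contribute to the motif, so a scan of the result
#' yields exactly `k` hits at the planted coordinates.
#'
#' @param pattern A [motif_pattern][parse_pattern].
#' @param k Number of instances.
#' @param spacer Number of background residues before, between and after
#'   instances (default 12).
#' @param seed RNG seed.
#' @return A list with `seq` and `truth` (data frame of 0-based
#'   `start`/`end` and realized `gaps` per instance).
#' @export
gen_planted_sequence <- function(pattern, k, spacer = 12L, seed) {
  if (k < 1L) stop("'k' must be at least 1")
  with_seed(seed, {
    pieces <- rand_residues(spacer)
    rows <- list()
    pos <- spacer
    for (i in seq_len(k)) {
      mot <- realize_motif(pattern)
      rows[[i]] <- data.frame(start = pos, end = pos + nchar(mot$seq),
                              gaps = paste(mot$gaps, collapse = ","),
                              stringsAsFactors = FALSE)
      pieces <- c(pieces, mot$seq, rand_residues(spacer))
      pos <- pos + nchar(mot$seq) + spacer
    }
    list(seq = paste(pieces, collapse = ""), truth = do.call(rbind, rows))
  })
}

## ---- toy structures ----------------------------------------------------

## straight poly-alanine backbone: CA along x at 3.8 A spacing
backbone_atoms <- function(n, resid = rep("ALA", n)) {
  rows <- list()
  for (k in seq_len(n)) {
    cax <- (k - 1) * 3.8
    rows[[k]] <- data.frame(
      resno = k, resid = resid[k],
      elety = c("N", "CA", "C", "O"),
      x = c(cax - 1.2, cax, cax + 1.2, cax + 1.4),
      y = c(0.8, 0, 0.8, 2.0),
      z = 0, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

format_pdb_atom <- function(serial, elety, resid, chain, resno, x, y, z,
                            record = "ATOM") {
  name_fmt <- if (nchar(elety) < 4L) sprintf(" %-3s", elety) else elety
  sprintf("%-6s%5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_fmt, resid, chain, resno, x, y, z, 1, 0,
          substr(gsub("^[0-9]+", "", elety), 1, 2))
}

atoms_to_pdb <- function(atoms, hetero = NULL, chain = "A") {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(nrow(atoms))) {
    serial <- serial + 1L
    lines <- c(lines, format_pdb_atom(serial, atoms$elety[i], atoms$resid[i],
                                      chain, atoms$resno[i],
                                      atoms$x[i], atoms$y[i], atoms$z[i]))
  }
  if (!is.null(hetero) && nrow(hetero)) {
    for (i in seq_len(nrow(hetero))) {
      serial <- serial + 1L
      lines <- c(lines, format_pdb_atom(serial, hetero$elety[i],
                                        hetero$resid[i], chain,
                                        9000L + i, hetero$x[i], hetero$y[i],
                                        hetero$z[i], record = "HETATM"))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

## unit vectors of a regular tetrahedron
TETRAHEDRON <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)

#' Generate a toy structure with a planted geometric feature
#'
#' Emits PDB text for a short poly-alanine chain carrying one feature at an
#' exact target geometry, together with the ground truth: a zinc ion with a
#' chosen ligand set at chosen distances (`"zn_site"`), a side-chain to
#' side-chain hydrogen bond (`"hbond"`), a Tyr OH to (i+4) backbone N
#' contact (`"tyr_i4"`), or an Arg-Tyr cation-pi pair at a given centroid
#' distance and normal angle (`"cation_pi"`).
#'
#' @param feature One of `"zn_site"`, `"hbond"`, `"tyr_i4"`, `"cation_pi"`.
#' @param distance Target distance in Angstrom (Zn-ligand distance, H-bond
#'   donor-acceptor distance, OH-N distance, or centroid-centroid distance
#'   respectively).
#' @param angle For `"cation_pi"`: angle between ring normal and
#'   centroid-cation vector, degrees (default 10).
#' @param ligands For `"zn_site"`: character vector of ligand descriptors
#'   among `"SG"` (Cys), `"ND1"`/`"NE2"` (His), `"OH"` (Tyr); default three
#'   SG and one ND1 (the S3N1 sphere). At most four ligands.
#' @param sep For `"hbond"`: ordinal residue separation between the two
#'   partners (default 10).
#' @param chain_length Number of backbone residues (default 24).
#' @param seed RNG seed (used only for reproducible metadata; atom placement
#'   is exact).
#' @return A list with `pdb` (text) and `truth` (list describing the
#'   planted feature).
#' @examples
#' toy <- gen_structure("cation_pi", distance = 4.2, angle = 10, seed = 1)
#' detect_cation_pi(read_structure(toy$pdb))
#' @export
gen_structure <- function(feature = c("zn_site", "hbond", "tyr_i4", "cation_pi"),
                          distance = NULL, angle = 10,
                          ligands = c("SG", "SG", "SG", "ND1"),
                          sep = 10L, chain_length = 24L, seed = 1) {
  feature <- match.arg(feature)
  if (chain_length < 12L) stop("chain_length must be at least 12")
  resid <- rep("ALA", chain_length)
  side <- NULL
  hetero <- NULL
  truth <- list(feature = feature)

  if (feature == "zn_site") {
    if (is.null(distance)) distance <- 2.3
    if (distance <= 0) stop("geometrically impossible spec: distance <= 0")
    if (length(ligands) > 4L) stop("at most four zinc ligands")
    lig_res <- c(SG = "CYS", ND1 = "HIS", NE2 = "HIS", OH = "TYR")
    if (any(!ligands %in% names(lig_res)))
      stop("unknown ligand descriptor(s): ",
           paste(setdiff(ligands, names(lig_res)), collapse = ", "))
    zn <- c(mean(c(0, (chain_length - 1) * 3.8)) , 15, 0)
    host <- seq(3L, by = 3L, length.out = length(ligands))
    resid[host] <- lig_res[ligands]
    side <- do.call(rbind, lapply(seq_along(ligands), function(i) {
      pos <- zn + distance * TETRAHEDRON[i, ]
      data.frame(resno = host[i], resid = lig_res[[ligands[i]]],
                 elety = ligands[i], x = pos[1], y = pos[2], z = pos[3],
                 stringsAsFactors = FALSE)
    }))
    hetero <- data.frame(resid = "ZN", elety = "ZN",
                         x = zn[1], y = zn[2], z = zn[3],
                         stringsAsFactors = FALSE)
    elems <- substr(ligands, 1, 1)
    counts <- table(factor(elems, levels = c("S", "N", "O")))
    truth$summary <- paste0(
      ifelse(counts > 0, paste0(names(counts), counts), ""), collapse = "")
    truth$distance <- distance
  } else if (feature == "hbond") {
    if (is.null(distance)) distance <- 2.9
    if (distance <= 0) stop("geometrically impossible spec: distance <= 0")
    i <- 5L; j <- i + as.integer(sep)
    if (j > chain_length) stop("separation exceeds chain length")
    resid[i] <- "SER"; resid[j] <- "ASN"
    p1 <- c((i - 1) * 3.8, 9, 0)
    p2 <- p1 + c(distance, 0, 0)
    side <- data.frame(resno = c(i, j), resid = c("SER", "ASN"),
                       elety = c("OG", "OD1"),
                       x = c(p1[1], p2[1]), y = c(p1[2], p2[2]),
                       z = c(p1[3], p2[3]), stringsAsFactors = FALSE)
    truth$distance <- distance
    truth$residues <- c(i, j)
    truth$seq_separation <- as.integer(sep)
  } else if (feature == "tyr_i4") {
    if (is.null(distance)) distance <- 2.9
    if (distance <= 0) stop("geometrically impossible spec: distance <= 0")
    i <- 6L
    if (i + 4L > chain_length) stop("chain too short for an (i+4) contact")
    resid[i] <- "TYR"
    ## backbone N of residue i+4 sits at ((i+4-1)*3.8 - 1.2, 0.8, 0)
    npos <- c((i + 3) * 3.8 - 1.2, 0.8, 0)
    oh <- npos + c(0, distance, 0)
    side <- data.frame(resno = i, resid = "TYR", elety = "OH",
                       x = oh[1], y = oh[2], z = oh[3],
                       stringsAsFactors = FALSE)
    truth$distance <- distance
    truth$residues <- c(i, i + 4L)
  } else if (feature == "cation_pi") {
    if (is.null(distance)) distance <- 4.2
    if (distance <= 0) stop("geometrically impossible spec: distance <= 0")
    if (angle < 0 || angle > 90) stop("angle must be in [0, 90] degrees")
    i <- 6L; j <- 16L
    resid[i] <- "TYR"; resid[j] <- "ARG"
    ctr <- c((i - 1) * 3.8, 8, 0)
    ## ring in the z = 0 plane (normal along z), radius 1.39 A
    th <- seq(0, 2 * pi, length.out = 7)[-7]
    ring <- data.frame(
      resno = i, resid = "TYR",
      elety = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
      x = ctr[1] + 1.39 * cos(th), y = ctr[2] + 1.39 * sin(th),
      z = ctr[3], stringsAsFactors = FALSE)
    arad <- angle * pi / 180
    gua_ctr <- ctr + distance * c(sin(arad), 0, cos(arad))
    ## three atoms whose centroid is exactly gua_ctr
    tri <- rbind(c(0, 0.75, 0), c(0.65, -0.375, 0), c(-0.65, -0.375, 0))
    gua <- data.frame(
      resno = j, resid = "ARG", elety = c("CZ", "NH1", "NH2"),
      x = gua_ctr[1] + tri[, 1], y = gua_ctr[2] + tri[, 2],
      z = gua_ctr[3] + tri[, 3], stringsAsFactors = FALSE)
    side <- rbind(ring, gua)
    truth$distance <- distance
    truth$angle <- angle
    truth$residues <- c(i, j)
  }

  atoms <- backbone_atoms(chain_length, resid)
  if (!is.null(side)) atoms <- rbind(atoms, side)
  atoms <- atoms[order(atoms$resno, match(atoms$elety,
                                          c("N", "CA", "C", "O"),
                                          nomatch = 99L)), , drop = FALSE]
  ## PDB text carries three decimals; quantize first and record the
  ## realized geometry as truth so round-trips are exact
  for (col in c("x", "y", "z")) {
    atoms[[col]] <- round(atoms[[col]], 3)
    if (!is.null(hetero)) hetero[[col]] <- round(hetero[[col]], 3)
  }
  pt <- function(df, sel) unlist(df[sel, c("x", "y", "z")], use.names = FALSE)
  if (feature == "zn_site") {
    znp <- pt(hetero, 1L)
    truth$distances <- vapply(seq_along(ligands), function(i) {
      sel <- atoms$resno == host[i] & atoms$elety == ligands[i]
      sqrt(sum((pt(atoms, sel) - znp)^2))
    }, numeric(1))
    truth$distance <- mean(truth$distances)
  } else if (feature == "hbond") {
    truth$distance <- sqrt(sum((pt(atoms, atoms$elety == "OG") -
                                pt(atoms, atoms$elety == "OD1"))^2))
  } else if (feature == "tyr_i4") {
    truth$distance <- sqrt(sum(
      (pt(atoms, atoms$elety == "OH") -
       pt(atoms, atoms$resno == truth$residues[2] & atoms$elety == "N"))^2))
  } else if (feature == "cation_pi") {
    ring_sel <- atoms$resid == "TYR" &
      atoms$elety %in% RING_ATOMS$TYR
    rg <- ring_geometry(coords(atoms[ring_sel, , drop = FALSE]))
    gua_sel <- atoms$resid == "ARG" & atoms$elety %in% c("CZ", "NH1", "NH2")
    gc <- colMeans(coords(atoms[gua_sel, , drop = FALSE]))
    v <- gc - rg$centroid
    truth$distance <- sqrt(sum(v^2))
    truth$angle <- acos(min(1, abs(sum(v * rg$normal)) / truth$distance)) * 180 / pi
  }
  truth$seed <- seed
  list(pdb = atoms_to_pdb(atoms, hetero), truth = truth)
}

## ---- genome tables -----------------------------------------------------

#' Generate a synthetic genome context table
#'
#' Samples `pzbd_deleted ~ Bernoulli(p_deleted)` per genome and the direct
#' glutaminylation route (GlnRS presence) from a 2x2 model with a requested
#' odds ratio between deletion and route presence: the route probability in
#' non-deleted genomes is `p_direct_base`, and in deleted genomes the odds
#' are multiplied by `odds_ratio`. gatCAB and 1/72 signature fields are
#' filled consistently with the pathway model: deleted genomes with no
#' direct route have their indirect route disabled (no gatCAB), all other
#' genomes carry gatCAB and the required signature with high probability.
#'
#' @param n Number of genomes.
#' @param p_deleted Probability of pZBD deletion (default 0.1).
#' @param odds_ratio Association strength (1 = independence).
#' @param p_direct_base Probability of a direct route in non-deleted
#'   genomes (default 0.5).
#' @param seed RNG seed.
#' @return A list with `table` (genome context data frame, see
#'   [read_genome_table()]) and `truth` (the generating parameters and
#'   per-cell probabilities).
#' @export
gen_genome_table <- function(n, p_deleted = 0.1, odds_ratio = 1,
                             p_direct_base = 0.5, seed) {
  if (p_deleted < 0 || p_deleted > 1 || p_direct_base <= 0 || p_direct_base >= 1)
    stop("invalid probabilities")
  if (odds_ratio <= 0) stop("'odds_ratio' must be positive")
  with_seed(seed, {
    deleted <- stats::runif(n) < p_deleted
    odds0 <- p_direct_base / (1 - p_direct_base)
    p1 <- odds_ratio * odds0 / (1 + odds_ratio * odds0)
    p_direct <- ifelse(deleted, p1, p_direct_base)
    direct <- stats::runif(n) < p_direct
    use_glurs2 <- direct & (stats::runif(n) < 0.2)
    has_glnrs <- direct & !use_glurs2
    has_glurs2 <- use_glurs2
    ## keep verdicts consistent: problem cell (deleted, no direct route)
    ## gets its indirect route disabled
    has_gatcab <- ifelse(deleted & !direct, FALSE, stats::runif(n) < 0.9)
    sig <- ifelse(has_gatcab, "UA",
                  sample(c("GC", "CG", "AU"), n, replace = TRUE))
    tab <- data.frame(
      genome_id = sprintf("g%04d", seq_len(n)),
      has_glnrs = has_glnrs, has_glurs2 = has_glurs2,
      has_gatcab = as.logical(has_gatcab), trna_gln_1_72 = sig,
      pzbd_deleted = deleted, stringsAsFactors = FALSE)
    list(table = tab,
         truth = list(n = n, p_deleted = p_deleted, odds_ratio = odds_ratio,
                      p_direct_deleted = p1, p_direct_base = p_direct_base,
                      seed = seed))
  })
}

## ---- titration / kinetics / zinc assays --------------------------------

#' Simulate a fluorescence titration with known binding parameters
#'
#' Forward-simulates the exact depletion-aware 1:1 model
#' (`signal = baseline + amplitude * bound_fraction`) and applies
#' multiplicative Gaussian noise. Defaults reproduce the wild-type GluRS /
#' tRNA-Glu titration conditions: Kd 62.5 nM at 0.5 uM enzyme.
#'
#' @param kd Dissociation constant, molar (default 62.5e-9).
#' @param enzyme_conc Enzyme concentration, molar (default 0.5e-6).
#' @param ligand_concs Titration points, molar. The default is a 38-point
#'   design: 25 nM steps through the depletion transition around the
#'   enzyme concentration (25-750 nM), then eight sparser points out to
#'   3 uM for the plateau — the region below and around the equivalence
#'   point is what identifies Kd when the enzyme is well above it.
#' @param baseline,amplitude Signal model parameters (defaults 1 and -0.6:
#'   fluorescence quenched on binding).
#' @param noise Multiplicative noise standard deviation (e.g. 0.01 for 1%).
#' @param seed RNG seed.
#' @return A list with `series` (data frame `ligand_conc`, `signal`) and
#'   `truth` (the generating parameters).
#' @export
gen_titration <- function(kd = 62.5e-9, enzyme_conc = 0.5e-6,
                          ligand_concs = c(seq(0.025, 0.75, by = 0.025),
                                           0.8, 0.9, 1, 1.2, 1.5, 2, 2.5,
                                           3) * 1e-6,
                          baseline = 1, amplitude = -0.6,
                          noise = 0, seed = 1) {
  if (noise < 0) stop("'noise' must be non-negative")
  with_seed(seed, {
    f <- bound_fraction(ligand_concs, enzyme_conc, kd)
    y <- baseline + amplitude * f
    if (noise > 0) y <- y * (1 + stats::rnorm(length(y), sd = noise))
    list(series = data.frame(ligand_conc = ligand_concs, signal = y),
         truth = list(kd = kd, enzyme_conc = enzyme_conc,
                      baseline = baseline, amplitude = amplitude,
                      noise = noise, seed = seed))
  })
}

#' Simulate a Michaelis-Menten rate series with known parameters
#'
#' Forward-simulates `v = kcat * E * S / (Km + S)` with multiplicative
#' Gaussian noise. Defaults reproduce the wild-type glutamylation kinetics:
#' kcat 5.3 per second, Km 65.4 uM, substrate 50-300 uM.
#'
#' @param kcat Turnover number, per second (default 5.3).
#' @param km Michaelis constant, molar (default 65.4e-6).
#' @param enzyme_conc Enzyme concentration, molar (default 50e-9).
#' @param substrate_concs Substrate points, molar (default eight points
#'   spanning 50-300 uM).
#' @param noise Multiplicative noise standard deviation.
#' @param seed RNG seed.
#' @return A list with `series` (data frame `substrate_conc`, `rate`) and
#'   `truth`.
#' @export
gen_mm <- function(kcat = 5.3, km = 65.4e-6, enzyme_conc = 50e-9,
                   substrate_concs = seq(50e-6, 300e-6, length.out = 8),
                   noise = 0, seed = 1) {
  if (noise < 0) stop("'noise' must be non-negative")
  with_seed(seed, {
    v <- kcat * enzyme_conc * substrate_concs / (km + substrate_concs)
    if (noise > 0) v <- v * (1 + stats::rnorm(length(v), sd = noise))
    list(series = data.frame(substrate_conc = substrate_concs, rate = v),
         truth = list(kcat = kcat, km = km, enzyme_conc = enzyme_conc,
                      noise = noise, seed = seed))
  })
}

#' Simulate a PAR/MMTS zinc assay with known stoichiometry
#'
#' Builds a linear standard curve (absorbance at 500 nm against zinc
#' concentration) and a sample whose background-subtracted plateau
#' absorbance corresponds to `ratio` zinc ions per protein.
#'
#' @param ratio True zinc:protein molar ratio (default 0.93).
#' @param protein_conc Protein concentration, molar (default 10e-6).
#' @param slope Calibration slope, absorbance per molar (default 5e4).
#' @param intercept Calibration intercept (default 0).
#' @param standards_zn Standard zinc concentrations, molar (default 0 to
#'   15 uM in six steps).
#' @param noise Multiplicative noise on standard absorbances.
#' @param seed RNG seed.
#' @return A list with `standards` (data frame `zn_conc`, `a500`),
#'   `sample_a500_background`, `sample_a500_plateau`, `protein_conc`, and
#'   `truth`.
#' @export
gen_zinc <- function(ratio = 0.93, protein_conc = 10e-6, slope = 5e4,
                     intercept = 0, standards_zn = seq(0, 15e-6, length.out = 6),
                     noise = 0, seed = 1) {
  if (noise < 0) stop("'noise' must be non-negative")
  if (ratio < 0) stop("'ratio' must be non-negative")
  with_seed(seed, {
    a <- intercept + slope * standards_zn
    if (noise > 0) a <- a * (1 + stats::rnorm(length(a), sd = noise))
    bg <- 0.02
    plateau <- bg + intercept + slope * ratio * protein_conc
    list(standards = data.frame(zn_conc = standards_zn, a500 = a),
         sample_a500_background = bg, sample_a500_plateau = plateau,
         protein_conc = protein_conc,
         truth = list(ratio = ratio, slope = slope, intercept = intercept,
                      noise = noise, seed = seed))
  })
}
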