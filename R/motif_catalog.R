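# ZB-motif notation: anchored residue letters separated by bounded wildcard
# gaps, e.g. "CxCx20-21Yx3C".  "x" alone is a gap of exactly one residue,
# "x20" exactly twenty, "x20-21" any count in [20, 21].

AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Parse zinc-binding-motif notation into an executable pattern
#'
#' Turns the compact gapped-motif notation used for zinc-binding (ZB) motifs,
#' such as `"CxCx20-21Yx3C"`, into a structured pattern that
#' [scan_sequence()] can match. Anchored residues are uppercase amino-acid
#' letters (a set of alternatives may be written in brackets, e.g. `"[CH]"`);
#' gaps are written `x` (exactly one arbitrary residue), `xN` (exactly `N`)
#' or `xA-B` (any count between `A` and `B`). Underscores and en-dashes in
#' the notation are tolerated, so `"CxCx_20-21_Yx_3_C"` parses identically.
#'
#' @param notation Motif string.
#' @param name Short label for the pattern (e.g. `"bact-I"`).
#' @param taxon Catalog the pattern belongs to; one of
#'   `"bacteria-GluRS"`, `"bacteria-GluQRS"`, `"archaea-GluRS"`,
#'   `"eukarya-GluRS"` (free text is allowed for user catalogs).
#' @return An object of class `motif_pattern`: a list with `name`, `taxon`,
#'   `residue_sets` (list of character vectors of allowed letters),
#'   `gap_min`/`gap_max` (integer vectors, one per inter-anchor gap) and
#'   `source_string`.
#' @examples
#' p <- parse_pattern("CxCx20-21Yx3C", name = "bact-I", taxon = "bacteria-GluRS")
#' print(p)
#' @export
parse_pattern <- function(notation, name = notation, taxon = "custom") {
  if (!is.character(notation) || length(notation) != 1L || is.na(notation))
    stop("'notation' must be a single string")
  raw <- notation
  ## normalize: drop underscores, map en/em dashes to "-"
  s <- gsub("_", "", notation, fixed = TRUE)
  s <- gsub("–|—", "-", s)
  if (!nzchar(s)) stop("empty motif notation")

  chars <- strsplit(s, "")[[1]]
  residue_sets <- list()
  gap_min <- integer(0)
  gap_max <- integer(0)
  i <- 1L
  n <- length(chars)
  expect_residue <- TRUE
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("x", "X")) {
      if (expect_residue)
        stop("malformed motif notation at token 'x' (position ", i,
             "): consecutive gaps or leading gap in ", sQuote(raw))
      ## gap token: optional number or a-b range follows
      j <- i + 1L
      num <- ""
      while (j <= n && grepl("[0-9]", chars[j])) { num <- paste0(num, chars[j]); j <- j + 1L }
      if (nzchar(num) && j <= n && chars[j] == "-") {
        num2 <- ""
        k <- j + 1L
        while (k <= n && grepl("[0-9]", chars[k])) { num2 <- paste0(num2, chars[k]); k <- k + 1L }
        if (!nzchar(num2))
          stop("malformed gap range after '", num, "-' in ", sQuote(raw))
        a <- as.integer(num); b <- as.integer(num2)
        if (a > b) stop("invalid gap range ", a, "-", b, " (min > max) in ", sQuote(raw))
        gap_min <- c(gap_min, a); gap_max <- c(gap_max, b)
        i <- k
      } else if (nzchar(num)) {
        gap_min <- c(gap_min, as.integer(num)); gap_max <- c(gap_max, as.integer(num))
        i <- j
      } else {
        gap_min <- c(gap_min, 1L); gap_max <- c(gap_max, 1L)
        i <- j
      }
      expect_residue <- TRUE
    } else if (ch == "[") {
      j <- i + 1L
      set <- character(0)
      while (j <= n && chars[j] != "]") { set <- c(set, toupper(chars[j])); j <- j + 1L }
      if (j > n) stop("unclosed '[' in ", sQuote(raw))
      if (!length(set) || !all(set %in% AA_STANDARD))
        stop("invalid residue set token '[", paste(set, collapse = ""), "]' in ", sQuote(raw))
      residue_sets <- c(residue_sets, list(set))
      if (length(residue_sets) > 1L && length(gap_min) < length(residue_sets) - 1L) {
        gap_min <- c(gap_min, 0L); gap_max <- c(gap_max, 0L)  # adjacent anchors
      }
      i <- j + 1L
      expect_residue <- FALSE
    } else if (toupper(ch) %in% AA_STANDARD) {
      residue_sets <- c(residue_sets, list(toupper(ch)))
      if (length(residue_sets) > 1L && length(gap_min) < length(residue_sets) - 1L) {
        gap_min <- c(gap_min, 0L); gap_max <- c(gap_max, 0L)
      }
      i <- i + 1L
      expect_residue <- FALSE
    } else {
      stop("invalid token '", ch, "' at position ", i, " in ", sQuote(raw))
    }
  }
  if (expect_residue)
    stop("dangling gap at end of motif notation ", sQuote(raw))
  if (length(residue_sets) < 1L)
    stop("motif notation contains no anchored residues: ", sQuote(raw))
  structure(
    list(name = name, taxon = taxon, residue_sets = residue_sets,
         gap_min = gap_min, gap_max = gap_max, source_string = raw),
    class = "motif_pattern")
}

#' @export
format.motif_pattern <- function(x, ...) {
  k <- length(x$residue_sets)
  out <- character(0)
  for (i in seq_len(k)) {
    set <- x$residue_sets[[i]]
    out <- c(out, if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]"))
    if (i < k) {
      a <- x$gap_min[i]; b <- x$gap_max[i]
      out <- c(out,
               if (a == 0L && b == 0L) "" else
               if (a == b && a == 1L) "x" else
               if (a == b) paste0("x", a) else paste0("x", a, "-", b))
    }
  }
  paste(out, collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("ZB-motif pattern ", sQuote(x$name), " [", x$taxon, "]: ",
      format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.motif_pattern <- function(x, ...) format(x)

## minimal anchored span of a pattern (all gaps at minimum)
pattern_min_span <- function(p) length(p$residue_sets) + sum(p$gap_min)
pattern_max_span <- function(p) length(p$residue_sets) + sum(p$gap_max)

#' Built-in ZB-motif catalogs
#'
#' Returns the ordered ZB-motif catalog for a taxon. Catalog order encodes
#' priority: the canonical motif (group I) precedes the modified motif
#' (group II), and [classify_motif()] reports the first catalog entry that
#' matched.
#'
#' The shipped catalogs are: bacterial GluRS
#' (`CxCx20-21Yx3C`, `CxCx20Yx3H`); bacterial Glu-Q-RS (`CxCx11-28Yx3C`);
#' archaeal GluRS (`CxCx14CxC`, `CxCx14CxH`); eukaryal GluRS
#' (`CxCx20Yx3C`, `CxCx20Cx3C`).
#'
#' @param taxon One of `"bacteria-GluRS"`, `"bacteria-GluQRS"`,
#'   `"archaea-GluRS"`, `"eukarya-GluRS"`.
#' @return A list of [motif_pattern][parse_pattern] objects, in priority order.
#' @examples
#' zb_catalog("archaea-GluRS")
#' @export
zb_catalog <- function(taxon = c("bacteria-GluRS", "bacteria-GluQRS",
                                 "archaea-GluRS", "eukarya-GluRS")) {
  taxon <- match.arg(taxon)
  defs <- switch(taxon,
    "bacteria-GluRS"  = list(c("bact-I",  "CxCx20-21Yx3C"),
                             c("bact-II", "CxCx20Yx3H")),
    "bacteria-GluQRS" = list(c("gluqrs-I", "CxCx11-28Yx3C")),
    "archaea-GluRS"   = list(c("arch-I",  "CxCx14CxC"),
                             c("arch-II", "CxCx14CxH")),
    "eukarya-GluRS"   = list(c("euk-I",  "CxCx20Yx3C"),
                             c("euk-II", "CxCx20Cx3C")))
  lapply(defs, function(d) parse_pattern(d[2], name = d[1], taxon = taxon))
}

#' Read a motif catalog from a YAML file
#'
#' The file holds a list of entries with fields `name`, `taxon` and
#' `notation`; order in the file is catalog priority order.
#'
#' @param path Path to the YAML file.
#' @return A list of [motif_pattern][parse_pattern] objects.
#' @export
read_catalog_yaml <- function(path) {
  entries <- yaml::read_yaml(path)
  if (!length(entries)) stop("empty catalog file: ", path)
  lapply(entries, function(e) {
    if (is.null(e$notation)) stop("catalog entry without 'notation' in ", path)
    parse_pattern(e$notation,
                  name = if (is.null(e$name)) e$notation else e$name,
                  taxon = if (is.null(e$taxon)) "custom" else e$taxon)
  })
}

## --- sequence validation ------------------------------------------------

## normalizes to uppercase; errors on anything outside the 20 letters + X
check_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop("'seq' must be a single string")
  s <- toupper(seq)
  bad <- setdiff(unique(strsplit(s, "")[[1]]), c(AA_STANDARD, "X"))
  if (length(bad))
    stop("sequence contains non-amino-acid character(s): ",
         paste(sQuote(bad), collapse = ", "))
  s
}

#' Scan a protein sequence for gapped ZB-motif matches
#'
#' Finds every placement of every pattern whose anchored residues all match
#' the sequence, with each inter-anchor gap length inside the pattern's
#' bounds. All overlapping matches are reported. An `X` in the sequence never
#' satisfies an anchored residue set, but wildcard gaps may span `X`
#' positions (gaps are purely positional). Input is case-insensitive.
#'
#' Hits are ordered leftmost-first, then by pattern catalog order, then by
#' realized gap lengths (shortest first).
#'
#' @param seq Amino-acid sequence (one-letter codes; `X` allowed as unknown).
#' @param patterns A single [motif_pattern][parse_pattern] or a list of them
#'   (e.g. from [zb_catalog()]).
#' @param window Optional length-2 integer vector `c(start, end)`, a 0-based
#'   half-open window; only matches whose anchored residues all lie inside it
#'   are reported.
#' @return A data frame with one row per hit: `pattern`, `start` (0-based
#'   index of the first anchored residue), `end` (0-based exclusive index
#'   past the last), `anchored_positions` and `gaps` (comma-separated).
#' @examples
#' seq <- paste0("AA", "CAC", strrep("A", 20), "Y", "AAA", "C", "AA")
#' scan_sequence(seq, zb_catalog("bacteria-GluRS"))
#' @export
scan_sequence <- function(seq, patterns, window = NULL) {
  s <- check_sequence(seq)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  if (inherits(patterns, "motif_pattern")) patterns <- list(patterns)
  if (!is.null(window)) {
    if (length(window) != 2L || any(is.na(window)))
      stop("'window' must be c(start, end), 0-based half-open")
    if (window[1] < 0 || window[2] > n || window[1] > window[2])
      stop("'window' out of range for sequence of length ", n)
  }
  rows <- list()
  for (pi in seq_along(patterns)) {
    p <- patterns[[pi]]
    hits <- match_pattern(chars, p)
    for (h in hits) {
      if (!is.null(window) && (h$anchors[1] < window[1] ||
                               h$anchors[length(h$anchors)] >= window[2]))
        next
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = p$name,
        pattern_index = pi,
        start = h$anchors[1],
        end = h$anchors[length(h$anchors)] + 1L,
        anchored_positions = paste(h$anchors, collapse = ","),
        gaps = paste(h$gaps, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pattern = character(0), start = integer(0),
                      end = integer(0), anchored_positions = character(0),
                      gaps = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  ## leftmost-first, catalog order, shortest gaps first (gap enumeration in
  ## match_pattern is already ascending, so row order within pattern/start
  ## is lexicographic by gaps; sort stably on the outer keys)
  out <- out[order(out$start, out$pattern_index), , drop = FALSE]
  out$pattern_index <- NULL
  rownames(out) <- NULL
  out
}

## core matcher: anchored candidate positions joined gap-wise.
## Returns list of list(anchors = 0-based integer vector, gaps = integer vector).
match_pattern <- function(chars, p) {
  n <- length(chars)
  k <- length(p$residue_sets)
  if (pattern_min_span(p) > n) return(list())
  cand <- lapply(p$residue_sets, function(set) which(chars %in% set))  # 1-based
  if (any(!lengths(cand))) return(list())
  ## depth-first extension with ascending gap lengths
  res <- list()
  extend <- function(anchors, gaps) {
    j <- length(anchors)
    if (j == k) {
      res[[length(res) + 1L]] <<- list(anchors = anchors - 1L, gaps = gaps)
      return(invisible())
    }
    last <- anchors[j]
    for (g in p$gap_min[j]:p$gap_max[j]) {
      nxt <- last + g + 1L
      if (nxt > n) break
      if (nxt %in% cand[[j + 1L]]) extend(c(anchors, nxt), c(gaps, g))
    }
  }
  for (s0 in cand[[1]]) extend(s0, integer(0))
  ## order: by start then gap-lexicographic ascending (DFS already yields
  ## gap-ascending within a start; starts iterate ascending)
  res
}

#' Classify a sequence's motif status from scan hits
#'
#' Returns the label of the highest-priority catalog pattern with at least
#' one hit (catalog order = priority: canonical before modified), or
#' `"none"` when nothing matched.
#'
#' @param hits A hit data frame from [scan_sequence()].
#' @param catalog The pattern list used for the scan (priority order).
#' @return A single character label.
#' @export
classify_motif <- function(hits, catalog) {
  if (inherits(catalog, "motif_pattern")) catalog <- list(catalog)
  for (p in catalog)
    if (p$name %in% hits$pattern) return(p$name)
  "none"
}

#' Report disrupted (near-miss) motif placements
#'
#' Enumerates every placement of a pattern (start position and realized gap
#' combination) in which at least `min_matches` anchored residues match the
#' sequence but at least one does not — e.g. the disrupted motif
#' `CxMx20Yx3W` relative to `CxCx20-21Yx3C`. This report is descriptive
#' only; it is never used for group assignment.
#'
#' @param seq Amino-acid sequence.
#' @param pattern A [motif_pattern][parse_pattern].
#' @param min_matches Minimum number of matching anchors (default 2).
#' @return A data frame with `start`, `gaps`, `n_matched`, `n_anchors`, and
#'   `matched_mask` (e.g. `"C.CY"` with `.` at mismatched anchors).
#' @export
find_disrupted <- function(seq, pattern, min_matches = 2L) {
  s <- check_sequence(seq)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  k <- length(pattern$residue_sets)
  gap_grid <- expand.grid(lapply(seq_len(k - 1L),
                                 function(j) pattern$gap_min[j]:pattern$gap_max[j]))
  rows <- list()
  for (gi in seq_len(nrow(gap_grid))) {
    gaps <- as.integer(gap_grid[gi, ])
    offsets <- cumsum(c(0L, gaps + 1L))  # anchor offsets from start
    span <- offsets[k] + 1L
    if (span > n) next
    for (s0 in 0:(n - span)) {
      pos <- s0 + offsets  # 0-based anchor positions
      ok <- vapply(seq_len(k), function(j)
        chars[pos[j] + 1L] %in% pattern$residue_sets[[j]], logical(1))
      nm <- sum(ok)
      if (nm >= min_matches && nm < k) {
        mask <- vapply(seq_len(k), function(j)
          if (ok[j]) chars[pos[j] + 1L] else ".", character(1))
        rows[[length(rows) + 1L]] <- data.frame(
          start = s0, gaps = paste(gaps, collapse = ","),
          n_matched = nm, n_anchors = k,
          matched_mask = paste(mask, collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), gaps = character(0),
                      n_matched = integer(0), n_anchors = integer(0),
                      matched_mask = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, -out$n_matched), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a multi-record FASTA file for ZB-motifs
#'
#' Reads protein sequences with [Biostrings::readAAStringSet()] and runs
#' [scan_sequence()] on each record.
#'
#' @param fasta Path to a FASTA file.
#' @param patterns Pattern list, e.g. [zb_catalog()].
#' @param window Optional 0-based half-open window applied to every record.
#' @return A data frame of hits with a leading `seq_id` column.
#' @export
scan_fasta <- function(fasta, patterns, window = NULL) {
  seqs <- Biostrings::readAAStringSet(fasta)
  if (!length(seqs)) stop("no sequences in ", fasta)
  res <- lapply(seq_along(seqs), function(i) {
    h <- scan_sequence(as.character(seqs[[i]]), patterns, window = window)
    if (nrow(h)) cbind(seq_id = names(seqs)[i], h, stringsAsFactors = FALSE)
    else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(seq_id = character(0), pattern = character(0),
                      start = integer(0), end = integer(0),
                      anchored_positions = character(0), gaps = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
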