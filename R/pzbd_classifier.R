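# pZBD extraction from anchor-annotated alignments and five-group assignment.
#
# The pZBD is the region of the GluRS N-terminal catalytic domain lying
# strictly between two beta-strands, E3 and E4.  Anchors are supplied as
# alignment column indices (the pipeline never infers secondary structure):
# e3_col is the last column of strand E3, e4_col the first column of E4,
# both 0-based.  The anchor strands themselves are excluded from the domain,
# so a fully "deleted" pZBD has length 0 even though E3/E4 are retained.

#' Anchor specification for pZBD extraction
#'
#' @param e3_col 0-based alignment column index of the last column of strand
#'   E3.
#' @param e4_col 0-based alignment column index of the first column of strand
#'   E4; must satisfy `e3_col < e4_col`.
#' @return A list of class `anchor_spec`.
#' @export
anchor_spec <- function(e3_col, e4_col) {
  e3_col <- as.integer(e3_col); e4_col <- as.integer(e4_col)
  if (is.na(e3_col) || is.na(e4_col) || e3_col < 0L || e4_col <= e3_col)
    stop("invalid anchors: need 0 <= e3_col < e4_col")
  structure(list(e3_col = e3_col, e4_col = e4_col), class = "anchor_spec")
}

#' Read an anchor specification from YAML
#'
#' The file must define `e3_col` and `e4_col` (0-based columns).
#' @param path Path to the YAML file.
#' @return An [anchor_spec()].
#' @export
read_anchors_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$e3_col) || is.null(y$e4_col))
    stop("anchors file must define e3_col and e4_col: ", path)
  anchor_spec(y$e3_col, y$e4_col)
}

## coerce an alignment argument to a named uppercase character vector
as_alignment_chars <- function(alignment) {
  if (inherits(alignment, "AAStringSet") || inherits(alignment, "XStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  if (!is.character(alignment) || !length(alignment))
    stop("'alignment' must be a non-empty character vector or AAStringSet")
  widths <- nchar(alignment)
  if (length(unique(widths)) != 1L)
    stop("ragged alignment: records have widths ",
         paste(unique(widths), collapse = ", "))
  if (is.null(names(alignment)))
    names(alignment) <- paste0("seq", seq_along(alignment))
  toupper(alignment)
}

#' Extract pZBD windows and lengths from an anchored alignment
#'
#' For each record, the pZBD is the ungapped residue stretch strictly
#' between alignment columns `e3_col` and `e4_col`; its length is the number
#' of non-gap characters in that column range. Coordinates are reported in
#' 0-based half-open ungapped sequence space.
#'
#' @param alignment Aligned sequences: a named character vector, an
#'   `AAStringSet`, or a path to an aligned FASTA file.
#' @param anchors An [anchor_spec()] (or list with `e3_col`, `e4_col`).
#' @return A data frame with `seq_id`, `pzbd_start`, `pzbd_end`, `length`.
#' @examples
#' aln <- c(a = "MK-CDEF-GH", b = "MKQC--FAGH")
#' extract_pzbd(aln, anchor_spec(2, 8))
#' @export
extract_pzbd <- function(alignment, anchors) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment) && !grepl("[\n-]", alignment))
    alignment <- Biostrings::readAAStringSet(alignment)
  aln <- as_alignment_chars(alignment)
  if (!inherits(anchors, "anchor_spec"))
    anchors <- anchor_spec(anchors$e3_col, anchors$e4_col)
  width <- nchar(aln[[1]])
  if (anchors$e4_col >= width)
    stop("anchor e4_col (", anchors$e4_col, ") outside alignment width ", width)
  gap_chars <- c("-", ".")
  res <- lapply(seq_along(aln), function(i) {
    chars <- strsplit(aln[[i]], "")[[1]]
    is_res <- !(chars %in% gap_chars)
    ## columns strictly between anchors, 1-based: (e3_col+2) .. e4_col
    inner <- if (anchors$e4_col - anchors$e3_col > 1L)
      seq.int(anchors$e3_col + 2L, anchors$e4_col) else integer(0)
    len <- sum(is_res[inner])
    before <- sum(is_res[seq_len(anchors$e3_col + 1L)])
    data.frame(seq_id = names(aln)[i], pzbd_start = before,
               pzbd_end = before + len, length = len,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assign a sequence to one of the five pZBD groups
#'
#' Group I: canonical taxon motif present. Group II: modified taxon motif.
#' For motif-free sequences the pZBD length decides: group V ("deleted") for
#' length 0-17, group IV ("short") for 31-36, group III ("long") for
#' length 37 and above. Motif-free lengths 18-30 fall in a gap with no
#' observed members and are flagged `"unassigned"` rather than silently
#' misfiled.
#'
#' @param length Non-negative integer pZBD length (vectorised).
#' @param motif_label Label from [classify_motif()] on the pZBD window
#'   (vectorised; `"none"` for motif-free).
#' @param catalog Pattern list defining which labels are group I/II
#'   (default: bacterial GluRS catalog).
#' @return Character vector of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"` or
#'   `"unassigned"`.
#' @examples
#' assign_group(50, "bact-I")
#' assign_group(c(33, 12, 50), c("none", "none", "none"))
#' @export
assign_group <- function(length, motif_label, catalog = zb_catalog("bacteria-GluRS")) {
  if (any(is.na(length)) || any(length < 0)) stop("negative or missing pZBD length")
  if (inherits(catalog, "motif_pattern")) catalog <- list(catalog)
  labels <- vapply(catalog, function(p) p$name, character(1))
  n <- max(base::length(length), base::length(motif_label))
  length <- rep_len(as.integer(length), n)
  motif_label <- rep_len(motif_label, n)
  vapply(seq_len(n), function(i) {
    ml <- motif_label[i]; L <- length[i]
    j <- match(ml, labels)
    if (!is.na(j) && j <= 2L) return(c("I", "II")[j])
    if (L <= 17L) "V"
    else if (L >= 31L && L <= 36L) "IV"
    else if (L >= 37L) "III"
    else "unassigned"
  }, character(1))
}

#' Classify every sequence of an anchored alignment into pZBD groups
#'
#' Full per-sequence pipeline: extract the pZBD window between the E3/E4
#' anchors, scan it (plus a small margin on each side, so a motif anchor
#' falling on a strand edge still counts) with the taxon catalog, and assign
#' groups I-V.
#'
#' @inheritParams extract_pzbd
#' @param taxon Catalog selector passed to [zb_catalog()], or a pattern list.
#' @param margin Residues added to each side of the pZBD window for motif
#'   scanning (default 3).
#' @return A data frame with `seq_id`, `pzbd_start`, `pzbd_end`, `length`,
#'   `motif_label`, `group`.
#' @export
classify_pzbd <- function(alignment, anchors, taxon = "bacteria-GluRS",
                          margin = 3L) {
  catalog <- if (is.character(taxon)) zb_catalog(taxon) else taxon
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment) && !grepl("[\n-]", alignment))
    alignment <- Biostrings::readAAStringSet(alignment)
  aln <- as_alignment_chars(alignment)
  ann <- extract_pzbd(aln, anchors)
  ungapped <- gsub("[-.]", "", aln)
  ann$motif_label <- vapply(seq_len(nrow(ann)), function(i) {
    s <- ungapped[[i]]
    w0 <- max(0L, ann$pzbd_start[i] - margin)
    w1 <- min(nchar(s), ann$pzbd_end[i] + margin)
    hits <- scan_sequence(s, catalog, window = c(w0, w1))
    classify_motif(hits, catalog)
  }, character(1))
  ann$group <- assign_group(ann$length, ann$motif_label, catalog)
  ann
}

#' Length histogram of pZBDs split by motif status
#'
#' Counts annotations per pZBD length, split into motif-containing and
#' motif-free. Every length in the requested range appears in the output,
#' with zero counts where empty.
#'
#' @param annotations Data frame from [classify_pzbd()] (needs `length` and
#'   `motif_label`).
#' @param range Optional length-2 integer vector of lengths to tabulate
#'   (default: observed min to max).
#' @return A data frame with `length`, `with_motif`, `without_motif`.
#' @export
length_histogram <- function(annotations, range = NULL) {
  if (!nrow(annotations)) stop("no annotations to tabulate")
  if (is.null(range)) range <- c(min(annotations$length), max(annotations$length))
  lens <- seq.int(range[1], range[2])
  has <- annotations$motif_label != "none"
  data.frame(
    length = lens,
    with_motif = vapply(lens, function(L)
      sum(annotations$length == L & has), integer(1)),
    without_motif = vapply(lens, function(L)
      sum(annotations$length == L & !has), integer(1)))
}
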