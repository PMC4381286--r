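# Genomic co-occurrence logic linking pZBD deletion to redundancy or
# disruption of the indirect glutaminylation pathway.
#
# A genome has a *direct* Gln-tRNA(Gln) route when it encodes GlnRS or a
# second, tRNA(Gln)-specific GluRS copy (GluRS2).  The *indirect* route
# (GluRS misacylation followed by GatCAB transamidation) requires the
# gatCAB operon and the tRNA(Gln) acceptor-stem 1/72 identity pair
# recognised by GatCAB.  The consistency model: a pZBD-deleted GluRS is
# expected only where the indirect route is redundant (direct route
# present) or already disrupted (gatCAB missing or a non-matching 1/72
# signature).

VALID_BASES <- c("A", "C", "G", "U")

## does an observed 1/72 pair satisfy the required pair?
## orientation = "either" accepts the reversed reading as well, because the
## literature writes the same pair in both orientations (U1-A72 vs A1-U72).
signature_matches <- function(pair, required, orientation = c("either", "exact")) {
  orientation <- match.arg(orientation)
  pair <- toupper(pair); required <- toupper(required)
  if (pair == "??" || grepl("\\?", pair)) return(NA)
  chk <- function(p) {
    b <- strsplit(p, "")[[1]]
    if (length(b) != 2L || !all(b %in% VALID_BASES))
      stop("invalid 1/72 base pair: ", sQuote(p))
    b
  }
  b <- chk(pair); r <- chk(required)
  identical(b, r) || (orientation == "either" && identical(rev(b), r))
}

#' Evaluate pathway consistency for one genome
#'
#' Applies the co-occurrence model to a genome's gene-content flags: the
#' verdict is consistent unless the GluRS pZBD is deleted while the genome
#' has no direct glutaminylation route (neither GlnRS nor GluRS2) *and* the
#' indirect route is intact (gatCAB present and the tRNA-Gln 1/72 identity
#' pair compatible with GatCAB recognition).
#'
#' An unknown 1/72 signature (`"?"` characters) propagates conservatively:
#' the indirect route is treated as intact and the verdict is annotated.
#' Because the 1/72 pair appears in the literature in both orientations,
#' matching is orientation-insensitive by default (`orientation = "either"`).
#'
#' @param ctx A one-row data frame or list with fields `genome_id`,
#'   `has_glnrs`, `has_glurs2`, `has_gatcab` (logical), `trna_gln_1_72`
#'   (two-character pair over A/C/G/U, or `"?"`/`"??"`), `pzbd_deleted`
#'   (logical).
#' @param required_pair The 1/72 pair required for productive GatCAB
#'   recognition (default `"UA"`, i.e. U1-A72).
#' @param orientation `"either"` (default) or `"exact"` signature matching.
#' @return A one-row data frame: `genome_id`, `direct_gln_route`,
#'   `indirect_route_intact`, `consistent`, `note`.
#' @examples
#' evaluate_pathway(list(genome_id = "g1", has_glnrs = TRUE,
#'   has_glurs2 = FALSE, has_gatcab = TRUE, trna_gln_1_72 = "UA",
#'   pzbd_deleted = TRUE))
#' @export
evaluate_pathway <- function(ctx, required_pair = "UA",
                             orientation = c("either", "exact")) {
  orientation <- match.arg(orientation)
  direct <- isTRUE(as.logical(ctx$has_glnrs)) || isTRUE(as.logical(ctx$has_glurs2))
  sig <- signature_matches(as.character(ctx$trna_gln_1_72), required_pair,
                           orientation)
  note <- ""
  if (is.na(sig)) {
    indirect <- isTRUE(as.logical(ctx$has_gatcab))
    if (indirect) note <- "1/72 signature unknown; indirect route assumed intact"
  } else {
    indirect <- isTRUE(as.logical(ctx$has_gatcab)) && sig
  }
  deleted <- isTRUE(as.logical(ctx$pzbd_deleted))
  consistent <- !deleted || direct || !indirect
  if (!consistent)
    note <- paste0("exception: pZBD deleted with intact indirect route ",
                   "and no direct route")
  data.frame(genome_id = as.character(ctx$genome_id),
             direct_gln_route = direct,
             indirect_route_intact = indirect,
             consistent = consistent, note = note,
             stringsAsFactors = FALSE)
}

#' Evaluate pathway consistency for a genome table
#'
#' Row-wise [evaluate_pathway()] over a genome context table.
#'
#' @param contexts Data frame with the columns described in
#'   [evaluate_pathway()], or a path to a TSV file with those columns.
#' @inheritParams evaluate_pathway
#' @return A data frame with one verdict row per genome.
#' @export
evaluate_pathways <- function(contexts, required_pair = "UA",
                              orientation = c("either", "exact")) {
  orientation <- match.arg(orientation)
  contexts <- read_genome_table(contexts)
  out <- do.call(rbind, lapply(seq_len(nrow(contexts)), function(i)
    evaluate_pathway(contexts[i, ], required_pair, orientation)))
  rownames(out) <- NULL
  out
}

#' Read (or pass through) a genome context table
#'
#' @param x A data frame, or a path to a TSV with header columns
#'   `genome_id`, `has_glnrs`, `has_glurs2`, `has_gatcab`,
#'   `trna_gln_1_72`, `pzbd_deleted`.
#' @return A data frame with logical flag columns.
#' @export
read_genome_table <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, colClasses = "character")
  }
  need <- c("genome_id", "has_glnrs", "has_glurs2", "has_gatcab",
            "trna_gln_1_72", "pzbd_deleted")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("genome table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("has_glnrs", "has_glurs2", "has_gatcab", "pzbd_deleted")) {
    v <- x[[col]]
    if (is.character(v)) {
      v <- ifelse(v %in% c("1", "true", "TRUE", "True"), TRUE,
                  ifelse(v %in% c("0", "false", "FALSE", "False"), FALSE, NA))
    }
    x[[col]] <- as.logical(v)
  }
  x
}

#' Exact test of association between pZBD deletion and a direct route
#'
#' Builds the 2x2 contingency table of `pzbd_deleted` against presence of a
#' direct glutaminylation route (GlnRS or GluRS2) and computes the
#' two-sided exact hypergeometric p-value (Fisher's exact test: the sum of
#' the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table).
#'
#' @param contexts Genome context data frame or TSV path (see
#'   [read_genome_table()]); the two tested fields must have no unknowns.
#' @return A list with `table` (2x2 integer matrix, rows = pZBD deleted
#'   TRUE/FALSE, columns = direct route TRUE/FALSE), `p_value`, and
#'   `odds_ratio` (conditional MLE from the exact test).
#' @export
contingency_test <- function(contexts) {
  contexts <- read_genome_table(contexts)
  if (!nrow(contexts)) stop("empty genome table")
  deleted <- as.logical(contexts$pzbd_deleted)
  direct <- as.logical(contexts$has_glnrs) | as.logical(contexts$has_glurs2)
  if (any(is.na(deleted)) || any(is.na(direct)))
    stop("unknown values in tested fields")
  tab <- table(factor(deleted, levels = c(TRUE, FALSE)),
               factor(direct, levels = c(TRUE, FALSE)))
  dimnames(tab) <- list(pzbd_deleted = c("TRUE", "FALSE"),
                        direct_route = c("TRUE", "FALSE"))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = unclass(tab), p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}

#' The seven pZBD-deleted bacterial genomes
#'
#' Loads the packaged table of the seven bacteria whose GluRS lacks the
#' pZBD (three tenericutes, two verrucomicrobia, one planctomycete, one
#' alpha-proteobacterial GluRS1), with their GlnRS/GluRS2/gatCAB content
#' and tRNA-Gln 1/72 identity signature. Gene-content flags encode
#' published genome annotations. Only two signatures are published exactly
#' (U1-A72 for the N. sennetsu GluRS1 genome, A1-U72 for M. infernorum);
#' the five genomes reported merely as lacking the U1-A72 signature carry
#' the synthetic placeholder pair `"GC"`, which matches neither
#' orientation of the requirement.
#'
#' @return A genome context data frame (see [read_genome_table()]).
#' @export
pzbd_deleted_genomes <- function() {
  read_genome_table(system.file("extdata", "pzbd_deleted_genomes.tsv",
                                package = "pzbd", mustWork = TRUE))
}
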