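# ORF-integrity evaluation and pseudogene calling for opsin coding sequences.

#' Transmembrane-region annotation for a reference coding sequence
#'
#' Maps the packaged bovine rod-opsin helix topology (approximate helix
#' bounds in bovine residue numbering) onto reference codon coordinates
#' through a bovine numbering map of the reference protein.
#'
#' @param reference An [opsin_sequence()] with CDS.
#' @param path Optional TSV (`region`, `start`, `end`) of bovine residue
#'   ranges overriding the packaged topology.
#' @return Data frame with columns `region`, `start`, `end` in reference
#'   codon coordinates.
#' @export
tm_regions_for_reference <- function(reference, path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "bovine_tm_regions.tsv",
                        package = "salmopsin", mustWork = TRUE)
  }
  tm <- read.delim(path, stringsAsFactors = FALSE)
  map <- map_to_bovine_numbering(reference)
  ok <- !is.na(map$query_pos) & !is.na(map$bovine_pos)
  bov2q <- setNames(map$query_pos[ok], map$bovine_pos[ok])
  conv <- function(b, side) {
    # nearest mapped bovine position at or inside the helix bound
    cand <- as.integer(names(bov2q))
    cand <- if (side == "start") cand[cand >= b] else cand[cand <= b]
    if (!length(cand)) return(NA_integer_)
    bov2q[[as.character(if (side == "start") min(cand) else max(cand))]]
  }
  out <- data.frame(
    region = tm$region,
    start = vapply(tm$start, conv, integer(1), side = "start"),
    end = vapply(tm$end, conv, integer(1), side = "end"))
  out[!is.na(out$start) & !is.na(out$end), ]
}

.aln_nt <- function(query_cds, reference_cds) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query_cds), Biostrings::DNAString(reference_cds),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
  list(q = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]],
       r = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]])
}

#' Evaluate the ORF integrity of a candidate opsin coding sequence
#'
#' Aligns the query CDS globally to an intact reference CDS, locates indels
#' and classifies them by length modulo 3 (frameshifting or in-frame),
#' translates the query to find premature stop codons, and checks whether
#' any large deletion disrupts an annotated transmembrane region. The
#' verdict is:
#'
#' * `pseudogene` - at least one frameshifting indel or premature stop
#'   codon (or a query shorter than half the reference, recorded as a
#'   truncation);
#' * `nonfunctional_suspect` - no frameshift or stop, but an in-frame
#'   deletion of at least `large_deletion_nt` nucleotides, flagged
#'   `tm3_disruption` when it overlaps an annotated transmembrane helix;
#' * `intact` - none of the above.
#'
#' @param query,reference [opsin_sequence()] records with CDS; the reference
#'   must translate without internal stop codons.
#' @param tm_regions Data frame of reference codon ranges (`region`,
#'   `start`, `end`); defaults to the bovine helix topology mapped through
#'   the reference's bovine numbering.
#' @param large_deletion_nt Threshold (nt) for a "large" in-frame deletion.
#' @return An `orf_report`.
#' @export
evaluate_orf <- function(query, reference, tm_regions = NULL,
                         large_deletion_nt = 30L) {
  if (is.null(query$cds) || is.null(reference$cds)) {
    stop("both query and reference must carry a CDS")
  }
  ref_aa <- .translate_cds(reference$cds)
  if (grepl("\\*", sub("\\*$", "", ref_aa))) {
    stop("reference '", reference$id, "' has an internal stop codon")
  }
  if (is.null(tm_regions)) {
    tm_regions <- tm_regions_for_reference(reference)
  }

  truncation <- "none"
  if (nchar(query$cds) < 0.5 * nchar(reference$cds)) {
    truncation <- if (substr(query$cds, 1, 3) == substr(reference$cds, 1, 3))
      "3prime" else "5prime"
    rep <- structure(list(
      query_id = query$id, reference_id = reference$id,
      indels = data.frame(reference_codon_position = integer(),
                          length_nt = integer(), type = character(),
                          frame_effect = character()),
      premature_stops = integer(), truncation = truncation,
      tm3_disruption = FALSE, verdict = "pseudogene"),
      class = "orf_report")
    return(rep)
  }

  al <- .aln_nt(query$cds, reference$cds)
  qpos <- cumsum(al$q != "-")
  rpos <- cumsum(al$r != "-")

  # indel runs over alignment columns
  state <- ifelse(al$q == "-", "deletion", ifelse(al$r == "-", "insertion",
                                                  "match"))
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  indels <- list()
  for (k in seq_along(runs$values)) {
    if (runs$values[k] == "match") next
    len <- runs$lengths[k]
    # reference nucleotide at the run (deletion) or the base the inserted
    # segment precedes (insertion)
    rstart <- if (runs$values[k] == "deletion") rpos[starts[k]]
              else min(rpos[starts[k]] + 1L, max(rpos))
    codon <- (rstart - 1L) %/% 3L + 1L
    indels[[length(indels) + 1L]] <- data.frame(
      reference_codon_position = codon, length_nt = len,
      type = runs$values[k],
      frame_effect = if (len %% 3L == 0L) "in-frame" else "frameshift")
  }
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(reference_codon_position = integer(), length_nt = integer(),
               type = character(), frame_effect = character())

  # premature stops: translate the query in its own first frame and map the
  # stop codon's first nucleotide to a reference codon through the alignment
  q_aa <- .translate_cds(query$cds)
  aa_vec <- strsplit(q_aa, "")[[1]]
  stops_q <- which(aa_vec == "*")
  stops_q <- stops_q[stops_q < length(aa_vec)]  # terminal stop is normal
  premature_stops <- vapply(stops_q, function(cp) {
    nt1 <- 3L * cp - 2L
    col <- match(nt1, qpos * (al$q != "-"))
    if (is.na(col) || al$r[col] == "-") return((nt1 - 1L) %/% 3L + 1L)
    (rpos[col] - 1L) %/% 3L + 1L
  }, integer(1))

  big_del <- indels[indels$type == "deletion" &
                      indels$length_nt >= large_deletion_nt, , drop = FALSE]
  tm3 <- FALSE
  if (nrow(big_del) && nrow(tm_regions)) {
    for (i in seq_len(nrow(big_del))) {
      c1 <- big_del$reference_codon_position[i]
      c2 <- c1 + (big_del$length_nt[i] - 1L) %/% 3L
      if (any(tm_regions$start <= c2 & tm_regions$end >= c1)) tm3 <- TRUE
    }
  }

  n_frameshift <- sum(indels$frame_effect == "frameshift")
  large_inframe_del <- any(indels$type == "deletion" &
                             indels$frame_effect == "in-frame" &
                             indels$length_nt >= large_deletion_nt)
  verdict <- if (n_frameshift >= 1L || length(premature_stops) >= 1L) {
    "pseudogene"
  } else if (tm3 || large_inframe_del) {
    "nonfunctional_suspect"
  } else {
    "intact"
  }

  structure(list(query_id = query$id, reference_id = reference$id,
                 indels = indels, premature_stops = premature_stops,
                 truncation = truncation, tm3_disruption = tm3,
                 verdict = verdict),
            class = "orf_report")
}

#' @export
print.orf_report <- function(x, ...) {
  cat("<orf_report> ", x$query_id, " vs ", x$reference_id, ": ",
      toupper(x$verdict), "\n", sep = "")
  if (nrow(x$indels)) {
    cat("  indels:\n"); print(x$indels, row.names = FALSE)
  }
  if (length(x$premature_stops)) {
    cat("  premature stop(s) at reference codon(s): ",
        paste(x$premature_stops, collapse = ", "), "\n", sep = "")
  }
  if (x$tm3_disruption) cat("  transmembrane-region disruption\n")
  if (x$truncation != "none") cat("  truncation: ", x$truncation, "\n",
                                  sep = "")
  invisible(x)
}

#' Serialize an ORF report as JSON
#'
#' @param report An `orf_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_orf_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' One-line verdict table for a set of ORF reports
#'
#' @param reports An `orf_report` or list of them.
#' @param path Optional TSV output file.
#' @return Data frame with columns `query_id`, `reference_id`, `n_indels`,
#'   `n_frameshifts`, `n_premature_stops`, `tm3_disruption`, `truncation`,
#'   `verdict`.
#' @export
orf_verdict_table <- function(reports, path = NULL) {
  if (inherits(reports, "orf_report")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) {
    data.frame(query_id = r$query_id, reference_id = r$reference_id,
               n_indels = nrow(r$indels),
               n_frameshifts = sum(r$indels$frame_effect == "frameshift"),
               n_premature_stops = length(r$premature_stops),
               tm3_disruption = r$tm3_disruption,
               truncation = r$truncation, verdict = r$verdict)
  }))
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' GFF-like lesion track for an ORF report
#'
#' One line per indel and premature stop, 1-based inclusive reference
#' nucleotide coordinates.
#'
#' @param report An `orf_report`.
#' @param path Optional output file.
#' @return Data frame in GFF-like column layout.
#' @export
orf_lesion_track <- function(report, path = NULL) {
  rows <- list()
  if (nrow(report$indels)) {
    for (i in seq_len(nrow(report$indels))) {
      c1 <- report$indels$reference_codon_position[i]
      len <- report$indels$length_nt[i]
      start <- 3L * (c1 - 1L) + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = report$reference_id, source = "salmopsin",
        type = report$indels$type[i], start = start,
        end = start + max(len - 1L, 0L), score = ".", strand = "+",
        frame = ".", attributes = paste0("frame_effect=",
                                         report$indels$frame_effect[i]))
    }
  }
  for (cp in report$premature_stops) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = report$reference_id, source = "salmopsin",
      type = "premature_stop", start = 3L * (cp - 1L) + 1L, end = 3L * cp,
      score = ".", strand = "+", frame = ".",
      attributes = paste0("query=", report$query_id))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seqid = character(), source = character(), type = character(),
               start = integer(), end = integer(), score = character(),
               strand = character(), frame = character(),
               attributes = character())
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  df
}
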