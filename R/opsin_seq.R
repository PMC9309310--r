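# Sequence ingestion, bovine-numbered site extraction, identity screening.

.OPSIN_CLASSES <- c("lws", "sws1", "sws2", "rh2", "rh1", "unknown")

# Bovine-numbered spectral tuning sites registered per opsin class.
# rh1: the 27 rod-opsin sites interrogated for rod pigments; lws: the
# five-sites rule positions; sws1: site 86 (UV/violet switch); rh2: site 122
# (E122Q green/blue switch). sws2 pigments are handled by the descriptor
# regression route, so no rule sites are registered.
.TUNING_SITES <- list(
  rh1  = c(83L, 90L, 96L, 102L, 113L, 118L, 122L, 124L, 132L, 164L, 183L,
           194L, 195L, 207L, 208L, 211L, 214L, 253L, 261L, 265L, 269L,
           289L, 292L, 295L, 299L, 300L, 317L),
  lws  = c(164L, 181L, 261L, 269L, 292L),
  sws1 = 86L,
  rh2  = 122L,
  sws2 = integer(0)
)

.AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWYX*", "")[[1]]
.NT_LETTERS <- strsplit("ACGTURYSWKMBDHVN", "")[[1]]

#' Registered spectral tuning sites for an opsin class
#'
#' @param opsin_class One of `"lws"`, `"sws1"`, `"sws2"`, `"rh2"`, `"rh1"`.
#' @return Integer vector of bovine-numbered sites (possibly empty).
#' @export
registered_sites <- function(opsin_class) {
  if (!opsin_class %in% names(.TUNING_SITES)) {
    stop("unknown opsin_class '", opsin_class, "'; valid classes: ",
         paste(names(.TUNING_SITES), collapse = ", "))
  }
  .TUNING_SITES[[opsin_class]]
}

.translate_cds <- function(cds) {
  n <- 3L * (nchar(cds) %/% 3L)
  if (n < 3L) stop("cds shorter than one codon")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE))
  aa
}

.protein_to_first_stop <- function(aa) sub("\\*.*$", "", aa)

#' Construct an opsin sequence record
#'
#' Holds a coding and/or protein sequence together with species and opsin
#' class labels. When only a CDS is given the protein is derived by
#' translating the first complete reading frame up to the first stop codon.
#'
#' @param id Accession or label.
#' @param cds Optional nucleotide coding sequence.
#' @param protein Optional amino-acid sequence (derived from `cds` if absent).
#' @param species Species label.
#' @param opsin_class One of `r paste(.OPSIN_CLASSES, collapse = ", ")`.
#' @return An object of class `opsin_sequence`.
#' @export
opsin_sequence <- function(id, cds = NULL, protein = NULL,
                           species = NA_character_, opsin_class = "unknown") {
  opsin_class <- match.arg(opsin_class, .OPSIN_CLASSES)
  if (is.null(cds) && is.null(protein)) {
    stop("record '", id, "': need cds and/or protein")
  }
  if (!is.null(cds)) {
    cds <- toupper(cds)
    bad <- setdiff(strsplit(cds, "")[[1]], .NT_LETTERS)
    if (length(bad)) {
      stop("record '", id, "': non-IUPAC nucleotide character(s): ",
           paste(unique(bad), collapse = ", "))
    }
    if (nchar(cds) < 3L) stop("record '", id, "': cds shorter than 3 nt")
  }
  if (is.null(protein)) {
    protein <- .protein_to_first_stop(.translate_cds(cds))
  } else {
    protein <- toupper(protein)
    bad <- setdiff(strsplit(protein, "")[[1]], .AA_LETTERS)
    if (length(bad)) {
      stop("record '", id, "': non-IUPAC amino-acid character(s): ",
           paste(unique(bad), collapse = ", "))
    }
  }
  if (nchar(protein) == 0L) stop("record '", id, "': empty protein")
  if (!is.null(cds)) {
    tr <- .protein_to_first_stop(.translate_cds(cds))
    if (!identical(tr, .protein_to_first_stop(protein))) {
      stop("record '", id,
           "': translation of first frame does not match protein")
    }
  }
  structure(list(id = id, species = species, opsin_class = opsin_class,
                 cds = cds, protein = protein),
            class = "opsin_sequence")
}

#' @export
print.opsin_sequence <- function(x, ...) {
  cat("<opsin_sequence> ", x$id, "  class=", x$opsin_class,
      if (!is.na(x$species)) paste0("  species=", x$species), "\n", sep = "")
  cat("  protein: ", nchar(x$protein), " aa",
      if (!is.null(x$cds)) paste0("; cds: ", nchar(x$cds), " nt"), "\n",
      sep = "")
  invisible(x)
}

.infer_class <- function(header) {
  m <- regmatches(tolower(header),
                  regexpr("(lws|sws1|sws2|rh1|rh2)", tolower(header)))
  if (length(m)) m else "unknown"
}

#' Read opsin sequences from a FASTA file
#'
#' Nucleotide records become coding sequences (protein derived by
#' translation); amino-acid records are stored as protein only. The opsin
#' class is inferred from class tags (`lws`, `sws1`, `sws2`, `rh1`, `rh2`)
#' anywhere in the header, `"unknown"` otherwise.
#'
#' @param path FASTA file.
#' @return A list of [opsin_sequence()] records.
#' @export
read_opsin_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- strsplit(trimws(header), "[ \t]")[[1]][1]
    seqchars <- toupper(as.character(set[[i]]))
    letters <- unique(strsplit(seqchars, "")[[1]])
    if (all(letters %in% c("A", "C", "G", "T", "U", "N"))) {
      opsin_sequence(id, cds = seqchars, opsin_class = .infer_class(header))
    } else {
      opsin_sequence(id, protein = seqchars,
                     opsin_class = .infer_class(header))
    }
  })
}

#' Write opsin sequences to FASTA
#'
#' @param seqs List of [opsin_sequence()] records.
#' @param path Output file.
#' @param what `"cds"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_opsin_fasta <- function(seqs, path, what = c("cds", "protein")) {
  what <- match.arg(what)
  if (inherits(seqs, "opsin_sequence")) seqs <- list(seqs)
  txt <- unlist(lapply(seqs, function(s) {
    body <- if (what == "cds") s$cds else s$protein
    if (is.null(body)) stop("record '", s$id, "' has no ", what)
    c(paste0(">", s$id, " class=", s$opsin_class), body)
  }))
  writeLines(txt, path)
  invisible(path)
}

#' The bovine rod opsin reference protein
#'
#' The 348-residue bovine rhodopsin used as the conventional numbering
#' reference for spectral tuning sites (accession NP_001014890).
#'
#' @return An [opsin_sequence()]; the accession is stored in
#'   `attr(, "accession")`.
#' @export
bovine_rhodopsin <- function() {
  path <- system.file("extdata", "bovine_rh1_NP001014890.fasta",
                      package = "salmopsin", mustWork = TRUE)
  ref <- read_opsin_fasta(path)[[1]]
  ref$opsin_class <- "rh1"
  ref$species <- "Bos taurus"
  attr(ref, "accession") <- "NP_001014890"
  ref
}

#' Map a query opsin onto bovine rod-opsin numbering
#'
#' Globally aligns the query protein against the 348-residue bovine rod opsin
#' (end gaps penalized, BLOSUM62) and records, column by column, which query
#' position corresponds to which bovine position. Opsins are full-length
#' globally alignable GPCRs, so a global alignment is appropriate.
#'
#' @param query An [opsin_sequence()].
#' @param reference Reference protein string or [opsin_sequence()]
#'   (default: [bovine_rhodopsin()]); must be 348 residues.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A `numbering_map`: data frame with columns `query_pos` and
#'   `bovine_pos` (NA marks a gap in that sequence). Queries shorter than
#'   100 residues set `attr(, "unreliable") = TRUE` with a warning.
#' @export
map_to_bovine_numbering <- function(query, reference = bovine_rhodopsin(),
                                    gap_opening = 10, gap_extension = 0.5) {
  qp <- if (inherits(query, "opsin_sequence")) query$protein else query
  rp <- if (inherits(reference, "opsin_sequence")) reference$protein else reference
  if (!nzchar(qp) || !nzchar(rp)) stop("empty protein sequence")
  if (nchar(rp) != 348L) {
    stop("reference must be the 348-residue bovine rod opsin (got ",
         nchar(rp), " residues)")
  }
  unreliable <- FALSE
  if (nchar(qp) < 100L) {
    warning("query shorter than 100 residues; bovine numbering unreliable")
    unreliable <- TRUE
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qp), Biostrings::AAString(rp),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(qa != "-")
  rpos <- cumsum(ra != "-")
  map <- data.frame(
    query_pos  = ifelse(qa != "-", qpos, NA_integer_),
    bovine_pos = ifelse(ra != "-", rpos, NA_integer_))
  class(map) <- c("numbering_map", "data.frame")
  attr(map, "unreliable") <- unreliable
  map
}

#' Extract residues at the registered tuning sites of a class
#'
#' @param query An [opsin_sequence()].
#' @param map A `numbering_map` computed for `query` by
#'   [map_to_bovine_numbering()].
#' @param opsin_class Class whose registered site list is read off; defaults
#'   to the query's own class.
#' @return A `tuning_site_profile`: named character vector of one-letter
#'   residues, `"-"` where the site falls in an alignment gap, with
#'   `pigment_id` and `opsin_class` attributes.
#' @export
extract_tuning_sites <- function(query, map,
                                 opsin_class = query$opsin_class) {
  sites <- registered_sites(opsin_class)
  res <- vapply(sites, function(s) {
    hit <- map$query_pos[!is.na(map$bovine_pos) & map$bovine_pos == s]
    hit <- hit[!is.na(hit)]
    if (length(hit) != 1L) "-" else substr(query$protein, hit, hit)
  }, character(1))
  tuning_site_profile(setNames(res, sites), pigment_id = query$id,
                      opsin_class = opsin_class)
}

#' Construct a tuning-site profile directly
#'
#' @param residues Named character vector: names are bovine-numbered sites,
#'   values one-letter residue codes or `"-"` for unalignable sites.
#' @param pigment_id Label.
#' @param opsin_class Opsin class; sites must belong to the class's
#'   registered list.
#' @return A `tuning_site_profile`.
#' @export
tuning_site_profile <- function(residues, pigment_id = "pigment",
                                opsin_class) {
  sites <- as.integer(names(residues))
  reg <- registered_sites(opsin_class)
  if (anyNA(sites) || !all(sites %in% reg)) {
    stop("sites must belong to the registered ", opsin_class, " list: ",
         paste(reg, collapse = ", "))
  }
  ok <- residues %in% c(strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]], "-")
  if (!all(ok)) stop("invalid residue code(s): ",
                     paste(residues[!ok], collapse = ", "))
  structure(as.character(residues), names = as.character(sites),
            pigment_id = pigment_id, opsin_class = opsin_class,
            class = "tuning_site_profile")
}

#' @export
print.tuning_site_profile <- function(x, ...) {
  cat("<tuning_site_profile> ", attr(x, "pigment_id"),
      " (", attr(x, "opsin_class"), ")\n", sep = "")
  print(setNames(as.character(x), names(x)))
  invisible(x)
}

#' Write tuning-site profiles as TSV
#'
#' Columns: `pigment_id`, `class`, `site`, `residue`.
#'
#' @param profiles A `tuning_site_profile` or list of them.
#' @param path Output file (or connection).
#' @return The assembled data frame, invisibly.
#' @export
write_site_profile_tsv <- function(profiles, path) {
  if (inherits(profiles, "tuning_site_profile")) profiles <- list(profiles)
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(pigment_id = attr(p, "pigment_id"),
               class = attr(p, "opsin_class"),
               site = as.integer(names(p)), residue = as.character(p))
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Global-alignment nucleotide percent identity
#'
#' Identity is matches divided by alignment columns (internal gap columns
#' included), times 100, from a global alignment with affine gap penalties.
#'
#' @param a,b Nucleotide strings.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  Biostrings::pid(aln, type = "PID1")
}

#' Codon-aware coding-sequence percent identity
#'
#' Aligns the translations globally, projects the protein alignment back onto
#' codons (each aligned residue pair contributes its three nucleotide
#' columns, each gap three gap columns), and scores nucleotide identity over
#' the projected columns. Used when both records carry a CDS, since probe
#' targets are coding regions.
#'
#' @param a_cds,b_cds Coding sequences (nucleotide strings).
#' @return Percent identity in `[0, 100]`.
#' @export
codon_identity <- function(a_cds, b_cds) {
  ap <- .protein_to_first_stop(.translate_cds(a_cds))
  bp <- .protein_to_first_stop(.translate_cds(b_cds))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ap), Biostrings::AAString(bp),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qpos <- cumsum(qa != "-")
  rpos <- cumsum(ra != "-")
  matches <- 0L
  cols <- 3L * length(qa)
  for (i in seq_along(qa)) {
    if (qa[i] == "-" || ra[i] == "-") next
    ca <- substr(a_cds, 3L * qpos[i] - 2L, 3L * qpos[i])
    cb <- substr(b_cds, 3L * rpos[i] - 2L, 3L * rpos[i])
    matches <- matches +
      sum(strsplit(ca, "")[[1]] == strsplit(cb, "")[[1]])
  }
  100 * matches / cols
}

#' Pairwise identity matrix for probe cross-hybridization screening
#'
#' @param seqs List of [opsin_sequence()] records with CDS.
#' @param codon_aware Use [codon_identity()] when both CDS present (default),
#'   else plain [percent_identity()].
#' @return Symmetric matrix of percent identities (100 on the diagonal).
#' @export
identity_matrix <- function(seqs, codon_aware = TRUE) {
  n <- length(seqs)
  ids <- vapply(seqs, function(s) s$id, character(1))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- seqs[[i]]$cds; b <- seqs[[j]]$cds
    if (is.null(a) || is.null(b)) stop("identity_matrix requires CDS")
    v <- if (codon_aware) codon_identity(a, b) else percent_identity(a, b)
    m[i, j] <- m[j, i] <- v
  }
  m
}

#' Flag riboprobe cross-hybridization risk from percent identity
#'
#' Probes above 90% identity to a paralogue hybridize to it; below 65% no
#' cross-hybridization is expected; the intermediate band is uncertain (the
#' ~87% identity observed within the rh2 and lws classes falls there, where
#' cross-hybridization is likely but not assured).
#'
#' @param identity Percent identity in `[0, 100]`.
#' @return One of `"hybridizes"`, `"uncertain"`, `"no_cross"`.
#' @export
cross_hybridization_flag <- function(identity) {
  stopifnot(is.numeric(identity), identity >= 0, identity <= 100)
  vapply(identity, function(x) {
    if (x >= 90) "hybridizes" else if (x <= 65) "no_cross" else "uncertain"
  }, character(1))
}
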