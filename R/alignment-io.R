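#' @useDynLib opsinconv, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm pchisq sd rpois rgeom runif uniroot setNames dhyper fisher.test
#' @importFrom utils combn write.table packageVersion
NULL

ALN_BASES <- c("A", "C", "G", "T")
ALN_GAP <- c("-", "N")
# two-fold IUPAC ambiguity codes and their (alphabetical) expansions
IUPAC2 <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)
ALN_ALPHABET <- c(ALN_BASES, ALN_GAP, names(IUPAC2))

new_alignment <- function(seq_matrix, meta = NULL) {
  if (is.null(meta)) {
    meta <- do.call(rbind, lapply(rownames(seq_matrix), function(id) {
      cbind(raw_id = id, as.data.frame(parse_sequence_id(id, quiet = TRUE),
                                       stringsAsFactors = FALSE))
    }))
    rownames(meta) <- NULL
  }
  structure(list(seq = seq_matrix, meta = meta), class = "lm_alignment")
}

#' Construct an alignment from named sequence strings
#'
#' Convenience constructor used throughout the package (and its tests) to
#' build an alignment in code. Record metadata (individual, species, sex,
#' locus) is parsed from the names via [parse_sequence_id()].
#'
#' @param x Named character vector of equal-length sequence strings.
#' @return An object of class `lm_alignment`: a list with `seq` (character
#'   matrix, records x sites, uppercase) and `meta` (data frame of parsed
#'   record metadata).
#' @export
as_alignment <- function(x) {
  stopifnot(is.character(x), length(x) >= 1, !is.null(names(x)))
  x <- toupper(x)
  lens <- nchar(x)
  if (length(unique(lens)) != 1) {
    stop("sequences are not aligned: lengths ", paste(unique(lens), collapse = ", "))
  }
  if (anyDuplicated(names(x))) stop("duplicate record IDs")
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(m) <- names(x)
  bad <- which(!(m %in% ALN_ALPHABET))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    stop(sprintf("illegal symbol '%s' in record '%s' at site %d",
                 m[bad[1]], rownames(m)[i[1]], i[2]))
  }
  new_alignment(m)
}

#' @export
print.lm_alignment <- function(x, ...) {
  cat(sprintf("lm_alignment: %d records x %d sites\n", nrow(x$seq), ncol(x$seq)))
  cat("records:", paste(utils::head(rownames(x$seq), 6), collapse = ", "),
      if (nrow(x$seq) > 6) "..." else "", "\n")
  invisible(x)
}

#' Number of sites / records in an alignment
#' @param aln An `lm_alignment`.
#' @return Integer.
#' @export
n_sites <- function(aln) ncol(aln$seq)

#' @rdname n_sites
#' @export
n_records <- function(aln) nrow(aln$seq)

#' Read a sequential FASTA alignment
#'
#' Reads a multi-FASTA file of aligned sequences, checks that all records
#' have equal length and contain only `A C G T - N` and the two-fold IUPAC
#' ambiguity codes (`R Y S W K M`), and parses record metadata from the IDs
#' (scheme `<individual>_<species>_<sex>_<locus>`, e.g. `1_Hag_M_L`).
#'
#' @param path Path to a FASTA file.
#' @return An `lm_alignment` with records in file order, case-normalized to
#'   uppercase.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  x <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  as_alignment(x)
}

#' Write an alignment to sequential FASTA
#'
#' @param aln An `lm_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$seq, 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- rownames(aln$seq)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Parse a record ID of the form `<individual>_<species>_<sex>_<locus>`
#'
#' IDs follow the underscore scheme used for the opsin data sets:
#' `1_Hag_M_L` is individual 1, species code `Hag`, male, L opsin locus.
#' Neutral-reference records put the locus code in the third field and an
#' allele number in the fourth (`55_Hla_E_1` is an eta-globin allele), in
#' which case sex is unknown. Non-conforming IDs parse leniently to
#' all-unknown with `locus = "other"` and a warning.
#'
#' @param raw_id Character ID.
#' @param quiet Suppress the non-conforming warning.
#' @return A list with `individual`, `species`, `sex` (`"M"`, `"F"` or
#'   `"unknown"`), `locus` (`"L"`, `"M"`, `"E"`, `"S"` or `"other"`) and
#'   `copy` (allele/copy field for neutral references, else `NA`).
#' @export
parse_sequence_id <- function(raw_id, quiet = FALSE) {
  unknown <- list(individual = "unknown", species = "unknown",
                  sex = "unknown", locus = "other", copy = NA_character_)
  tok <- strsplit(raw_id, "_", fixed = TRUE)[[1]]
  if (length(tok) != 4 || !grepl("^[A-Za-z]{3}$", tok[2])) {
    if (!quiet) warning("ID does not follow the naming scheme: ", raw_id)
    return(unknown)
  }
  if (tok[3] %in% c("M", "F")) {
    list(individual = tok[1], species = tok[2], sex = tok[3],
         locus = if (tok[4] %in% c("L", "M", "E", "S")) tok[4] else "other",
         copy = NA_character_)
  } else if (tok[3] %in% c("E", "S")) {
    # neutral reference: third field is the locus, fourth the allele
    list(individual = tok[1], species = tok[2], sex = "unknown",
         locus = tok[3], copy = tok[4])
  } else {
    if (!quiet) warning("ID does not follow the naming scheme: ", raw_id)
    unknown
  }
}

#' Reassemble a record ID from parsed fields
#' @param p A list as returned by [parse_sequence_id()].
#' @return Character ID.
#' @export
format_sequence_id <- function(p) {
  if (!is.na(p$copy)) paste(p$individual, p$species, p$locus, p$copy, sep = "_")
  else paste(p$individual, p$species, p$sex, p$locus, sep = "_")
}

#' Complete-deletion site filter
#'
#' Returns the (1-based, increasing) site indices at which no sequence in
#' `ids` carries a gap (`-`) or an undetermined base (`N`). This is the
#' "eliminate all positions containing gaps" rule applied before every
#' distance computation; `N` is treated like a gap (conservative).
#'
#' @param aln An `lm_alignment`.
#' @param ids Record IDs defining the comparison set; default all records.
#' @return Integer vector of retained site indices.
#' @export
complete_deletion_columns <- function(aln, ids = rownames(aln$seq)) {
  if (length(ids) == 0) stop("empty record subset")
  miss <- setdiff(ids, rownames(aln$seq))
  if (length(miss)) stop("unknown record IDs: ", paste(miss, collapse = ", "))
  m <- aln$seq[ids, , drop = FALSE]
  which(colSums(matrix(m %in% ALN_GAP, nrow = nrow(m))) == 0)
}

#' Split a record with heterozygous sites into two haplotype records
#'
#' Two-fold IUPAC ambiguity codes are resolved deterministically: the
#' alphabetically first base goes to copy `_a`, the second to copy `_b`.
#' Per-site statistics are unaffected by this arbitrary phasing; analyses
#' that genuinely require haplotypes are restricted to single-copy males.
#'
#' @param aln An `lm_alignment`.
#' @param id Record ID to split.
#' @return An `lm_alignment` with two records (`<id>_a`, `<id>_b`).
#' @export
split_heterozygous_record <- function(aln, id) {
  s <- aln$seq[id, ]
  bad <- which(!(s %in% c(ALN_BASES, ALN_GAP, names(IUPAC2))))
  if (length(bad)) {
    stop("unsupported symbol '", s[bad[1]], "' at site ", bad[1],
         " (three/four-fold ambiguity codes are not supported)")
  }
  a <- s
  b <- s
  het <- which(s %in% names(IUPAC2))
  for (j in het) {
    exp2 <- IUPAC2[[s[j]]]
    a[j] <- exp2[1]
    b[j] <- exp2[2]
  }
  m <- rbind(a, b)
  rownames(m) <- paste0(id, c("_a", "_b"))
  new_alignment(m)
}

#' Subset an alignment by record IDs
#' @param aln An `lm_alignment`.
#' @param ids Record IDs to keep (in the given order).
#' @return An `lm_alignment`.
#' @export
subset_records <- function(aln, ids) {
  keep <- match(ids, rownames(aln$seq))
  if (anyNA(keep)) stop("unknown record IDs: ",
                        paste(ids[is.na(keep)], collapse = ", "))
  new_alignment(aln$seq[keep, , drop = FALSE], aln$meta[keep, , drop = FALSE])
}

#' Assign records to analysis groups
#'
#' The default grouping is species x locus (e.g. `Hag_L`), the unit used for
#' diversity, divergence and among-group trees.
#'
#' @param aln An `lm_alignment`.
#' @param by Either `"species_locus"` or a named character vector mapping
#'   record ID to group key.
#' @return Named character vector: record ID -> group key.
#' @export
group_labels <- function(aln, by = "species_locus") {
  if (is.character(by) && length(by) == 1 && by == "species_locus") {
    setNames(paste(aln$meta$species, aln$meta$locus, sep = "_"),
             aln$meta$raw_id)
  } else {
    miss <- setdiff(rownames(aln$seq), names(by))
    if (length(miss)) stop("records without a group: ", paste(miss, collapse = ", "))
    by[rownames(aln$seq)]
  }
}
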