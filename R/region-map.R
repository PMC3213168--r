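#' Define the exon/intron layout of an aligned gene region
#'
#' A region map partitions the alignment into named exon and intron
#' intervals (1-based, inclusive, non-overlapping, sorted) and anchors the
#' spectral-tuning residues to codon start offsets inside exons. `phase` is
#' the codon position (0, 1 or 2) of the first base of each exon, i.e. how
#' many bases of the current codon were already seen in the previous exon;
#' phases must chain consistently across consecutive exons.
#'
#' @param regions Data frame with columns `name`, `start`, `end`, `kind`
#'   (`"exon"`/`"intron"`) and `phase` (`NA` for introns).
#' @param anchors Named list: residue number -> `list(region=, offset=)`
#'   where `offset` is the 1-based offset of the codon's first base within
#'   the region.
#' @return An object of class `region_map`.
#' @export
region_map <- function(regions, anchors = list()) {
  stopifnot(is.data.frame(regions),
            all(c("name", "start", "end", "kind", "phase") %in% names(regions)))
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  if (any(regions$end < regions$start)) stop("region with end < start")
  if (anyDuplicated(regions$name)) stop("duplicate region names")
  if (!all(regions$kind %in% c("exon", "intron"))) stop("kind must be exon or intron")
  if (nrow(regions) > 1 &&
      any(regions$start[-1] <= regions$end[-nrow(regions)])) {
    stop("regions overlap")
  }
  ex <- regions[regions$kind == "exon", , drop = FALSE]
  if (any(is.na(ex$phase)) || !all(ex$phase %in% 0:2)) {
    stop("every exon needs a codon phase in 0..2")
  }
  if (nrow(ex) > 1) {
    len <- ex$end - ex$start + 1
    expected <- (ex$phase[-nrow(ex)] + len[-nrow(ex)]) %% 3
    if (!all(expected == ex$phase[-1])) {
      stop("exon lengths are incompatible with the declared codon phases")
    }
  }
  for (res in names(anchors)) {
    a <- anchors[[res]]
    r <- regions[regions$name == a$region, ]
    if (nrow(r) != 1 || r$kind != "exon") {
      stop("anchor for residue ", res, " must fall in an exon region")
    }
    if (a$offset < 1 || a$offset + 2 > r$end - r$start + 1) {
      stop("anchor codon for residue ", res, " exceeds region ", a$region)
    }
  }
  structure(list(regions = regions, anchors = anchors), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("region_map:\n")
  print(x$regions)
  if (length(x$anchors)) {
    cat("anchors:",
        paste(sprintf("%s@%s+%d", names(x$anchors),
                      vapply(x$anchors, `[[`, "", "region"),
                      vapply(x$anchors, function(a) as.integer(a$offset), 0L)),
              collapse = "  "), "\n")
  }
  invisible(x)
}

#' Default layout of the central L/M opsin region (exon 3 - exon 5)
#'
#' Exon 3 (169 bp), intron 3 (1550 bp), exon 4 (166 bp), intron 4 (1550 bp)
#' and exon 5 (240 bp), 3675 aligned sites in total, with the spectral-tuning
#' residues anchored at residue 180 (exon 3) and residues 277 and 285
#' (exon 5). The exon phases chain as 0/1/2 so that codons split across
#' introns are reassembled when exons are concatenated.
#'
#' @return A `region_map`.
#' @export
default_region_map <- function() {
  regions <- data.frame(
    name  = c("exon3", "intron3", "exon4", "intron4", "exon5"),
    start = c(1L, 170L, 1720L, 1886L, 3436L),
    end   = c(169L, 1719L, 1885L, 3435L, 3675L),
    kind  = c("exon", "intron", "exon", "intron", "exon"),
    phase = c(0L, NA, 1L, NA, 2L),
    stringsAsFactors = FALSE
  )
  region_map(regions, anchors = list(
    `180` = list(region = "exon3", offset = 115L),
    `277` = list(region = "exon5", offset = 71L),
    `285` = list(region = "exon5", offset = 95L)
  ))
}

region_interval <- function(map, name) {
  r <- map$regions[map$regions$name == name, ]
  if (nrow(r) != 1) stop("unknown region name: ", name)
  r
}

#' Site indices covered by named regions
#' @param map A `region_map`.
#' @param names Region names; default all.
#' @param kind Optionally restrict to `"exon"` or `"intron"` regions.
#' @return Integer vector of 1-based site indices, in map order.
#' @export
region_sites <- function(map, names = map$regions$name, kind = NULL) {
  if (length(names) == 0) stop("empty region name list")
  if (!is.null(kind)) {
    names <- intersect(names, map$regions$name[map$regions$kind == kind])
  }
  unlist(lapply(names, function(nm) {
    r <- region_interval(map, nm)
    seq.int(r$start, r$end)
  }), use.names = FALSE)
}

#' Extract named regions from an alignment
#'
#' Concatenates the named intervals in map order. For pure-exon slices the
#' phase of the first exon is carried in attribute `"phase"`.
#'
#' @param aln An `lm_alignment`.
#' @param map A `region_map`.
#' @param names Region names to keep.
#' @return An `lm_alignment` of the concatenated slice.
#' @export
slice_region <- function(aln, map, names) {
  sites <- region_sites(map, names)
  out <- new_alignment(aln$seq[, sites, drop = FALSE], aln$meta)
  kinds <- map$regions$kind[match(names, map$regions$name)]
  if (all(kinds == "exon")) {
    attr(out, "phase") <- region_interval(map, names[1])$phase
  }
  out
}

#' Absolute alignment positions of an anchored residue's codon
#' @param map A `region_map`.
#' @param residue_number Residue number with an anchor in the map.
#' @return Integer vector of the codon's three site indices.
#' @export
anchor_codon_sites <- function(map, residue_number) {
  a <- map$anchors[[as.character(residue_number)]]
  if (is.null(a)) stop("no anchor for residue ", residue_number)
  r <- region_interval(map, a$region)
  r$start + a$offset - 1 + 0:2
}

#' Map coding sites to codons
#'
#' Concatenates all exon regions in order and, honouring the first exon's
#' phase, assigns each coding site to a codon. Leading/trailing bases that
#' belong to codons not fully contained in the region are dropped (their
#' alignment positions are returned in `partial`).
#'
#' @param map A `region_map`.
#' @return List with `sites` (alignment positions of in-frame coding sites,
#'   by codon), `codon` (codon index per coding site), `pos_in_codon`
#'   (1..3) and `partial` (alignment positions of dropped partial-codon
#'   bases).
#' @export
coding_frame <- function(map) {
  ex <- map$regions[map$regions$kind == "exon", , drop = FALSE]
  coding_sites <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    seq.int(ex$start[i], ex$end[i])
  }))
  skip <- (3 - ex$phase[1]) %% 3
  n <- length(coding_sites)
  n_codons <- (n - skip) %/% 3
  used <- coding_sites[skip + seq_len(n_codons * 3)]
  partial <- setdiff(coding_sites, used)
  list(sites = used,
       codon = rep(seq_len(n_codons), each = 3),
       pos_in_codon = rep(1:3, times = n_codons),
       partial = partial)
}

#' Read/write a region map as YAML
#'
#' The on-disk format mirrors the constructor: a `regions` list of
#' `{name,start,end,kind,phase}` entries and an `anchors` map.
#'
#' @param path YAML file path.
#' @return A `region_map` (for the reader); `path` invisibly (writer).
#' @export
read_region_map <- function(path) {
  y <- yaml::read_yaml(path)
  regions <- do.call(rbind, lapply(y$regions, function(r) {
    data.frame(name = r$name, start = as.integer(r$start),
               end = as.integer(r$end), kind = r$kind,
               phase = if (is.null(r$phase)) NA_integer_ else as.integer(r$phase),
               stringsAsFactors = FALSE)
  }))
  anchors <- lapply(y$anchors, function(a) list(region = a$region,
                                               offset = as.integer(a$offset)))
  region_map(regions, anchors)
}

#' @rdname read_region_map
#' @param map A `region_map` to write.
#' @export
write_region_map <- function(map, path) {
  y <- list(
    regions = lapply(seq_len(nrow(map$regions)), function(i) {
      r <- map$regions[i, ]
      out <- list(name = r$name, start = r$start, end = r$end, kind = r$kind)
      if (!is.na(r$phase)) out$phase <- r$phase
      out
    }),
    anchors = lapply(map$anchors, function(a) list(region = a$region,
                                                   offset = a$offset))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
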