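AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Stop")

translate_codon <- function(codon) {
  # codon: character vector of 3 bases or a 3-character string
  if (length(codon) == 3) codon <- paste(codon, collapse = "")
  aa1 <- unname(Biostrings::GENETIC_CODE[codon])
  if (is.na(aa1)) return(NA_character_)
  unname(AA3[aa1])
}

#' Amino acid at an anchored spectral-tuning residue
#'
#' Extracts the anchored codon for `residue_number` from one record and
#' translates it with the standard genetic code. A gap, `N` or ambiguity
#' code inside the codon yields `"undetermined"` (flagged, not fatal).
#'
#' @param aln An `lm_alignment`.
#' @param id Record ID.
#' @param map A `region_map` with an anchor for `residue_number`.
#' @param residue_number Residue number (180, 277 or 285 in the default map).
#' @return Three-letter amino acid code (e.g. `"Tyr"`) or `"undetermined"`.
#' @export
residue_at <- function(aln, id, map, residue_number) {
  sites <- anchor_codon_sites(map, residue_number)
  codon <- aln$seq[id, sites]
  if (!all(codon %in% ALN_BASES)) return("undetermined")
  translate_codon(codon)
}

#' Classify an opsin gene from the three spectral-tuning residues
#'
#' The L opsin is defined by Tyr277/Thr285 and the M opsin by Phe277/Ala285;
#' any other 277/285 combination is `"undetermined"` (a putative exon-5
#' hybrid). A spectral hybrid is an L gene carrying Ala180 or an M gene
#' carrying Ser180. The peak absorbance is inferred by the additive model
#' (see [infer_lambda_max()]).
#'
#' @param res180,res277,res285 Three-letter amino acid codes.
#' @return A list of class `opsin_genotype` with fields `res180`, `res277`,
#'   `res285`, `gene_call` (`"L"`, `"M"` or `"undetermined"`),
#'   `spectral_hybrid` and `lambda_max_nm` (NA when not modeled).
#' @export
classify_opsin_gene <- function(res180, res277, res285) {
  gene_call <- if (identical(res277, "Tyr") && identical(res285, "Thr")) "L"
               else if (identical(res277, "Phe") && identical(res285, "Ala")) "M"
               else "undetermined"
  hybrid <- (gene_call == "L" && identical(res180, "Ala")) ||
            (gene_call == "M" && identical(res180, "Ser"))
  structure(list(res180 = res180, res277 = res277, res285 = res285,
                 gene_call = gene_call, spectral_hybrid = hybrid,
                 lambda_max_nm = infer_lambda_max(res180, res277, res285)),
            class = "opsin_genotype")
}

#' Additive model of peak absorbance (lambda max)
#'
#' Starting from the 560 nm L pigment anchor, the substitutions Ser180Ala,
#' Tyr277Phe and Thr285Ala shift lambda max by -7, -8 and -15 nm in an
#' additive manner, reaching the 530 nm M pigment when all three M-type
#' residues are present. Unmodeled residues give `NA` with an explanatory
#' attribute.
#'
#' @param res180 `"Ser"` or `"Ala"`.
#' @param res277 `"Tyr"` or `"Phe"`.
#' @param res285 `"Thr"` or `"Ala"`.
#' @return Peak absorbance in nm, or `NA`.
#' @export
infer_lambda_max <- function(res180, res277, res285) {
  ok <- identical(res180, "Ser") || identical(res180, "Ala")
  ok <- ok && (identical(res277, "Tyr") || identical(res277, "Phe"))
  ok <- ok && (identical(res285, "Thr") || identical(res285, "Ala"))
  if (!ok) {
    return(structure(NA_real_,
                     reason = "residue outside the modeled tuning states"))
  }
  560 - 7 * identical(res180, "Ala") - 8 * identical(res277, "Phe") -
    15 * identical(res285, "Ala")
}

#' @export
print.opsin_genotype <- function(x, ...) {
  cat(sprintf("opsin genotype: %s (180=%s, 277=%s, 285=%s)%s  lambda_max=%s nm\n",
              x$gene_call, x$res180, x$res277, x$res285,
              if (x$spectral_hybrid) " [spectral hybrid]" else "",
              ifelse(is.na(x$lambda_max_nm), "NA", x$lambda_max_nm)))
  invisible(x)
}

#' Genotype every record of an alignment
#'
#' @param aln An `lm_alignment`.
#' @param map A `region_map` with anchors for residues 180, 277 and 285.
#' @return Data frame: record ID, the three residues, `gene_call`,
#'   `spectral_hybrid` and `lambda_max_nm`. Undetermined calls are reported,
#'   never dropped.
#' @export
opsin_genotype_table <- function(aln, map) {
  rows <- lapply(rownames(aln$seq), function(id) {
    g <- classify_opsin_gene(residue_at(aln, id, map, 180),
                             residue_at(aln, id, map, 277),
                             residue_at(aln, id, map, 285))
    data.frame(raw_id = id, res180 = g$res180, res277 = g$res277,
               res285 = g$res285, gene_call = g$gene_call,
               spectral_hybrid = g$spectral_hybrid,
               lambda_max_nm = as.numeric(g$lambda_max_nm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
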